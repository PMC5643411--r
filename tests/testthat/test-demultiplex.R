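fq_dt <- function(id, seq, qual = strrep("D", max(c(1L, nchar(seq))))) {
  data.table(id = id, seq = seq,
             qual = substr(rep_len(qual, length(seq)), 1L, nchar(seq)))
}

test_that("composite reads concatenate the documented slots", {
  r1 <- fq_dt("r1", random_seq <- paste(rep("ACGT", 63), collapse = ""))
  r1$seq <- substr(r1$seq, 1, 251); r1$qual <- strrep("D", 251)
  r2 <- fq_dt("r1", strrep("A", 251), strrep("E", 251))
  i1 <- fq_dt("r1", "GGGGGG", "FFFFFF")
  comp <- compose_reads(r1, r2, i1)
  expect_equal(nchar(comp$seq), 30 + 6 + 6 + 251)
  expect_equal(comp$umi_region, strrep("A", 30))
  expect_equal(comp$i1_hex, "GGGGGG")
  expect_equal(comp$r1_hex, substr(r1$seq, 7, 12))
  expect_equal(substr(comp$seq, 43, nchar(comp$seq)), r1$seq)
  # qualities concatenate the same way
  expect_equal(comp$qual, paste0(strrep("E", 30), "FFFFFF",
                                 strrep("D", 6), strrep("D", 251)))
})

test_that("empty streams give empty output and short records are dropped", {
  e <- fq_dt(character(), character())
  comp <- compose_reads(e, e, e)
  expect_equal(nrow(comp), 0L)
  expect_equal(attr(comp, "dropped"), 0L)

  r1 <- fq_dt(c("a", "b"), c(strrep("A", 100), strrep("A", 100)))
  r2 <- fq_dt(c("a", "b"), c(strrep("C", 20), strrep("C", 100)))
  i1 <- fq_dt(c("a", "b"), c("GGGGGG", "GGGGGG"))
  comp <- compose_reads(r1, r2, i1)
  expect_equal(nrow(comp), 1L)
  expect_equal(attr(comp, "dropped"), 1L)
})

test_that("desynchronized read IDs are a hard error at the record", {
  r1 <- fq_dt(c("a", "b"), rep(strrep("A", 50), 2))
  r2 <- fq_dt(c("a", "x"), rep(strrep("C", 50), 2))
  i1 <- fq_dt(c("a", "b"), rep("GGGGGG", 2))
  expect_error(compose_reads(r1, r2, i1), "record 2")
})

test_that("index matching honours the mismatch budget and ambiguity rule", {
  sheet <- data.frame(sample_name = c("A", "B"),
                      index1 = c("AAAAAA", "CCCCCC"),
                      index2 = c("GGGGGG", "TTTTTT"))
  mk <- function(i1, r1hex, n = 1L) {
    r1 <- fq_dt(paste0("r", seq_len(n)),
                rep(paste0("ACGTAC", r1hex, strrep("A", 100)), n))
    r2 <- fq_dt(r1$id, rep(strrep("C", 40), n))
    i1 <- fq_dt(r1$id, rep(i1, n))
    compose_reads(r1, r2, i1)
  }
  # exact match: all reads to A, none elsewhere
  asg <- demultiplex_reads(mk("AAAAAA", "GGGGGG", 100L), sheet, 1L)
  expect_equal(unname(attr(asg, "counts")), c(100L, 0L, 0L))
  # one substitution in index1: assigned at mm=1, undetermined at mm=0
  one_off <- mk("AAAAAT", "GGGGGG")
  expect_equal(demultiplex_reads(one_off, sheet, 1L)$sample, "A")
  expect_equal(demultiplex_reads(one_off, sheet, 0L)$sample,
               "undetermined")
  # sheet rows differing by one base in index2 only; equidistant read is
  # ambiguous and must be routed to undetermined
  sheet2 <- data.frame(sample_name = c("A", "B"),
                       index1 = c("AAAAAA", "AAAAAA"),
                       index2 = c("GGGGGG", "GGGGGT"))
  # read index2 "GGGGGA": distance 1 to both rows
  amb <- mk("AAAAAA", "GGGGGA")
  asg2 <- demultiplex_reads(amb, sheet2, 1L)
  expect_equal(asg2$sample, "undetermined")
  expect_equal(attr(asg2, "ambiguous"), 1L)
})

test_that("per-sample counts + undetermined + dropped conserve the input", {
  sim <- toy_sim()
  d <- withr::local_tempdir()
  sheet <- data.frame(sample_name = "toy_beta", index1 = "ATCACG",
                      index2 = "CGATGT")
  # corrupt one R2 to trigger a drop
  r2 <- copy(sim$reads$r2)
  r2$seq[1L] <- substr(r2$seq[1L], 1L, 10L)
  r2$qual[1L] <- substr(r2$qual[1L], 1L, 10L)
  f1 <- file.path(d, "R1.fq"); f2 <- file.path(d, "R2.fq")
  f3 <- file.path(d, "I1.fq")
  write_fastq(sim$reads$r1$id, sim$reads$r1$seq, sim$reads$r1$qual, f1)
  write_fastq(r2$id, r2$seq, r2$qual, f2)
  write_fastq(sim$reads$i1$id, sim$reads$i1$seq, sim$reads$i1$qual, f3)
  log <- demultiplex_fastq(f1, f2, f3, sheet, file.path(d, "out"),
                           compress = FALSE)
  expect_equal(sum(log$counts) + log$dropped, nrow(sim$reads$r1))
  expect_equal(log$dropped, 1L)
})

test_that("error-free simulated reads demultiplex to their generating sample
           and output is byte-identical across runs", {
  simA <- toy_sim(seed = 5L, sample_index = c("ATCACG", "CGATGT"))
  simB <- toy_sim(seed = 6L, sample_index = c("TTAGGC", "TGACCA"))
  sheet <- data.frame(sample_name = c("sampleA_beta", "sampleB_beta"),
                      index1 = c("ATCACG", "TTAGGC"),
                      index2 = c("CGATGT", "TGACCA"))
  d <- withr::local_tempdir()
  cat_fq <- function(part, path) {
    a <- simA$reads[[part]]; b <- simB$reads[[part]]
    write_fastq(c(a$id, b$id), c(a$seq, b$seq), c(a$qual, b$qual), path)
  }
  f1 <- file.path(d, "R1.fq"); f2 <- file.path(d, "R2.fq")
  f3 <- file.path(d, "I1.fq")
  cat_fq("r1", f1); cat_fq("r2", f2); cat_fq("i1", f3)
  log1 <- demultiplex_fastq(f1, f2, f3, sheet, file.path(d, "run1"),
                            compress = FALSE)
  log2 <- demultiplex_fastq(f1, f2, f3, sheet, file.path(d, "run2"),
                            compress = FALSE)
  expect_equal(unname(log1$counts[c("sampleA_beta", "sampleB_beta",
                                    "undetermined")]),
               c(nrow(simA$reads$r1), nrow(simB$reads$r1), 0L))
  for (s in c("sampleA_beta", "sampleB_beta")) {
    expect_identical(readLines(log1$files[[s]]), readLines(log2$files[[s]]))
  }
})
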