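test_that("tag search agrees with a brute-force Hamming scan", {
  tt <- tag_table(toy)
  set.seed(42)
  # exact tag embedded at a known position
  q <- paste0(umitcr:::random_dna(1, 17), tt$tag[3L], umitcr:::random_dna(1, 25))
  hits <- find_tag_hits(q, toy)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos, 17L)
  expect_equal(hits$mm, 0L)
  expect_equal(hits$segment_class, tt$segment_class[3L])
  expect_equal(hits$gene_idx, tt$gene_idx[3L])
  # one substitution inside the tag is still found, two are not; a random
  # panel is compared hit-for-hit against the oracle
  for (i in 1:10) {
    tag_i <- sample(nrow(tt), 1L)
    tag <- tt$tag[tag_i]
    n_err <- sample(0:2, 1L)
    mut <- strsplit(tag, "")[[1]]
    pos_err <- sample(nchar(tag), n_err)
    for (p in pos_err) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1L]
    q <- paste0(umitcr:::random_dna(1, 11), paste(mut, collapse = ""),
                umitcr:::random_dna(1, 13))
    got <- as.data.frame(find_tag_hits(q, toy)[, .(pos, mm)])
    want <- oracle_tag_scan(q, tt$tag, 1L)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      expect_equal(got[order(got$pos), ],
                   want[order(want$pos), c("pos", "mm")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("constructed reads decombine to their generating identifier", {
  # junction bases chosen not to extend either germline flank, so the drawn
  # identifier is already canonical
  comp <- make_composite(0L, 1L, 2L, 1L, "TTT")
  res <- decombine_reads(comp$seq, comp$qual, comp$id, toy)
  expect_equal(nrow(res$records), 1L)
  r <- res$records
  expect_equal(r$v_index, 0L)
  expect_equal(r$j_index, 1L)
  expect_equal(r$v_deletions, 2L)
  expect_equal(r$j_deletions, 1L)
  expect_equal(r$insert, "TTT")
  expect_true(grepl(r$insert, r$intertag, fixed = TRUE))
  expect_equal(r$umi_region, substr(comp$seq, 1L, 30L))
  # identity case: no deletions, empty insert
  comp0 <- make_composite(2L, 2L, 0L, 0L, "")
  r0 <- decombine_reads(comp0$seq, comp0$qual, comp0$id, toy)$records
  expect_equal(unlist(r0[, .(v_index, j_index, v_deletions, j_deletions)]),
               c(v_index = 2L, j_index = 2L, v_deletions = 0L,
                 j_deletions = 0L))
  expect_equal(r0$insert, "")
})

test_that("no-calls are categorized and conserved in the log", {
  comp <- make_composite(0L, 1L, 2L, 1L, "TTT")
  # remove the J region entirely -> no J tag
  no_j <- substr(comp$seq, 1L, nchar(comp$seq) - 65L)
  res <- decombine_reads(c(comp$seq, no_j), rep(comp$qual, 2) |>
                           substr(1, nchar(c(comp$seq, no_j))),
                         c("a", "b"), toy)
  expect_equal(res$log$assigned, 1L)
  expect_equal(unname(res$log$no_call["no_j_tag"]), 1L)
  expect_equal(res$log$assigned + sum(res$log$no_call), res$log$reads_in)
})

test_that("deletion/insert decomposition is canonical-minimal (oracle)", {
  set.seed(7)
  for (i in 1:25) {
    vi <- sample(0:3, 1L); ji <- sample(0:2, 1L)
    vd <- sample(0:8, 1L); jd <- sample(0:6, 1L)
    ins <- umitcr:::random_dna(1, sample(0:12, 1L))
    comp <- make_composite(vi, ji, vd, jd, ins)
    rec <- decombine_reads(comp$seq, comp$qual, comp$id, toy)$records
    expect_equal(nrow(rec), 1L)
    want <- oracle_decompose(rec$intertag, vi, ji)
    expect_equal(rec$v_deletions, want$v_deletions)
    expect_equal(rec$j_deletions, want$j_deletions)
    expect_equal(rec$insert, want$insert)
    # soundness: identifier reconstructs to a sequence consistent with the
    # read between the tag anchors
    full <- reconstruct_sequence(rec$v_index, rec$j_index, rec$v_deletions,
                                 rec$j_deletions, rec$insert, toy)
    expect_true(grepl(rec$intertag, full, fixed = TRUE))
  }
})

test_that("a single tag mismatch is tolerated and counted in the error rate", {
  comp <- make_composite(1L, 0L, 3L, 2L, "AATT")
  # mutate one base inside the V tag (tag occupies R1 positions 31..50 of
  # the rearrangement; locate it in the composite read)
  tag <- toy$v_genes$tag[2L]
  pos <- regexpr(tag, comp$seq, fixed = TRUE)[[1]]
  s <- comp$seq
  ch <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), ch)[1L]
  res <- decombine_reads(s, comp$qual, comp$id, toy)
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$v_index, 1L)
  # 1 mismatching base over 40 inspected tag bases
  expect_equal(res$log$error_rate_lower_bound, 1 / 40)
})

test_that("error-rate lower bound is the pooled mismatch ratio", {
  hits <- data.frame(mm = c(rep(0L, 90), rep(1L, 10)), tag_len = 20L)
  expect_equal(error_rate_lower_bound(hits), 10 / 2000)
  expect_equal(error_rate_lower_bound(data.frame(mm = integer(),
                                                 tag_len = integer())),
               NA_real_)
})

test_that("serialized records have exactly 10 comma-separated fields and
           round-trip through the .n12 dialect", {
  sim <- toy_sim()
  res <- run_sim_pipeline(sim)
  d <- withr::local_tempdir()
  p <- file.path(d, "toy.n12")
  write_n12(res$dec$records, p)
  lines <- readLines(p)
  expect_true(all(lengths(strsplit(lines, ",", fixed = TRUE)) %in%
                    c(10L, 9L)))  # 9 splits when the insert field is empty
  expect_true(all(vapply(lines, function(l)
    nchar(gsub("[^,]", "", l)) == 9L, logical(1L))))
  back <- read_n12(p)
  expect_equal(as.data.frame(back), as.data.frame(res$dec$records))
})

test_that("chain is inferable from conventional file names", {
  expect_equal(infer_chain("donor1_alpha.fq.gz"), "alpha")
  expect_equal(infer_chain("/x/y/TRB_sample.fq"), "beta")
  expect_true(is.na(infer_chain("sample1.fq")))
})
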