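# Stage 1: rebuild composite reads from the three sequencer FASTQ files and
# split them into per-sample FASTQ files by dual index.
#
# The sequencer emits three synchronized files: R1 holds the V(D)J read with
# a 6-nt sample index at positions 6-12 (preceded by 6 random bases that
# exist only to give the instrument base diversity), R2 starts with the
# 30-base region covering the ligation spacers and the split UMI, and I1 is
# the 6-nt Illumina index read. A composite read is the concatenation
# UMI-region (30) + I1 hexamer (6) + R1 hexamer (6) + full R1.

#' Read and validate a demultiplexing sample sheet
#'
#' @param path CSV with columns `sample_name,index1,index2` and optionally
#'   `chain`. `index1` is matched against the I1 read, `index2` against the
#'   within-R1 hexamer.
#' @return data.table of validated rows.
#' @export
read_sample_sheet <- function(path) {
  s <- as.data.table(read.csv(path, stringsAsFactors = FALSE,
                              strip.white = TRUE))
  validate_sample_sheet(s)
}

validate_sample_sheet <- function(s) {
  s <- as.data.table(s)
  for (nm in c("sample_name", "index1", "index2"))
    if (!nm %in% names(s)) stop("sample sheet lacks column ", nm)
  if (!"chain" %in% names(s)) s[, chain := NA_character_]
  s[, `:=`(index1 = toupper(index1), index2 = toupper(index2))]
  if (any(nchar(s$index1) != 6L) || any(nchar(s$index2) != 6L))
    stop("sample sheet indices must be 6 nt")
  if (any(grepl("[^ACGT]", c(s$index1, s$index2))))
    stop("sample sheet indices must be ACGT only")
  if (any(!grepl("^[A-Za-z0-9._-]+$", s$sample_name)))
    stop("sample names must be filesystem-safe ([A-Za-z0-9._-])")
  if (anyDuplicated(s[, .(index1, index2)]))
    stop("duplicate (index1, index2) pairs in sample sheet")
  if (anyDuplicated(s$sample_name))
    stop("duplicate sample names in sample sheet")
  s[]
}

#' Rebuild composite reads from R1/R2/I1 FASTQ records
#'
#' @param r1,r2,i1 data.tables as returned by [read_fastq()], or file paths.
#'   The three inputs must be record-synchronized (same read IDs in the same
#'   order); a mismatch is a hard error naming the offending record.
#' @return data.table with one row per retained triple: `id`, `seq` (the
#'   30 + 6 + 6 + length(R1) composite), `qual`, plus the parsed slots
#'   `umi_region`, `umi_qual`, `i1_hex`, `r1_hex`. Records whose R2 is
#'   shorter than 30 nt or whose R1 is shorter than 12 nt are dropped and
#'   counted in the `dropped` attribute.
#' @export
compose_reads <- function(r1, r2, i1) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (is.character(i1)) i1 <- read_fastq(i1)
  if (nrow(r1) != nrow(r2) || nrow(r1) != nrow(i1))
    stop("R1/R2/I1 record counts differ (", nrow(r1), "/", nrow(r2), "/",
         nrow(i1), ")")
  if (nrow(r1) == 0L) {
    out <- data.table(id = character(), seq = character(),
                      qual = character(), umi_region = character(),
                      umi_qual = character(), i1_hex = character(),
                      r1_hex = character())
    setattr(out, "dropped", 0L)
    return(out)
  }
  key1 <- sub(" .*$", "", r1$id)
  key2 <- sub(" .*$", "", r2$id)
  key3 <- sub(" .*$", "", i1$id)
  bad <- which(key1 != key2 | key1 != key3)
  if (length(bad))
    stop("R1/R2/I1 are not record-synchronized at record ", bad[1L],
         " (", key1[bad[1L]], " / ", key2[bad[1L]], " / ", key3[bad[1L]], ")")
  ok <- nchar(r2$seq) >= 30L & nchar(r1$seq) >= 12L & nchar(i1$seq) >= 6L
  dropped <- sum(!ok)
  r1 <- r1[ok]; r2 <- r2[ok]; i1 <- i1[ok]
  umi_region <- substr(r2$seq, 1L, 30L)
  umi_qual <- substr(r2$qual, 1L, 30L)
  i1_hex <- substr(i1$seq, 1L, 6L)
  i1_hexq <- substr(i1$qual, 1L, 6L)
  # the within-R1 index sits immediately after the 6 random bases
  r1_hex <- substr(r1$seq, 7L, 12L)
  r1_hexq <- substr(r1$qual, 7L, 12L)
  out <- data.table(
    id = r1$id,
    seq = paste0(umi_region, i1_hex, r1_hex, r1$seq),
    qual = paste0(umi_qual, i1_hexq, r1_hexq, r1$qual),
    umi_region = umi_region, umi_qual = umi_qual,
    i1_hex = i1_hex, r1_hex = r1_hex
  )
  setattr(out, "dropped", dropped)
  out
}

#' Assign composite reads to samples by dual index
#'
#' Each read is assigned to the unique sample sheet row whose `index1`
#' matches the I1 hexamer and whose `index2` matches the within-R1 hexamer,
#' both within `max_mismatches` substitutions. Reads matching no row, or
#' more than one, go to `"undetermined"` (the latter counted as ambiguous).
#'
#' @param reads Composite reads from [compose_reads()].
#' @param sheet A validated sample sheet.
#' @param max_mismatches 0 or 1 mismatches tolerated per index.
#' @return `reads` with an added `sample` column, with attributes `counts`
#'   (named per-sample totals incl. undetermined) and `ambiguous`.
#' @export
demultiplex_reads <- function(reads, sheet, max_mismatches = 1L) {
  sheet <- validate_sample_sheet(sheet)
  if (!max_mismatches %in% c(0L, 1L))
    stop("max_mismatches must be 0 or 1")
  n <- nrow(reads)
  n_match <- integer(n)
  assigned <- rep(NA_integer_, n)
  for (srow in if (n == 0L) integer(0L) else seq_len(nrow(sheet))) {
    hit <- hamming_cpp(reads$i1_hex, sheet$index1[srow]) <= max_mismatches &
      hamming_cpp(reads$r1_hex, sheet$index2[srow]) <= max_mismatches
    n_match <- n_match + hit
    assigned[hit & is.na(assigned)] <- srow
  }
  ambiguous <- sum(n_match > 1L)
  sample <- if (n == 0L) character(0L) else
    ifelse(n_match == 1L, sheet$sample_name[assigned], "undetermined")
  out <- copy(reads)[, sample := sample]
  counts <- setNames(
    vapply(c(sheet$sample_name, "undetermined"),
           function(s) sum(sample == s), integer(1L)),
    c(sheet$sample_name, "undetermined")
  )
  setattr(out, "counts", counts)
  setattr(out, "ambiguous", ambiguous)
  out
}

#' Demultiplex R1/R2/I1 FASTQ files into per-sample FASTQ files
#'
#' Runs [compose_reads()] and [demultiplex_reads()] and writes one FASTQ per
#' sample (named `<sample_name>.fq.gz`) plus `undetermined.fq.gz`. Output
#' records carry the 30-base UMI region prepended to the full R1 read — the
#' input contract of [decombine_fastq()]; the index hexamers are consumed at
#' this stage. A plain-text log and a CSV twin of the per-sample counts are
#' written alongside.
#'
#' @param r1,r2,i1 FASTQ paths (gzip transparently supported).
#' @param sheet Sample sheet path or data.frame.
#' @param outdir Output directory.
#' @param max_mismatches Per-index mismatch tolerance (0 or 1).
#' @param compress Write gzipped FASTQ (default TRUE).
#' @return Invisibly, a list with `counts`, `ambiguous`, `dropped`, `total`,
#'   and `files`.
#' @export
demultiplex_fastq <- function(r1, r2, i1, sheet, outdir,
                              max_mismatches = 1L, compress = TRUE) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- validate_sample_sheet(sheet)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  composite <- compose_reads(r1, r2, i1)
  dropped <- attr(composite, "dropped")
  asg <- demultiplex_reads(composite, sheet, max_mismatches)
  ext <- if (compress) ".fq.gz" else ".fq"
  files <- character(0L)
  for (s in c(sheet$sample_name, "undetermined")) {
    sub <- asg[sample == s]
    path <- file.path(outdir, paste0(s, ext))
    out_seq <- paste0(sub$umi_region, substr(sub$seq, 43L, nchar(sub$seq)))
    out_qual <- paste0(sub$umi_qual, substr(sub$qual, 43L, nchar(sub$qual)))
    write_fastq(sub$id, out_seq, out_qual, path)
    files[s] <- path
  }
  counts <- attr(asg, "counts")
  log <- list(total = nrow(composite) + dropped, dropped = dropped,
              ambiguous = attr(asg, "ambiguous"), counts = counts,
              files = files)
  writeLines(c(
    paste0("reads_in: ", log$total),
    paste0("dropped_short: ", dropped),
    paste0("ambiguous: ", log$ambiguous),
    paste0(names(counts), ": ", counts)
  ), file.path(outdir, "demultiplex.log"))
  write.csv(data.frame(sample = names(counts), reads = as.integer(counts)),
            file.path(outdir, "demultiplex_counts.csv"), row.names = FALSE)
  invisible(log)
}
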