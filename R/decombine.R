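# Stage 2: identify rearranged TCRs by multi-pattern tag search and encode
# each read as a five-part identifier.
#
# Every germline gene carries a recognition tag (>= 16 nt, collision-free by
# the reference loader). A read is assigned when exactly one V gene tag and
# exactly one J gene tag are found (each with at most one mismatch) with the
# V hit upstream of the J hit. Deletions are then the smallest counts that
# make the remaining germline flanks match the read exactly, taking minimal
# V deletions first (the V-greedy canonical decomposition); the insert is
# whatever read sequence remains between the matched V end and J start.

#' Build the tag lookup table of a reference set
#'
#' One row per tag with its segment class, 0-based gene index, and the
#' germline context used for deletion counting (V suffix downstream of the
#' tag, J prefix upstream of it).
#'
#' @param ref A `tcr_reference`.
#' @return data.table used by [decombine_reads()].
#' @export
tag_table <- function(ref) {
  v <- ref$v_genes
  j <- ref$j_genes
  rbind(
    data.table(segment_class = "V", gene_idx = seq_len(nrow(v)) - 1L,
               tag = v$tag, tag_len = nchar(v$tag),
               context = substr(v$sequence, v$tag_offset + nchar(v$tag) + 1L,
                                nchar(v$sequence))),
    data.table(segment_class = "J", gene_idx = seq_len(nrow(j)) - 1L,
               tag = j$tag, tag_len = nchar(j$tag),
               context = substr(j$sequence, 1L, j$tag_offset))
  )
}

#' Find all tag occurrences in query sequences
#'
#' Reports every position at which any V or J tag of the reference matches
#' with at most `max_mm` substitutions.
#'
#' @param seqs Character vector of query sequences.
#' @param ref A `tcr_reference`.
#' @param max_mm Mismatch tolerance (default 1).
#' @return data.table with columns `read` (1-based query index),
#'   `segment_class`, `gene_idx` (0-based), `pos` (0-based match position),
#'   `mm`, `tag_len`.
#' @export
find_tag_hits <- function(seqs, ref, max_mm = 1L) {
  tt <- tag_table(ref)
  hits <- as.data.table(tag_scan_cpp(seqs, tt$tag, as.integer(max_mm)))
  hits[, `:=`(segment_class = tt$segment_class[tag],
              gene_idx = tt$gene_idx[tag], tag_len = tt$tag_len[tag])]
  hits[, tag := NULL]
  hits[]
}

#' Decombine reads into five-part identifiers
#'
#' Core assignment routine operating on composite-read sequences (30-base
#' UMI region followed by the full R1 read, the [demultiplex_fastq()] output
#' contract). The tag search runs on the R1 portion only.
#'
#' @param seq,qual,id Equal-length character vectors of sequences, quality
#'   strings and read identifiers.
#' @param ref A `tcr_reference`.
#' @param max_tag_mm Tag mismatch tolerance (default 1).
#' @return A list with `records` (one row per assigned read; the 10-field
#'   layout of [write_n12()]) and `log` (reads in/assigned, no-call counts
#'   by reason, and the per-base error-rate lower bound obtained from tag
#'   mismatches).
#' @export
decombine_reads <- function(seq, qual, id, ref, max_tag_mm = 1L) {
  stopifnot(length(seq) == length(qual), length(seq) == length(id))
  n <- length(seq)
  empty <- empty_n12()
  reasons <- c(too_short = 0L, no_v_tag = 0L, no_j_tag = 0L,
               multiple_v = 0L, multiple_j = 0L, order_violation = 0L,
               negative_insert = 0L)
  if (n == 0L) {
    return(list(records = empty,
                log = decombine_log(0L, 0L, reasons, NA_real_, 0L, 0L)))
  }
  umi_region <- substr(seq, 1L, 30L)
  umi_qual <- substr(qual, 1L, 30L)
  r1 <- substr(seq, 31L, nchar(seq))
  r1q <- substr(qual, 31L, nchar(qual))

  tt <- tag_table(ref)
  min_tag <- min(tt$tag_len)
  too_short <- nchar(seq) < 30L + min_tag
  reasons["too_short"] <- sum(too_short)
  idx_ok <- which(!too_short)

  hits <- find_tag_hits(r1[idx_ok], ref, max_tag_mm)
  hits[, read := idx_ok[read]]

  per_read <- hits[, .(
    nv = uniqueN(gene_idx[segment_class == "V"]),
    nj = uniqueN(gene_idx[segment_class == "J"])
  ), by = read]
  status <- merge(data.table(read = idx_ok), per_read, by = "read",
                  all.x = TRUE)
  status[is.na(nv), `:=`(nv = 0L, nj = 0L)]
  reasons["no_v_tag"] <- status[nv == 0L, .N]
  reasons["no_j_tag"] <- status[nv > 0L & nj == 0L, .N]
  reasons["multiple_v"] <- status[nv > 1L & nj >= 1L, .N]
  reasons["multiple_j"] <- status[nv == 1L & nj > 1L, .N]
  cand <- status[nv == 1L & nj == 1L, read]

  vhit <- hits[segment_class == "V" & read %in% cand]
  setorder(vhit, read, pos)
  vhit <- unique(vhit, by = "read")  # leftmost V hit
  jall <- hits[segment_class == "J" & read %in% cand]
  jall <- merge(jall,
                vhit[, .(read, vpos = pos, vtag_end = pos + tag_len)],
                by = "read")
  # rightmost J hit compatible with the V hit (J tag fully downstream of
  # the V tag); J overlapping the V tag leaves no room for a junction
  jcomp <- jall[pos >= vtag_end]
  setorder(jcomp, read, -pos)
  jcomp <- unique(jcomp, by = "read")
  bad_j <- jall[!read %in% jcomp$read]
  if (nrow(bad_j)) {
    per_bad <- bad_j[, .(maxpos = max(pos), vpos = vpos[1L]), by = read]
    reasons["negative_insert"] <- per_bad[maxpos >= vpos, .N]
    reasons["order_violation"] <- per_bad[maxpos < vpos, .N]
  }

  asg <- merge(vhit[, .(read, v_idx = gene_idx, vpos = pos,
                        vtag_end = pos + tag_len, vmm = mm,
                        vtag_len = tag_len)],
               jcomp[, .(read, j_idx = gene_idx, jpos = pos, jmm = mm,
                         jtag_len = tag_len)],
               by = "read")
  if (nrow(asg) == 0L) {
    return(list(records = empty,
                log = decombine_log(n, 0L, reasons, NA_real_, 0L, 0L)))
  }

  vt <- tt[segment_class == "V"]
  jt <- tt[segment_class == "J"]
  v_suffix <- vt$context[match(asg$v_idx, vt$gene_idx)]
  j_prefix <- jt$context[match(asg$j_idx, jt$gene_idx)]
  S <- nchar(v_suffix)
  P <- nchar(j_prefix)
  rr <- r1[asg$read]

  read_after <- substr(rr, asg$vtag_end + 1L, nchar(rr))
  lcp <- lcp_cpp(read_after, v_suffix)
  room <- asg$jpos - asg$vtag_end
  v_ext <- pmin(lcp, room)
  v_del <- S - v_ext
  v_end <- asg$vtag_end + v_ext
  between <- substr(rr, v_end + 1L, asg$jpos)
  j_ext <- lcs_cpp(between, j_prefix)
  j_del <- P - j_ext
  ins <- substr(rr, v_end + 1L, asg$jpos - j_ext)

  records <- data.table(
    v_index = asg$v_idx, j_index = asg$j_idx,
    v_deletions = v_del, j_deletions = j_del, insert = ins,
    read_id = id[asg$read],
    intertag = substr(rr, asg$vtag_end + 1L, asg$jpos),
    intertag_qual = substr(r1q[asg$read], asg$vtag_end + 1L, asg$jpos),
    umi_region = umi_region[asg$read], umi_qual = umi_qual[asg$read]
  )
  mm_total <- sum(asg$vmm) + sum(asg$jmm)
  bases_total <- sum(asg$vtag_len) + sum(asg$jtag_len)
  rate <- error_rate_lower_bound(
    data.table(mm = c(asg$vmm, asg$jmm),
               tag_len = c(asg$vtag_len, asg$jtag_len)))
  list(records = records,
       log = decombine_log(n, nrow(records), reasons, rate, mm_total,
                           bases_total))
}

decombine_log <- function(reads_in, assigned, reasons, rate, mm, bases) {
  list(reads_in = reads_in, assigned = assigned, no_call = reasons,
       error_rate_lower_bound = rate, tag_mismatches = mm,
       tag_bases = bases)
}

empty_n12 <- function() {
  data.table(v_index = integer(), j_index = integer(),
             v_deletions = integer(), j_deletions = integer(),
             insert = character(), read_id = character(),
             intertag = character(), intertag_qual = character(),
             umi_region = character(), umi_qual = character())
}

#' Lower bound on the per-base error rate from tag mismatches
#'
#' Accepted tag hits tolerate one substitution; counting mismatching tag
#' bases over all tag bases inspected gives a lower bound on the per-base
#' error rate around the TCR portion of the read (a lower bound because
#' two-error tags are rejected, not counted).
#'
#' @param hits data.frame with columns `mm` and `tag_len`, one row per
#'   accepted tag hit.
#' @return Mismatches per base, or `NA` when no hits were observed.
#' @export
error_rate_lower_bound <- function(hits) {
  if (NROW(hits) == 0L) return(NA_real_)
  sum(hits$mm) / sum(hits$tag_len)
}

#' Infer the TCR chain from a file name
#'
#' File names containing a chain word (`alpha`, `beta`, `gamma`, `delta`,
#' or the IMGT-style `TRA`/`TRB`/`TRG`/`TRD`) advertise their chain, which
#' lets downstream stages pick the matching reference without an explicit
#' argument.
#'
#' @param path File name or path.
#' @return Chain label, or `NA_character_` if none is recognizable.
#' @export
infer_chain <- function(path) {
  base <- tolower(basename(path))
  for (ch in c("alpha", "beta", "gamma", "delta")) {
    if (grepl(ch, base, fixed = TRUE)) return(ch)
  }
  up <- basename(path)
  map <- c(TRA = "alpha", TRB = "beta", TRG = "gamma", TRD = "delta")
  for (k in names(map)) if (grepl(k, up, fixed = TRUE)) return(map[[k]])
  NA_character_
}

#' Decombine a demultiplexed FASTQ file
#'
#' @param input FASTQ path (the [demultiplex_fastq()] output contract:
#'   30-base UMI region prepended to R1).
#' @param ref A `tcr_reference`.
#' @param out Optional output path for the `.n12` CSV; a sibling `.log`
#'   summary is written next to it.
#' @param max_tag_mm Tag mismatch tolerance.
#' @return A list with `records` and `log`, invisibly when `out` is given.
#' @export
decombine_fastq <- function(input, ref, out = NULL, max_tag_mm = 1L) {
  fq <- read_fastq(input)
  res <- decombine_reads(fq$seq, fq$qual, fq$id, ref, max_tag_mm)
  if (!is.null(out)) {
    write_n12(res$records, out)
    log_path <- paste0(tools::file_path_sans_ext(out), ".log")
    writeLines(c(
      paste0("reads_in: ", res$log$reads_in),
      paste0("assigned: ", res$log$assigned),
      paste0("no_call_", names(res$log$no_call), ": ", res$log$no_call),
      paste0("error_rate_lower_bound: ",
             format(res$log$error_rate_lower_bound, digits = 6))
    ), log_path)
    return(invisible(res))
  }
  res
}

#' Write / read the 10-field decombined record CSV
#'
#' The serialized form has exactly 10 comma-separated fields per record:
#' the five identifier fields, the read ID, the intertag sequence and its
#' qualities, and the 30-base UMI region and its qualities. No header line
#' is written (`.n12` dialect).
#'
#' @param records data.table from [decombine_reads()].
#' @param path Output path (conventionally `*.n12`).
#' @export
write_n12 <- function(records, path) {
  fwrite(records, path, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_n12
#' @export
read_n12 <- function(path) {
  if (file.size(path) == 0L) return(empty_n12())
  rec <- fread(path, header = FALSE, col.names = names(empty_n12()),
               colClasses = list(character = c(5L, 6L, 7L, 8L, 9L, 10L)))
  rec[is.na(insert), insert := ""]
  rec[is.na(intertag), intertag := ""]
  rec[]
}
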