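# Stage 4: reconstruct the rearranged nucleotide sequence from a five-part
# identifier, translate it in the frame anchored at the V gene's conserved
# cysteine codon, and extract the CDR3 (cysteine through the phenylalanine
# of the J gene's FGXG-style motif, both inclusive). Rearrangements with a
# frame shift, an in-frame stop at or before the J motif, or a missing
# motif are flagged non-productive.

#' Reconstruct the rearranged nucleotide sequence
#'
#' `V[0, len(V) - v_del)` + insert + `J[j_del, len(J))`. Vectorized over
#' identifier fields.
#'
#' @param v_index,j_index 0-based gene indices.
#' @param v_deletions,j_deletions Bases deleted from the V 3' end / J 5'
#'   end. Deletions may not consume the recognition tag (V) or exceed the
#'   tag offset (J).
#' @param insert Junctional insert sequence (possibly empty).
#' @param ref A `tcr_reference`.
#' @return Character vector of reconstructed sequences.
#' @export
reconstruct_sequence <- function(v_index, j_index, v_deletions, j_deletions,
                                 insert, ref) {
  v <- ref$v_genes
  j <- ref$j_genes
  if (any(v_index < 0L | v_index >= nrow(v)))
    stop("V index out of range")
  if (any(j_index < 0L | j_index >= nrow(j)))
    stop("J index out of range")
  vrow <- v_index + 1L
  jrow <- j_index + 1L
  v_max <- nchar(v$sequence[vrow]) - (v$tag_offset[vrow] +
                                        nchar(v$tag[vrow]))
  if (any(v_deletions < 0L | v_deletions > v_max))
    stop("V deletions exceed the deletable 3' region")
  if (any(j_deletions < 0L | j_deletions > j$tag_offset[jrow]))
    stop("J deletions exceed the deletable 5' region")
  paste0(
    substr(v$sequence[vrow], 1L, nchar(v$sequence[vrow]) - v_deletions),
    insert,
    substr(j$sequence[jrow], j_deletions + 1L, nchar(j$sequence[jrow]))
  )
}

#' Canonicalize five-part identifiers
#'
#' Deletion/insert decompositions are not unique when junction bases
#' coincide with germline sequence; the pipeline reports the V-greedy
#' canonical form (minimal V deletions first, then minimal J deletions).
#' This maps arbitrary valid identifiers to that form, so that identifiers
#' from different sources are comparable. The reconstructed nucleotide
#' sequence is unchanged.
#'
#' @inheritParams reconstruct_sequence
#' @return data.table of canonical identifier fields plus `id_key`.
#' @export
canonicalize_identifiers <- function(v_index, j_index, v_deletions,
                                     j_deletions, insert, ref) {
  rec <- reconstruct_sequence(v_index, j_index, v_deletions, j_deletions,
                              insert, ref)
  v <- ref$v_genes
  j <- ref$j_genes
  vrow <- v_index + 1L
  jrow <- j_index + 1L
  vtag_end <- v$tag_offset[vrow] + nchar(v$tag[vrow])
  v_suffix <- substr(v$sequence[vrow], vtag_end + 1L,
                     nchar(v$sequence[vrow]))
  S <- nchar(v_suffix)
  j_prefix <- substr(j$sequence[jrow], 1L, j$tag_offset[jrow])
  P <- nchar(j_prefix)
  jtag_pos <- (nchar(v$sequence[vrow]) - v_deletions) + nchar(insert) +
    (j$tag_offset[jrow] - j_deletions)
  read_after <- substr(rec, vtag_end + 1L, nchar(rec))
  v_ext <- pmin(lcp_cpp(read_after, v_suffix), jtag_pos - vtag_end)
  v_end <- vtag_end + v_ext
  between <- substr(rec, v_end + 1L, jtag_pos)
  j_ext <- lcs_cpp(between, j_prefix)
  out <- data.table(
    v_index = v_index, j_index = j_index,
    v_deletions = S - v_ext, j_deletions = P - j_ext,
    insert = substr(rec, v_end + 1L, jtag_pos - j_ext)
  )
  out[, id_key := identifier_key(v_index, j_index, v_deletions,
                                 j_deletions, insert)]
  out[]
}

#' Translate identifiers and extract CDR3 regions
#'
#' @inheritParams reconstruct_sequence
#' @return data.table with one row per identifier: `cdr3_aa` (empty when
#'   non-productive), `productive`, `fail_reason` (`none`, `out_of_frame`,
#'   `stop_codon`, or `missing_motif`).
#' @export
extract_cdr3 <- function(v_index, j_index, v_deletions, j_deletions, insert,
                         ref) {
  n <- length(v_index)
  rec <- reconstruct_sequence(v_index, j_index, v_deletions, j_deletions,
                              insert, ref)
  v <- ref$v_genes
  j <- ref$j_genes
  vrow <- v_index + 1L
  jrow <- j_index + 1L
  v_anchor <- v$motif_anchor[vrow]
  v_pat <- v$motif_pattern[vrow]
  j_anchor_gene <- j$motif_anchor[jrow]
  j_pat <- j$motif_pattern[jrow]
  v_kept <- nchar(v$sequence[vrow]) - v_deletions
  j_anchor <- v_kept + nchar(insert) + (j_anchor_gene - j_deletions)

  cdr3 <- character(n)
  reason <- rep("none", n)

  # structural motif loss: deletions consumed the anchor codon/motif span
  miss <- v_kept < v_anchor + 3L | j_deletions > j_anchor_gene |
    j_anchor + 3L * nchar(j_pat) > nchar(rec)
  reason[miss] <- "missing_motif"

  todo <- which(!miss)
  oof <- todo[(j_anchor[todo] - v_anchor[todo]) %% 3L != 0L]
  reason[oof] <- "out_of_frame"
  todo <- setdiff(todo, oof)

  if (length(todo)) {
    span <- substr(rec[todo], v_anchor[todo] + 1L, j_anchor[todo] + 3L)
    aa <- translate_dna(span)
    has_stop <- grepl("*", aa, fixed = TRUE)
    reason[todo[has_stop]] <- "stop_codon"
    keep <- todo[!has_stop]
    if (length(keep)) {
      aa_keep <- aa[!has_stop]
      jmotif_nt <- substr(rec[keep], j_anchor[keep] + 1L,
                          j_anchor[keep] + 3L * nchar(j_pat[keep]))
      jmotif_aa <- translate_dna(jmotif_nt)
      ok_v <- mapply(function(a, p) matches_motif(a, p),
                     aa_keep, v_pat[keep])
      ok_j <- mapply(function(a, p) matches_motif(a, p),
                     jmotif_aa, j_pat[keep])
      bad_motif <- !(ok_v & ok_j)
      reason[keep[bad_motif]] <- "missing_motif"
      good <- keep[!bad_motif]
      cdr3[good] <- aa_keep[!bad_motif]
    }
  }
  data.table(cdr3_aa = cdr3, productive = reason == "none",
             fail_reason = reason)
}

#' Translate a collapsed repertoire and tabulate CDR3s
#'
#' @param clones data.table with the five identifier fields and
#'   `abundance` ([collapse_records()] output or [read_freq()]).
#' @param ref A `tcr_reference`.
#' @param mode `"cdr3"` merges all identifiers encoding the same productive
#'   CDR3 and sums their frequencies; `"dcrcdr3"` keeps one row per
#'   identifier with its CDR3 appended.
#' @return A list with `table` (the requested output table) and `summary`
#'   (productive / non-productive clone and molecule counts plus per-gene
#'   usage frequencies over productive molecules).
#' @export
translate_repertoire <- function(clones, ref, mode = c("cdr3", "dcrcdr3")) {
  mode <- match.arg(mode)
  cl <- as.data.table(clones)
  if (!"abundance" %in% names(cl)) cl[, abundance := 1L]
  tr <- extract_cdr3(cl$v_index, cl$j_index, cl$v_deletions,
                     cl$j_deletions, cl$insert, ref)
  cl <- cbind(cl, tr)
  prod <- cl[productive == TRUE]
  summary <- list(
    n_clones = nrow(cl),
    n_productive_clones = nrow(prod),
    n_nonproductive_clones = nrow(cl) - nrow(prod),
    n_productive_molecules = sum(prod$abundance),
    n_nonproductive_molecules = sum(cl$abundance) - sum(prod$abundance),
    fail_reasons = table(cl$fail_reason[cl$productive == FALSE]),
    v_usage = prod[, .(frequency = sum(abundance)),
                   by = .(name = index_to_name(ref, "V", v_index))],
    j_usage = prod[, .(frequency = sum(abundance)),
                   by = .(name = index_to_name(ref, "J", j_index))]
  )
  tab <- if (mode == "cdr3") {
    out <- prod[, .(frequency = sum(abundance)), by = cdr3_aa]
    setorder(out, -frequency, cdr3_aa)
    out
  } else {
    out <- prod[, .(v_index, j_index, v_deletions, j_deletions, insert,
                    cdr3_aa, frequency = abundance)]
    setorder(out, -frequency, cdr3_aa)
    out
  }
  list(table = tab[], summary = summary, mode = mode)
}

#' Translate a `.freq` file into a `.cdr3` or `.dcrcdr3` file
#'
#' @param input Path to a 6-field `.freq` CSV.
#' @param ref A `tcr_reference`.
#' @param out Optional output path; headerless CSV in the dialect matching
#'   `mode` (`CDR3,frequency` or the five identifier fields + CDR3 +
#'   frequency). A sibling `.log` summarises productivity.
#' @param mode See [translate_repertoire()].
#' @return The [translate_repertoire()] result, invisibly when `out` is
#'   given.
#' @export
translate_file <- function(input, ref, out = NULL,
                           mode = c("cdr3", "dcrcdr3")) {
  mode <- match.arg(mode)
  res <- translate_repertoire(read_freq(input), ref, mode)
  if (!is.null(out)) {
    fwrite(res$table, out, col.names = FALSE, quote = FALSE)
    s <- res$summary
    writeLines(c(
      paste0("clones_in: ", s$n_clones),
      paste0("productive_clones: ", s$n_productive_clones),
      paste0("nonproductive_clones: ", s$n_nonproductive_clones),
      paste0("productive_molecules: ", s$n_productive_molecules),
      paste0("nonproductive_molecules: ", s$n_nonproductive_molecules)
    ), paste0(tools::file_path_sans_ext(out), ".cdr3.log"))
    return(invisible(res))
  }
  res
}
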