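# Stage 3: UMI-based error correction.
#
# Three passes over the decombined records:
#   (a) records are grouped by UMI and, within a group, distinct intertag
#       sequences are clustered greedily from the most read-abundant down,
#       absorbing any sequence whose per-base divergence from the current
#       reference is below a threshold — the most frequent variant is taken
#       to be the true sequence of that cDNA molecule;
#   (b) pass (a) repeats on the residue until the group is exhausted;
#   (c) where the same (or near-identical) TCR appears under several UMIs
#       that differ in at most a few bases, those UMIs are single-linkage
#       clustered and count as ONE founding molecule.
# A clonotype's abundance is the number of UMI clusters supporting its
# identifier; the reads absorbed per molecule measure PCR amplification.

#' Default collapse parameters
#'
#' @param max_seq_divergence Within-UMI clustering threshold: per-base
#'   divergence (mismatches over the longer length, one mismatch per
#'   missing base for unequal lengths) below which two intertag sequences
#'   are deemed the same molecule. Default 0.10.
#' @param max_umi_mismatches UMIs within this Hamming distance carrying the
#'   same TCR merge into one molecule. Default 2 (of 12).
#' @param max_tcr_mismatches Intertag mismatch budget for treating two
#'   records as the same TCR during UMI merging. Default 2.
#' @param min_umi_quality Minimum Phred score required on every one of the
#'   12 UMI bases. Default 20.
#' @param max_spacer_mismatches Spacer-sanity gate: each 8-base spacer slot
#'   may differ from the expected spacer by at most this many bases
#'   (ligation-artifact filter). Default 2.
#' @param spacer1,spacer2 Expected 8-nt spacer sequences of the ligation
#'   oligonucleotide.
#' @return Named list of parameters.
#' @export
collapse_params <- function(max_seq_divergence = 0.10,
                            max_umi_mismatches = 2L,
                            max_tcr_mismatches = 2L,
                            min_umi_quality = 20L,
                            max_spacer_mismatches = 2L,
                            spacer1 = default_spacers()[1L],
                            spacer2 = default_spacers()[2L]) {
  stopifnot(max_seq_divergence >= 0, max_seq_divergence < 1,
            nchar(spacer1) == 8L, nchar(spacer2) == 8L)
  list(max_seq_divergence = max_seq_divergence,
       max_umi_mismatches = as.integer(max_umi_mismatches),
       max_tcr_mismatches = as.integer(max_tcr_mismatches),
       min_umi_quality = as.integer(min_umi_quality),
       max_spacer_mismatches = as.integer(max_spacer_mismatches),
       spacer1 = spacer1, spacer2 = spacer2)
}

#' The package's default ligation-oligo spacer sequences
#'
#' Two fixed 8-mers separating the UMI halves in the 30-base region read at
#' the start of R2. Any oligo design can be substituted via
#' [collapse_params()] and [sim_config()].
#'
#' @return Character vector of length 2.
#' @export
default_spacers <- function() c("GTCGTGAT", "AGATCGGA")

#' Extract the 12-nt UMI from a 30-base UMI region
#'
#' The region layout is spacer1 (8) + 6 N + spacer2 (8) + 6 N (+ 2 bases of
#' transcript). The UMI is the concatenation of the two random hexamers.
#' Records fail the gate when any UMI base is below the quality threshold,
#' when either spacer slot diverges too far from the expected spacer
#' (mis-ligation), or when the region is shorter than 28 bases.
#'
#' @param umi_region,umi_qual Character vectors (sequence, Phred-33
#'   qualities).
#' @param params From [collapse_params()].
#' @return data.table with columns `umi`, `keep`, `reason`.
#' @export
extract_umi <- function(umi_region, umi_qual, params = collapse_params()) {
  n <- length(umi_region)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  len_ok <- nchar(umi_region) >= 28L & nchar(umi_qual) >= 28L
  keep[!len_ok] <- FALSE
  reason[!len_ok] <- "short_region"
  u1 <- substr(umi_region, 9L, 14L)
  u2 <- substr(umi_region, 23L, 28L)
  umi <- paste0(u1, u2)
  umi[!len_ok] <- NA_character_
  idx <- which(len_ok)
  if (length(idx)) {
    s1 <- substr(umi_region[idx], 1L, 8L)
    s2 <- substr(umi_region[idx], 15L, 22L)
    sp_bad <- hamming_cpp(s1, params$spacer1) > params$max_spacer_mismatches |
      hamming_cpp(s2, params$spacer2) > params$max_spacer_mismatches
    keep[idx[sp_bad]] <- FALSE
    reason[idx[sp_bad]] <- "spacer_mismatch"
    qs <- paste0(substr(umi_qual[idx], 9L, 14L),
                 substr(umi_qual[idx], 23L, 28L))
    minq <- vapply(phred_scores(qs), min, integer(1L))
    q_bad <- keep[idx] & minq < params$min_umi_quality
    keep[idx[q_bad]] <- FALSE
    reason[idx[q_bad]] <- "low_umi_quality"
  }
  data.table(umi = umi, keep = keep, reason = reason)
}

#' Greedy within-UMI clustering of intertag sequences
#'
#' Implements passes (a)-(b): distinct variants are ordered by descending
#' read count (ties broken toward the lexicographically smallest intertag
#' sequence, for determinism), the most common becomes the reference, every
#' remaining variant closer than `max_seq_divergence` is absorbed into it,
#' and the procedure recurses on the residue.
#'
#' @param variants data.table with columns `intertag`, `id_key` (serialized
#'   identifier) and `n_reads` — one row per distinct variant within one
#'   UMI group.
#' @param max_seq_divergence Per-base divergence threshold.
#' @return data.table with one row per cluster: reference `intertag`,
#'   `id_key`, and `n_reads` absorbed.
#' @export
collapse_within_umi <- function(variants, max_seq_divergence = 0.10) {
  v <- as.data.table(variants)
  if (nrow(v) == 1L)
    return(v[, .(intertag, id_key, n_reads)])
  setorder(v, -n_reads, intertag)
  out <- vector("list", nrow(v))
  k <- 0L
  while (nrow(v) > 0L) {
    ref_seq <- v$intertag[1L]
    div <- seq_divergence_cpp(v$intertag, ref_seq)
    absorb <- div < max_seq_divergence
    absorb[1L] <- TRUE
    k <- k + 1L
    out[[k]] <- data.table(intertag = ref_seq, id_key = v$id_key[1L],
                           n_reads = sum(v$n_reads[absorb]))
    v <- v[!absorb]
  }
  rbindlist(out[seq_len(k)])
}

#' Merge UMI clusters that stem from the same founding molecule
#'
#' Pass (c): entries whose TCRs are the same (identical identifier) or
#' near-identical (intertag mismatches, with length penalty, at most
#' `max_tcr_mismatches`) and whose UMIs lie within `max_umi_mismatches`
#' Hamming distance are single-linkage clustered; every connected component
#' counts as one molecule. The component's identifier is that of its most
#' read-supported member (ties toward the lexicographically smallest
#' identifier key).
#'
#' @param entries data.table with columns `umi`, `intertag`, `id_key`,
#'   `n_reads` (one row per within-UMI cluster).
#' @param max_umi_mismatches,max_tcr_mismatches Integer thresholds.
#' @return data.table with one row per molecule: `id_key`, `intertag`,
#'   `n_reads`, `n_umis` (UMIs merged into the cluster).
#' @export
merge_umis <- function(entries, max_umi_mismatches = 2L,
                       max_tcr_mismatches = 2L) {
  e <- as.data.table(entries)
  n <- nrow(e)
  if (n == 0L)
    return(data.table(id_key = character(), intertag = character(),
                      n_reads = integer(), n_umis = integer()))
  pairs <- as.data.table(near_pairs_cpp(e$umi, as.integer(max_umi_mismatches)))
  if (nrow(pairs)) {
    same_tcr <- e$id_key[pairs$i] == e$id_key[pairs$j] |
      seq_mismatches_cpp(e$intertag[pairs$i], e$intertag[pairs$j]) <=
        max_tcr_mismatches
    pairs <- pairs[same_tcr]
  }
  comp <- if (nrow(pairs)) {
    g <- igraph::graph_from_edgelist(as.matrix(pairs[, .(i, j)]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::components(g)$membership
  } else {
    seq_len(n)
  }
  e[, component := comp[seq_len(n)]]
  e[, {
    o <- order(-n_reads, id_key)
    .(id_key = id_key[o[1L]], intertag = intertag[o[1L]],
      n_reads = sum(n_reads), n_umis = uniqueN(umi))
  }, by = component][, component := NULL][]
}

#' Collapse decombined records into error-corrected clonotypes
#'
#' Runs the full correction: UMI extraction and quality/spacer gating,
#' within-UMI sequence clustering, and cross-UMI molecule merging. The
#' result is one row per clonotype with its molecule-count abundance.
#'
#' @param records data.table of decombined records ([decombine_reads()] /
#'   [read_n12()]).
#' @param params From [collapse_params()].
#' @return A list with `clones` (columns `v_index`, `j_index`,
#'   `v_deletions`, `j_deletions`, `insert`, `abundance`,
#'   `reads_absorbed`), `molecules` (one row per inferred molecule), and
#'   `log` (records in/rejected, UMI/molecule/clonotype counts, and the
#'   reads-per-molecule histogram that exposes PCR heterogeneity).
#' @export
collapse_records <- function(records, params = collapse_params()) {
  rec <- as.data.table(records)
  n_in <- nrow(rec)
  gate <- extract_umi(rec$umi_region, rec$umi_qual, params)
  rejected <- table(gate$reason[!gate$keep])
  rec <- rec[gate$keep]
  rec[, umi := gate$umi[gate$keep]]
  if (nrow(rec) == 0L) {
    return(list(clones = empty_freq(), molecules = data.table(),
                log = list(records_in = n_in, rejected = rejected,
                           retained = 0L, n_umis = 0L, n_molecules = 0L,
                           n_clonotypes = 0L,
                           reads_per_molecule = integer())))
  }
  rec[, id_key := identifier_key(v_index, j_index, v_deletions,
                                 j_deletions, insert)]
  variants <- rec[, .(n_reads = .N), by = .(umi, intertag, id_key)]
  # fast path: UMI groups with a single variant need no clustering
  nv <- variants[, .N, by = umi]
  single <- variants[umi %in% nv[N == 1L, umi]]
  multi <- variants[umi %in% nv[N > 1L, umi]]
  clustered <- if (nrow(multi)) {
    multi[, collapse_within_umi(.SD, params$max_seq_divergence),
          by = umi]
  } else {
    data.table(umi = character(), intertag = character(),
               id_key = character(), n_reads = integer())
  }
  entries <- rbind(single[, .(umi, intertag, id_key, n_reads)],
                   clustered[, .(umi, intertag, id_key, n_reads)])
  molecules <- merge_umis(entries, params$max_umi_mismatches,
                          params$max_tcr_mismatches)
  id_fields <- tstrsplit(molecules$id_key, ",", fixed = TRUE)
  if (length(id_fields) == 4L) id_fields[[5L]] <- rep("", nrow(molecules))
  molecules[, `:=`(v_index = as.integer(id_fields[[1L]]),
                   j_index = as.integer(id_fields[[2L]]),
                   v_deletions = as.integer(id_fields[[3L]]),
                   j_deletions = as.integer(id_fields[[4L]]),
                   insert = fifelse(is.na(id_fields[[5L]]), "",
                                    id_fields[[5L]]))]
  clones <- molecules[, .(abundance = .N, reads_absorbed = sum(n_reads)),
                      by = .(v_index, j_index, v_deletions, j_deletions,
                             insert)]
  setorder(clones, -abundance, v_index, j_index, v_deletions, j_deletions,
           insert)
  list(clones = clones[], molecules = molecules[],
       log = list(records_in = n_in, rejected = rejected,
                  retained = nrow(rec), n_umis = uniqueN(rec$umi),
                  n_molecules = nrow(molecules),
                  n_clonotypes = nrow(clones),
                  reads_per_molecule = table(molecules$n_reads)))
}

empty_freq <- function() {
  data.table(v_index = integer(), j_index = integer(),
             v_deletions = integer(), j_deletions = integer(),
             insert = character(), abundance = integer(),
             reads_absorbed = integer())
}

#' Collapse an `.n12` file into a `.freq` clonotype file
#'
#' @param input Path to a 10-field `.n12` CSV.
#' @param out Optional output path; the `.freq` dialect is the five
#'   identifier fields plus the abundance as a sixth field, no header. A
#'   sibling `.log` file summarises the run.
#' @param params From [collapse_params()].
#' @return The [collapse_records()] result, invisibly when `out` is given.
#' @export
collapse_file <- function(input, out = NULL, params = collapse_params()) {
  res <- collapse_records(read_n12(input), params)
  if (!is.null(out)) {
    write_freq(res$clones, out)
    log_path <- paste0(tools::file_path_sans_ext(out), ".collapse.log")
    rj <- res$log$rejected
    writeLines(c(
      paste0("records_in: ", res$log$records_in),
      paste0("retained: ", res$log$retained),
      if (length(rj)) paste0("rejected_", names(rj), ": ", as.integer(rj)),
      paste0("umis: ", res$log$n_umis),
      paste0("molecules: ", res$log$n_molecules),
      paste0("clonotypes: ", res$log$n_clonotypes),
      "reads_per_molecule_histogram:",
      paste0("  ", names(res$log$reads_per_molecule), ": ",
             as.integer(res$log$reads_per_molecule))
    ), log_path)
    return(invisible(res))
  }
  res
}

#' Write / read the 6-field clonotype CSV (`.freq` dialect)
#'
#' @param clones data.table with the five identifier fields and
#'   `abundance`.
#' @param path Output path.
#' @export
write_freq <- function(clones, path) {
  fwrite(clones[, .(v_index, j_index, v_deletions, j_deletions, insert,
                    abundance)],
         path, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_freq
#' @export
read_freq <- function(path) {
  if (file.size(path) == 0L) return(empty_freq()[, -"reads_absorbed"])
  cl <- fread(path, header = FALSE,
              col.names = c("v_index", "j_index", "v_deletions",
                            "j_deletions", "insert", "abundance"),
              colClasses = list(character = 5L))
  cl[is.na(insert), insert := ""]
  cl[]
}
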