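# Ground-truthed read simulator.
#
# Emulates the amplicon layout the pipeline expects:
#   R1 = 6 random bases | 6-nt sample index | constant-region stub |
#        rearrangement (V..insert..J) | random filler to r1_length
#   R2 = spacer1 (8) | UMI half 1 (6) | spacer2 (8) | UMI half 2 (6) |
#        random filler to r2_length
#   I1 = 6-nt Illumina index
# Clone sizes follow a configurable law (power law by default), each
# molecule gets its own 12-nt UMI, the per-molecule read count follows a
# lognormal law (the PCR-heterogeneity model), and uniform substitution
# errors are applied to all three reads.

#' Simulation configuration
#'
#' @param ref A `tcr_reference` supplying germline genes.
#' @param n_clones Number of distinct clonotypes to generate.
#' @param clone_size_law List: `list(type = "powerlaw", exponent, x_max)`,
#'   `list(type = "uniform", size)` (every clone the same molecule count),
#'   or `list(type = "explicit", sizes)`.
#' @param amplification Per-molecule read-count law:
#'   `list(type = "lognormal", mean, sdlog)` (counts are
#'   `max(1, round(rlnorm))` with `meanlog` set so the lognormal mean is
#'   `mean`) or `list(type = "constant", reads)`.
#' @param error_rate Per-base substitution probability applied to R1, R2
#'   and I1.
#' @param spacer1,spacer2 8-nt ligation spacers.
#' @param sample_index Length-2 character vector `(index1, index2)`: the I1
#'   index and the within-R1 index.
#' @param r1_length,r2_length Read lengths.
#' @param constant_stub Constant-region fragment placed 3' of the index in
#'   R1 (the end of the C gene the primers anneal to).
#' @param read_quality_phred,umi_quality_phred Constant Phred scores used
#'   for quality strings; setting `umi_quality_phred` lower degrades only
#'   the 12 UMI bases (for gating experiments).
#' @param seed Integer RNG seed (mandatory: every dataset is reproducible).
#' @return Named list of validated settings.
#' @export
sim_config <- function(ref,
                       n_clones = 100L,
                       clone_size_law = list(type = "powerlaw",
                                             exponent = 2, x_max = 1e4),
                       amplification = list(type = "lognormal",
                                            mean = 20, sdlog = 0.6),
                       error_rate = 0,
                       spacer1 = default_spacers()[1L],
                       spacer2 = default_spacers()[2L],
                       sample_index = c("ATCACG", "CGATGT"),
                       r1_length = 250L,
                       r2_length = 100L,
                       constant_stub = "CATCAGCAGGAGGCTTGT",
                       read_quality_phred = 35L,
                       umi_quality_phred = 35L,
                       seed = 1L) {
  stopifnot(inherits(ref, "tcr_reference"),
            error_rate >= 0, error_rate <= 1,
            nchar(spacer1) == 8L, nchar(spacer2) == 8L,
            length(sample_index) == 2L, all(nchar(sample_index) == 6L),
            r2_length >= 28L, !is.null(seed))
  list(ref = ref, n_clones = as.integer(n_clones),
       clone_size_law = clone_size_law, amplification = amplification,
       error_rate = error_rate, spacer1 = spacer1, spacer2 = spacer2,
       sample_index = toupper(sample_index),
       r1_length = as.integer(r1_length),
       r2_length = as.integer(r2_length),
       constant_stub = toupper(constant_stub),
       read_quality_phred = as.integer(read_quality_phred),
       umi_quality_phred = as.integer(umi_quality_phred),
       seed = as.integer(seed))
}

draw_clone_sizes <- function(law, n_clones) {
  switch(law$type,
    powerlaw = rpowerlaw(n_clones, law$exponent, 1L,
                         as.integer(law$x_max %||% 1e4)),
    uniform = rep(as.integer(law$size %||% 1L), n_clones),
    explicit = {
      if (length(law$sizes) != n_clones)
        stop("explicit clone-size list length != n_clones")
      as.integer(law$sizes)
    },
    stop("unknown clone size law: ", law$type)
  )
}

draw_read_counts <- function(law, n_molecules) {
  switch(law$type,
    lognormal = {
      sdlog <- law$sdlog %||% 0.6
      meanlog <- log(law$mean) - sdlog^2 / 2
      pmax(1L, as.integer(round(rlnorm(n_molecules, meanlog, sdlog))))
    },
    constant = rep(as.integer(law$reads %||% 1L), n_molecules),
    stop("unknown amplification law: ", law$type)
  )
}

# Truncated-geometric helper (mean before truncation `mean`, cap `cap`).
rtgeom <- function(n, mean, cap) {
  pmin(rgeom(n, 1 / (mean + 1)), cap)
}

draw_identifiers <- function(ref, n, max_rearr_len) {
  v <- ref$v_genes
  j <- ref$j_genes
  v_max <- nchar(v$sequence) - (v$tag_offset + nchar(v$tag))
  out <- NULL
  redrawn <- 0L
  while (is.null(out) || nrow(out) < n) {
    need <- n - if (is.null(out)) 0L else nrow(out)
    m <- need + ceiling(need / 2) + 5L
    vi <- sample.int(nrow(v), m, replace = TRUE) - 1L
    ji <- sample.int(nrow(j), m, replace = TRUE) - 1L
    vd <- pmin(rtgeom(m, 3, 10L), v_max[vi + 1L])
    jd <- pmin(rtgeom(m, 3, 8L), j$tag_offset[ji + 1L])
    ilen <- rtgeom(m, 6, 20L)
    ins <- character(m)
    for (L in unique(ilen)) {
      sel <- ilen == L
      ins[sel] <- random_dna(sum(sel), L)
    }
    # canonical (V-greedy) form so that ground truth matches pipeline output
    cand <- canonicalize_identifiers(vi, ji, vd, jd, ins, ref)
    rearr_len <- nchar(v$sequence[vi + 1L]) - vd + nchar(ins) +
      nchar(j$sequence[ji + 1L]) - jd
    ok <- rearr_len <= max_rearr_len
    redrawn <- redrawn + sum(!ok)
    cand <- cand[ok]
    out <- unique(rbind(out, cand), by = "id_key")
  }
  out <- out[seq_len(n)]
  setattr(out, "redrawn", redrawn)
  out
}

#' Simulate a ground-truthed repertoire as R1/R2/I1 FASTQ triples
#'
#' @param cfg From [sim_config()].
#' @param dir Optional output directory; when given, gzipped
#'   `<prefix>_R1/_R2/_I1.fq.gz`, ground-truth CSVs and the echoed
#'   configuration JSON are written there.
#' @param prefix File name prefix (include a chain word such as `"beta"` to
#'   enable chain auto-detection downstream).
#' @param fixed_identifiers Optional data.table of identifier fields; its
#'   rows replace the last drawn clones (used to plant known clones such as
#'   spike-ins).
#' @return A list with `truth_clones` (identifier fields + `molecules`),
#'   `truth_molecules` (per-molecule UMI and read count),
#'   `reads` (in-memory R1/R2/I1 data.tables), `files` (when `dir` given),
#'   `umi_collisions` and `clones_redrawn`.
#' @export
simulate_repertoire <- function(cfg, dir = NULL, prefix = "sim_beta",
                                fixed_identifiers = NULL) {
  set.seed(cfg$seed)
  ref <- cfg$ref
  sizes <- draw_clone_sizes(cfg$clone_size_law, cfg$n_clones)
  overhead <- 12L + nchar(cfg$constant_stub)
  clones <- draw_identifiers(ref, cfg$n_clones,
                             cfg$r1_length - overhead)
  if (!is.null(fixed_identifiers)) {
    fx0 <- as.data.table(fixed_identifiers)
    fx <- canonicalize_identifiers(as.integer(fx0$v_index),
                                   as.integer(fx0$j_index),
                                   as.integer(fx0$v_deletions),
                                   as.integer(fx0$j_deletions),
                                   as.character(fx0$insert), ref)
    redrawn <- attr(clones, "redrawn")
    keep <- clones[seq_len(cfg$n_clones - nrow(fx))]
    if (any(fx$id_key %in% keep$id_key))
      stop("fixed identifier collides with a drawn background clone")
    clones <- rbind(keep, fx)
    setattr(clones, "redrawn", redrawn)
  }
  clones[, molecules := sizes]
  rearr <- reconstruct_sequence(clones$v_index, clones$j_index,
                                clones$v_deletions, clones$j_deletions,
                                clones$insert, ref)

  n_mol <- sum(sizes)
  mol_clone <- rep(seq_len(cfg$n_clones), sizes)
  umis <- random_dna(n_mol, 12L)
  umi_collisions <- sum(duplicated(umis))
  reads_per_mol <- draw_read_counts(cfg$amplification, n_mol)

  n_reads <- sum(reads_per_mol)
  read_mol <- rep(seq_len(n_mol), reads_per_mol)
  read_clone <- mol_clone[read_mol]

  # R1: 6 random | index2 | constant stub | rearrangement | random filler
  rand6 <- random_dna(n_reads, 6L)
  rearr_read <- rearr[read_clone]
  fill_len <- cfg$r1_length - overhead - nchar(rearr_read)
  filler <- character(n_reads)
  for (L in unique(fill_len)) {
    sel <- fill_len == L
    filler[sel] <- random_dna(sum(sel), L)
  }
  r1_seq <- paste0(rand6, cfg$sample_index[2L], cfg$constant_stub,
                   rearr_read, filler)
  # R2: spacer1 | umi[1:6] | spacer2 | umi[7:12] | filler
  u <- umis[read_mol]
  r2_seq <- paste0(cfg$spacer1, substr(u, 1L, 6L), cfg$spacer2,
                   substr(u, 7L, 12L),
                   random_dna(n_reads, cfg$r2_length - 28L))
  i1_seq <- rep(cfg$sample_index[1L], n_reads)

  if (cfg$error_rate > 0) {
    r1_seq <- as.character(mutate_seqs_cpp(r1_seq, cfg$error_rate))
    r2_seq <- as.character(mutate_seqs_cpp(r2_seq, cfg$error_rate))
    i1_seq <- as.character(mutate_seqs_cpp(i1_seq, cfg$error_rate))
  }

  qc <- rawToChar(as.raw(33L + cfg$read_quality_phred))
  qu <- rawToChar(as.raw(33L + cfg$umi_quality_phred))
  r1_qual <- strrep(qc, cfg$r1_length)
  r2_qual <- if (cfg$umi_quality_phred == cfg$read_quality_phred) {
    strrep(qc, cfg$r2_length)
  } else {
    paste0(strrep(qc, 8L), strrep(qu, 6L), strrep(qc, 8L), strrep(qu, 6L),
           strrep(qc, cfg$r2_length - 28L))
  }
  i1_qual <- strrep(qc, 6L)

  ids <- paste0("sim:", read_mol, ":", sequence(reads_per_mol))
  reads <- list(
    r1 = data.table(id = ids, seq = r1_seq, qual = r1_qual),
    r2 = data.table(id = ids, seq = r2_seq, qual = r2_qual),
    i1 = data.table(id = ids, seq = i1_seq, qual = i1_qual)
  )
  truth_molecules <- data.table(
    molecule = seq_len(n_mol), clone = mol_clone, umi = umis,
    reads_emitted = reads_per_mol
  )
  out <- list(truth_clones = clones[], truth_molecules = truth_molecules,
              reads = reads, files = NULL,
              umi_collisions = umi_collisions,
              clones_redrawn = attr(clones, "redrawn") %||% 0L)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(dir, paste0(prefix, c("_R1", "_R2", "_I1"),
                                   ".fq.gz"))
    write_fastq(ids, r1_seq, r1_qual, files[1L])
    write_fastq(ids, r2_seq, r2_qual, files[2L])
    write_fastq(ids, i1_seq, i1_qual, files[3L])
    fwrite(clones, file.path(dir, paste0(prefix, "_truth_clones.csv")))
    fwrite(truth_molecules,
           file.path(dir, paste0(prefix, "_truth_molecules.csv")))
    cfg_echo <- cfg[setdiff(names(cfg), "ref")]
    jsonlite::write_json(cfg_echo,
                         file.path(dir, paste0(prefix, "_config.json")),
                         auto_unbox = TRUE, pretty = TRUE)
    out$files <- setNames(files, c("r1", "r2", "i1"))
  }
  out
}

#' Simulate spike-in dilution series
#'
#' Mixes a known clone into a background repertoire at a series of
#' molecule ratios — the in-silico analogue of spiking a sequenced T cell
#' clone into PBMC at known cell numbers to calibrate quantitative
#' recovery.
#'
#' @param cfg From [sim_config()]; its clone-size law generates the
#'   background.
#' @param background_molecules Total background molecule count per dataset.
#' @param spike_identifier List with `v_index`, `j_index`, `v_deletions`,
#'   `j_deletions`, `insert` naming the spiked clone.
#' @param ratios Spike:background molecule ratios in `(0, 1]`.
#' @param dir Optional output directory (one subdirectory per ratio).
#' @return List of per-ratio results: the [simulate_repertoire()] output
#'   plus `ratio`, `spike_molecules` and `spike_key`.
#' @export
simulate_spikein <- function(cfg, background_molecules, spike_identifier,
                             ratios, dir = NULL) {
  stopifnot(all(ratios > 0), all(ratios <= 1))
  spike_key <- identifier_key(spike_identifier$v_index,
                              spike_identifier$j_index,
                              spike_identifier$v_deletions,
                              spike_identifier$j_deletions,
                              spike_identifier$insert)
  out <- vector("list", length(ratios))
  for (k in seq_along(ratios)) {
    seed_k <- cfg$seed + k
    set.seed(seed_k)
    # background clone sizes accumulated to the requested molecule total
    sizes <- integer(0L)
    while (sum(sizes) < background_molecules) {
      sizes <- c(sizes, draw_clone_sizes(cfg$clone_size_law,
                                         max(cfg$n_clones, 100L)))
    }
    cum <- cumsum(sizes)
    n_bg <- which(cum >= background_molecules)[1L]
    sizes <- sizes[seq_len(n_bg)]
    sizes[n_bg] <- sizes[n_bg] - (cum[n_bg] - background_molecules)
    if (sizes[n_bg] == 0L) {
      sizes <- sizes[-n_bg]
      n_bg <- n_bg - 1L
    }
    spike_molecules <- max(1L, as.integer(round(ratios[k] *
                                                  background_molecules)))
    cfg_k <- cfg
    cfg_k$seed <- seed_k
    cfg_k$n_clones <- n_bg + 1L
    cfg_k$clone_size_law <- list(type = "explicit",
                                 sizes = c(sizes, spike_molecules))
    sim <- simulate_repertoire(
      cfg_k,
      dir = if (is.null(dir)) NULL else
        file.path(dir, sprintf("ratio_%g", ratios[k])),
      prefix = "spike_beta",
      fixed_identifiers = as.data.table(spike_identifier)
    )
    out[[k]] <- list(sim = sim, ratio = ratios[k],
                     spike_molecules = spike_molecules,
                     spike_key = spike_key, seed = seed_k)
  }
  out
}

#' UMI saturation as a function of read depth
#'
#' Subsamples decombined records to each requested depth (nested draws, so
#' deeper subsamples contain shallower ones), collapses them, and reports
#' the number of distinct molecules recovered.
#'
#' @param records Decombined records ([decombine_reads()] output).
#' @param depths Ascending read depths.
#' @param params [collapse_params()].
#' @return data.table with columns `depth`, `molecules`, `capped` (TRUE
#'   where the requested depth exceeded the available reads and was
#'   truncated).
#' @export
saturation_curve <- function(records, depths, params = collapse_params()) {
  stopifnot(!is.unsorted(depths))
  rec <- as.data.table(records)
  perm <- sample.int(nrow(rec))
  out <- data.table(depth = as.integer(depths), molecules = NA_integer_,
                    capped = depths > nrow(rec))
  for (k in seq_along(depths)) {
    d <- min(depths[k], nrow(rec))
    res <- collapse_records(rec[perm[seq_len(d)]], params)
    out$molecules[k] <- res$log$n_molecules
  }
  out[]
}
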