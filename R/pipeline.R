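# Orchestrates demultiplex -> decombine -> collapse -> CDR3 translation
# (plus optional repertoire statistics) for every sample of a run, from a
# single serializable configuration.

#' Build a pipeline configuration
#'
#' @param r1,r2,i1 Paths to the three sequencer FASTQ files.
#' @param sample_sheet Path to the demultiplexing sample sheet CSV.
#' @param reference Path to a reference manifest JSON
#'   ([write_reference_set()]).
#' @param outdir Output directory.
#' @param chain Chain label; when `NULL` it must be inferable from each
#'   sample name (a chain word such as "alpha" in the name).
#' @param demultiplex,decombine,collapse,cdr3 Per-stage parameter lists
#'   (see the stage functions for available settings).
#' @param stats Optional list enabling repertoire statistics:
#'   `list(subsample_to = <molecules or NULL>)`.
#' @param seed Seed for the statistics subsampling draws.
#' @return Validated configuration list of class `umitcr_config`.
#' @export
pipeline_config <- function(r1, r2, i1, sample_sheet, reference, outdir,
                            chain = NULL,
                            demultiplex = list(max_mismatches = 1L),
                            decombine = list(max_tag_mm = 1L),
                            collapse = list(),
                            cdr3 = list(mode = "cdr3"),
                            stats = NULL,
                            seed = 1L) {
  cfg <- list(r1 = r1, r2 = r2, i1 = i1, sample_sheet = sample_sheet,
              reference = reference, outdir = outdir, chain = chain,
              demultiplex = demultiplex, decombine = decombine,
              collapse = collapse, cdr3 = cdr3, stats = stats,
              seed = as.integer(seed))
  class(cfg) <- "umitcr_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A `umitcr_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[intersect(names(x),
                                       names(formals(pipeline_config)))])
}

#' Run the full pipeline
#'
#' Executes demultiplexing, then per sample: tag assignment, UMI collapse
#' and CDR3 translation, writing every intermediate file (`.fq.gz`, `.n12`,
#' `.freq`, `.cdr3`/`.dcrcdr3`) and a combined JSON log to the output
#' directory. Stage parameters and file dialects are identical to running
#' the stage functions by hand, so manual and orchestrated runs produce
#' byte-identical intermediates.
#'
#' @param cfg A `umitcr_config` or path to its JSON form.
#' @return Invisibly, a list with per-sample results (`clones`, `cdr3`,
#'   stage logs) and the demultiplexing log.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  for (p in c(cfg$r1, cfg$r2, cfg$i1, cfg$sample_sheet))
    if (!file.exists(p)) stop("input not found: ", p)
  if (!file.exists(cfg$reference))
    stop("reference manifest not found: ", cfg$reference)
  ref <- load_reference_manifest(cfg$reference)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  # every sample must have a resolvable chain before any work starts
  chains <- cfg$chain %||% NA_character_
  sample_chain <- vapply(seq_len(nrow(sheet)), function(i) {
    ch <- sheet$chain[i]
    if (is.na(ch) || !nzchar(ch)) ch <- chains
    if (is.na(ch)) ch <- infer_chain(sheet$sample_name[i])
    ch
  }, character(1L))
  if (anyNA(sample_chain))
    stop("chain not specified and not inferable from sample name(s): ",
         paste(sheet$sample_name[is.na(sample_chain)], collapse = ", "))

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  dmx <- do.call(demultiplex_fastq,
                 c(list(r1 = cfg$r1, r2 = cfg$r2, i1 = cfg$i1,
                        sheet = sheet, outdir = cfg$outdir),
                   cfg$demultiplex))
  results <- list()
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$sample_name[i]
    fq <- dmx$files[[s]]
    n12 <- file.path(cfg$outdir, paste0(s, ".n12"))
    dec <- do.call(decombine_fastq,
                   c(list(input = fq, ref = ref, out = n12),
                     cfg$decombine))
    freq <- file.path(cfg$outdir, paste0(s, ".freq"))
    col_params <- do.call(collapse_params, cfg$collapse)
    col <- collapse_file(n12, out = freq, params = col_params)
    mode <- cfg$cdr3$mode %||% "cdr3"
    cdr3_out <- file.path(cfg$outdir,
                          paste0(s, if (mode == "cdr3") ".cdr3"
                                 else ".dcrcdr3"))
    trl <- translate_file(freq, ref, out = cdr3_out, mode = mode)
    res <- list(sample = s, chain = sample_chain[i],
                clones = col$clones, cdr3 = trl$table,
                logs = list(decombine = dec$log, collapse = col$log,
                            cdr3 = trl$summary))
    if (!is.null(cfg$stats)) {
      sizes <- col$clones$abundance
      if (length(sizes)) {
        sub_to <- cfg$stats$subsample_to
        if (!is.null(sub_to) && sub_to <= sum(sizes)) {
          sizes <- subsample_repertoire(sizes, sub_to,
                                        seed = cfg$seed + i)
        }
        res$stats <- list(
          n_clonotypes = length(sizes),
          n_molecules = sum(sizes),
          gini = gini_index(sizes),
          shannon = shannon_entropy(sizes),
          inverse_simpson = inverse_simpson(sizes),
          power_law = tryCatch(fit_power_law(sizes),
                               error = function(e) NULL)
        )
      }
    }
    results[[s]] <- res
  }
  combined <- list(
    demultiplex = dmx[c("total", "dropped", "ambiguous")],
    samples = lapply(results, function(r)
      list(chain = r$chain,
           reads_in = r$logs$decombine$reads_in,
           assigned = r$logs$decombine$assigned,
           molecules = r$logs$collapse$n_molecules,
           clonotypes = r$logs$collapse$n_clonotypes,
           productive_clones = r$logs$cdr3$n_productive_clones))
  )
  jsonlite::write_json(combined, file.path(cfg$outdir, "pipeline_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg_echo <- cfg
  class(cfg_echo) <- NULL
  cfg_echo$stats <- cfg$stats %||% NA
  jsonlite::write_json(cfg_echo,
                       file.path(cfg$outdir, "pipeline_config_used.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(list(demultiplex = dmx, samples = results))
}
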