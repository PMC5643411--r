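library(data.table)

toy <- toy_reference()

# A small simulated dataset shared by several tests.
toy_sim <- function(n_clones = 20L, sizes = NULL, reads = 2L,
                    error_rate = 0, seed = 11L, ...) {
  law <- if (is.null(sizes)) list(type = "uniform", size = 3L)
         else list(type = "explicit", sizes = sizes)
  cfg <- sim_config(toy, n_clones = n_clones, clone_size_law = law,
                    amplification = list(type = "constant", reads = reads),
                    error_rate = error_rate, seed = seed, ...)
  simulate_repertoire(cfg)
}

# Turn in-memory simulated reads into the demultiplexed-FASTQ contract
# (30-base UMI region prepended to the full R1).
sim_to_decombine_input <- function(sim) {
  list(seq = paste0(substr(sim$reads$r2$seq, 1L, 30L), sim$reads$r1$seq),
       qual = paste0(substr(sim$reads$r2$qual, 1L, 30L),
                     sim$reads$r1$qual),
       id = sim$reads$r1$id)
}

run_sim_pipeline <- function(sim, params = collapse_params()) {
  inp <- sim_to_decombine_input(sim)
  dec <- decombine_reads(inp$seq, inp$qual, inp$id, toy)
  col <- collapse_records(dec$records, params)
  list(dec = dec, col = col)
}

truth_clone_table <- function(sim) {
  t <- sim$truth_clones[, .(v_index, j_index, v_deletions, j_deletions,
                            insert, abundance = as.integer(molecules))]
  setkey(t, v_index, j_index, v_deletions, j_deletions, insert)
  t[]
}

recovered_clone_table <- function(col) {
  g <- col$clones[, .(v_index, j_index, v_deletions, j_deletions, insert,
                      abundance = as.integer(abundance))]
  setkey(g, v_index, j_index, v_deletions, j_deletions, insert)
  g[]
}

# Build one synthetic composite read (30-base UMI region + R1) for a given
# identifier, with full control over errors in tags/junction.
make_composite <- function(v_index, j_index, v_deletions, j_deletions,
                           insert, umi = "AAAAAACCCCCC",
                           stub = "CATCAGCAGGAGGCTTGT", ref = toy,
                           phred = 35L) {
  sp <- default_spacers()
  umi_region <- paste0(sp[1L], substr(umi, 1L, 6L), sp[2L],
                       substr(umi, 7L, 12L), "GG")
  rearr <- reconstruct_sequence(v_index, j_index, v_deletions, j_deletions,
                                insert, ref)
  r1 <- paste0("ACGTAC", "CGATGT", stub, rearr)
  seq <- paste0(umi_region, r1)
  q <- strrep(rawToChar(as.raw(33L + phred)), nchar(seq))
  list(seq = seq, qual = q, id = "synthetic:1")
}
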