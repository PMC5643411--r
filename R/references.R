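# Germline V/J reference sets: sequences, recognition tags, CDR3 motif
# anchors. Every downstream stage (tag assignment, reconstruction, CDR3
# extraction) is defined relative to a loaded reference set, and the integer
# V/J indices of the five-part identifier are positions in its load order.
#
# All coordinates are 0-based, half-open.

#' Construct a validated germline reference set
#'
#' A reference set bundles, for one TCR chain, the germline V and J gene
#' sequences together with the recognition tag and CDR3 motif anchor of each
#' gene. The integer V index `i` of a five-part identifier refers to the
#' `i`-th V gene in load order (0-based), and likewise for J.
#'
#' @param v_genes,j_genes data.frames with columns `name`, `sequence`,
#'   `tag`, `tag_offset` (0-based position of the tag within the sequence),
#'   `motif_anchor` (0-based position of the first base of the conserved
#'   CDR3 cysteine codon for V genes, or of the FGXG phenylalanine codon for
#'   J genes) and `motif_pattern` (amino-acid pattern anchored there; `X`
#'   is a wildcard).
#' @param chain Chain label, one of `"alpha"`, `"beta"`, `"gamma"`,
#'   `"delta"`.
#' @param species Free-text species label.
#' @return An object of class `tcr_reference`.
#' @export
reference_set <- function(v_genes, j_genes, chain = "beta",
                          species = "synthetic") {
  chain <- match.arg(chain, c("alpha", "beta", "gamma", "delta"))
  v <- validate_gene_table(as.data.table(v_genes), "V")
  j <- validate_gene_table(as.data.table(j_genes), "J")
  ref <- structure(
    list(chain = chain, species = species, v_genes = v, j_genes = j),
    class = "tcr_reference"
  )
  ref
}

validate_gene_table <- function(g, segment_class) {
  need <- c("name", "sequence", "tag", "tag_offset", "motif_anchor",
            "motif_pattern")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols))
    stop("reference ", segment_class, " table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  g <- g[, need, with = FALSE]
  g[, `:=`(name = as.character(name), sequence = toupper(sequence),
           tag = toupper(tag), tag_offset = as.integer(tag_offset),
           motif_anchor = as.integer(motif_anchor),
           motif_pattern = toupper(motif_pattern))]
  if (anyDuplicated(g$name))
    stop("duplicate ", segment_class, " gene names: ",
         paste(unique(g$name[duplicated(g$name)]), collapse = ", "))
  for (r in seq_len(nrow(g))) {
    nm <- g$name[r]
    seq <- g$sequence[r]; tag <- g$tag[r]; off <- g$tag_offset[r]
    if (grepl("[^ACGT]", seq))
      stop("gene ", nm, ": sequence contains non-ACGT characters")
    if (nchar(tag) < 16L)
      stop("gene ", nm, ": tag shorter than 16 nt cannot guarantee ",
           "unambiguous recognition")
    if (off < 0L || off + nchar(tag) > nchar(seq) ||
        substr(seq, off + 1L, off + nchar(tag)) != tag)
      stop("gene ", nm, ": tag is not a substring of its sequence at ",
           "offset ", off)
    anc <- g$motif_anchor[r]
    if (anc < 0L || anc + 3L > nchar(seq))
      stop("gene ", nm, ": motif anchor ", anc, " out of range")
    aa <- translate_dna(substr(seq, anc + 1L, anc + 3L))
    want <- substr(g$motif_pattern[r], 1L, 1L)
    if (want != "X" && aa != want)
      stop("gene ", nm, ": anchor codon translates to ", aa,
           " but motif pattern expects ", want)
  }
  # pairwise tag uniqueness: identical tags, or equal-length tags within
  # Hamming distance 1, would make 1-mismatch matching ambiguous
  tg <- g$tag
  if (length(tg) > 1L) {
    for (a in seq_len(length(tg) - 1L)) {
      for (b in seq((a + 1L), length(tg))) {
        if (nchar(tg[a]) != nchar(tg[b])) next
        d <- hamming_cpp(tg[a], tg[b])
        if (d <= 1L)
          stop("tags of genes ", g$name[a], " and ", g$name[b],
               " collide (Hamming distance ", d, " <= 1)")
      }
    }
  }
  g[]
}

#' @export
print.tcr_reference <- function(x, ...) {
  cat("TCR germline reference set (", x$chain, ", ", x$species, ")\n",
      sep = "")
  cat("  V genes:", nrow(x$v_genes), " J genes:", nrow(x$j_genes), "\n")
  invisible(x)
}

#' Load a reference set from FASTA, tag, and translate files
#'
#' The three files must describe exactly the same set of gene names. FASTA
#' order defines the integer indices used by the five-part identifier.
#'
#' @param fasta_path FASTA of germline sequences; headers are gene names.
#' @param tag_path CSV with columns `tag_sequence,tag_offset,gene_name`
#'   (offset 0-based).
#' @param translate_path CSV with columns
#'   `gene_name,motif_anchor,motif_pattern` (anchor 0-based).
#' @param chain Chain label.
#' @param species Species label.
#' @return A `tcr_reference`. V genes are the FASTA records whose tag entry
#'   marks them `V` via the gene class column, see Details.
#' @details Gene class is encoded in the gene name suffix-free way: the tag
#'   CSV carries an extra optional column `segment_class` (`V` or `J`); when
#'   absent, names containing `"V"` before any digit are V genes and names
#'   containing `"J"` are J genes.
#' @export
load_reference_set <- function(fasta_path, tag_path, translate_path,
                               chain = "beta", species = "synthetic") {
  for (p in c(fasta_path, tag_path, translate_path))
    if (!file.exists(p)) stop("reference file not found: ", p)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  fa <- data.table(name = names(seqs), sequence = as.character(seqs))
  tags <- as.data.table(read.csv(tag_path, stringsAsFactors = FALSE))
  trn <- as.data.table(read.csv(translate_path, stringsAsFactors = FALSE))
  for (nm in c("tag_sequence", "tag_offset", "gene_name")) {
    if (!nm %in% names(tags)) stop("tag file lacks column ", nm)
  }
  for (nm in c("gene_name", "motif_anchor", "motif_pattern")) {
    if (!nm %in% names(trn)) stop("translate file lacks column ", nm)
  }
  check_same_genes(fa$name, tags$gene_name, "tag")
  check_same_genes(fa$name, trn$gene_name, "translate")
  g <- merge(fa, tags, by.x = "name", by.y = "gene_name", sort = FALSE)
  g <- merge(g, trn, by.x = "name", by.y = "gene_name", sort = FALSE)
  # restore FASTA order (merge keeps x order with sort=FALSE, but be explicit)
  g <- g[match(fa$name, g$name)]
  setnames(g, "tag_sequence", "tag")
  if (!"segment_class" %in% names(g)) {
    g[, segment_class := ifelse(grepl("J", name), "J", "V")]
  }
  cls <- toupper(g$segment_class)
  if (!all(cls %in% c("V", "J")))
    stop("segment_class must be V or J")
  reference_set(g[cls == "V"], g[cls == "J"], chain = chain,
                species = species)
}

check_same_genes <- function(fasta_names, other_names, what) {
  miss <- setdiff(fasta_names, other_names)
  extra <- setdiff(other_names, fasta_names)
  if (length(miss))
    stop("gene(s) missing from ", what, " file: ",
         paste(miss, collapse = ", "))
  if (length(extra))
    stop("gene(s) in ", what, " file absent from FASTA: ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Write a reference set to its three file formats plus a JSON manifest
#'
#' @param ref A `tcr_reference`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Path to the JSON manifest, invisibly.
#' @export
write_reference_set <- function(ref, dir, prefix = ref$chain) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- rbind(cbind(ref$v_genes, segment_class = "V"),
             cbind(ref$j_genes, segment_class = "J"))
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  writeLines(paste0(">", g$name, "\n", g$sequence), fasta)
  tag_path <- file.path(dir, paste0(prefix, ".tags.csv"))
  write.csv(data.frame(tag_sequence = g$tag, tag_offset = g$tag_offset,
                       gene_name = g$name, segment_class = g$segment_class),
            tag_path, row.names = FALSE, quote = FALSE)
  trans_path <- file.path(dir, paste0(prefix, ".translate.csv"))
  write.csv(data.frame(gene_name = g$name, motif_anchor = g$motif_anchor,
                       motif_pattern = g$motif_pattern),
            trans_path, row.names = FALSE, quote = FALSE)
  manifest <- file.path(dir, paste0(prefix, ".manifest.json"))
  jsonlite::write_json(
    list(chain = ref$chain, species = ref$species,
         fasta = basename(fasta), tags = basename(tag_path),
         translate = basename(trans_path)),
    manifest, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Load a reference set named by a JSON manifest
#'
#' @param manifest_path Path to a manifest written by
#'   [write_reference_set()]; file paths inside are resolved relative to the
#'   manifest's directory.
#' @return A `tcr_reference`.
#' @export
load_reference_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("reference manifest not found: ", manifest_path)
  m <- jsonlite::read_json(manifest_path)
  d <- dirname(manifest_path)
  load_reference_set(file.path(d, m$fasta), file.path(d, m$tags),
                     file.path(d, m$translate),
                     chain = m$chain, species = m$species %||% "synthetic")
}

#' Map a V or J index back to its gene name
#'
#' @param ref A `tcr_reference`.
#' @param segment_class `"V"` or `"J"`.
#' @param index 0-based integer index (as stored in five-part identifiers).
#' @return The gene name.
#' @export
index_to_name <- function(ref, segment_class, index) {
  segment_class <- match.arg(toupper(segment_class), c("V", "J"))
  g <- if (segment_class == "V") ref$v_genes else ref$j_genes
  if (any(index < 0L | index >= nrow(g)))
    stop(segment_class, " index out of range [0, ", nrow(g) - 1L, "]")
  g$name[index + 1L]
}

#' Export the full index-to-name table of a reference set
#'
#' @param ref A `tcr_reference`.
#' @return A data.table with columns `segment_class`, `index` (0-based) and
#'   `name`.
#' @export
index_name_table <- function(ref) {
  rbind(
    data.table(segment_class = "V", index = seq_len(nrow(ref$v_genes)) - 1L,
               name = ref$v_genes$name),
    data.table(segment_class = "J", index = seq_len(nrow(ref$j_genes)) - 1L,
               name = ref$j_genes$name)
  )
}

#' The bundled toy reference set
#'
#' A synthetic four-V / three-J reference used throughout the package's
#' examples and tests. Genes are 60-80 nt, carry 20-nt recognition tags, a
#' conserved cysteine codon (V) and an FGXG-style motif (J); it is small
#' enough that exhaustive oracles are practical but exercises every loader
#' invariant.
#'
#' @param chain Chain label to stamp on the set.
#' @return A `tcr_reference`.
#' @export
toy_reference <- function(chain = "beta") {
  manifest <- system.file("extdata", "toyref", "toy.manifest.json",
                          package = "umitcr", mustWork = TRUE)
  ref <- load_reference_manifest(manifest)
  ref$chain <- match.arg(chain, c("alpha", "beta", "gamma", "delta"))
  ref
}

# Internal accessors used by the matcher and reconstruction code.
ref_genes <- function(ref, segment_class) {
  if (segment_class == "V") ref$v_genes else ref$j_genes
}
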