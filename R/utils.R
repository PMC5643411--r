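# Internal helpers shared across modules.

# Translate nucleotide strings to amino acids using the standard nuclear
# code. Sequences are truncated to whole codons; codons containing anything
# outside ACGT translate to "X".
translate_dna <- function(x) {
  x <- toupper(as.character(x))
  n_codon <- nchar(x) %/% 3L
  out <- character(length(x))
  ok <- n_codon > 0L
  if (any(ok)) {
    trimmed <- substr(x[ok], 1L, n_codon[ok] * 3L)
    has_other <- grepl("[^ACGT]", trimmed)
    aa <- character(sum(ok))
    if (any(!has_other)) {
      aa[!has_other] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(trimmed[!has_other]),
        no.init.codon = TRUE
      ))
    }
    if (any(has_other)) {
      # codon-by-codon so that fuzzy codons become X rather than an error
      aa[has_other] <- vapply(trimmed[has_other], function(s) {
        codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
        res <- vapply(codons, function(cd) {
          if (grepl("[^ACGT]", cd)) return("X")
          as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                             no.init.codon = TRUE))
        }, character(1L))
        paste(res, collapse = "")
      }, character(1L), USE.NAMES = FALSE)
    }
    out[ok] <- aa
  }
  out
}

# Match an amino-acid string against a motif pattern where X is a wildcard.
matches_motif <- function(aa, pattern) {
  if (nchar(aa) < nchar(pattern)) return(rep(FALSE, length(aa)))
  pat <- strsplit(pattern, "")[[1]]
  vapply(aa, function(s) {
    ch <- strsplit(substr(s, 1L, length(pat)), "")[[1]]
    all(pat == "X" | pat == ch)
  }, logical(1L), USE.NAMES = FALSE)
}

# Random DNA strings from the R RNG (column-wise paste0 keeps this fast for
# hundreds of thousands of reads).
random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0L))
  if (len == 0L) return(rep("", n))
  cols <- replicate(len, sample(alphabet, n, replace = TRUE),
                    simplify = FALSE)
  do.call(paste0, cols)
}

# Phred score vector from a quality string (offset 33).
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Serialize five-part identifiers to string keys
#'
#' The comma-joined form `v,j,v_del,j_del,insert` used to compare and group
#' clonotypes across tables.
#'
#' @param v_index,j_index,v_deletions,j_deletions,insert Identifier fields
#'   (vectorized).
#' @return Character vector of keys.
#' @export
identifier_key <- function(v_index, j_index, v_deletions, j_deletions, insert) {
  paste(v_index, j_index, v_deletions, j_deletions, insert, sep = ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
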