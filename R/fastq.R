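# Thin FASTQ layer over Biostrings. Gzip is handled transparently by file
# extension in both directions.

#' Read a FASTQ file into a data.table
#'
#' @param path FASTQ file, optionally gzipped.
#' @return data.table with columns `id` (full header line), `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.table(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write sequences with qualities to a FASTQ file
#'
#' @param id,seq,qual Character vectors of equal length.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @export
write_fastq <- function(id, seq, qual, path) {
  qual <- rep_len(qual, length(seq))
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(
    x, path, format = "fastq", qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
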