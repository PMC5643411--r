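# Repertoire-level statistics: clone-size spectra, inequality and diversity
# indices, fixed-depth subsampling, naive/memory overlap removal, and
# annotated-CDR3 lookup.

#' Clone-size spectrum
#'
#' The proportion of clonotypes present once, twice, etc.
#'
#' @param sizes Integer vector of clone abundances.
#' @return data.table with columns `abundance` and `proportion` (summing
#'   to 1).
#' @export
size_spectrum <- function(sizes) {
  if (length(sizes) == 0L) stop("empty abundance distribution")
  tab <- table(sizes)
  data.table(abundance = as.integer(names(tab)),
             proportion = as.numeric(tab) / length(sizes))
}

#' Gini index of clone-size inequality
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`; 0 for a perfectly even
#' repertoire, approaching 1 under extreme clonal dominance.
#'
#' @param sizes Integer vector of clone abundances.
#' @return Value in `[0, 1)`.
#' @export
gini_index <- function(sizes) {
  x <- as.numeric(sizes)
  n <- length(x)
  if (n == 0L) stop("empty abundance distribution")
  x <- sort(x)
  # sort-based evaluation of the mean-absolute-difference formula
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' Shannon entropy of a repertoire
#'
#' `H = -sum p_i log p_i` with `p_i` the molecule-frequency of clone `i`.
#'
#' @param sizes Integer vector of clone abundances.
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @return Entropy in the requested unit.
#' @export
shannon_entropy <- function(sizes, base = c("nats", "bits")) {
  base <- match.arg(base)
  x <- as.numeric(sizes)
  if (length(x) == 0L) stop("empty abundance distribution")
  p <- x / sum(x)
  h <- -sum(p * log(p))
  if (base == "bits") h / log(2) else h
}

#' Inverse Simpson index (effective clone number)
#'
#' `1 / sum p_i^2`; equals the clone count for a perfectly even repertoire.
#'
#' @param sizes Integer vector of clone abundances.
#' @return Effective number of clones.
#' @export
inverse_simpson <- function(sizes) {
  x <- as.numeric(sizes)
  if (length(x) == 0L) stop("empty abundance distribution")
  p <- x / sum(x)
  1 / sum(p^2)
}

#' Subsample a repertoire to a fixed number of molecules
#'
#' Draws `m` molecules uniformly without replacement from the
#' molecule-level multiset, so diversity indices become comparable across
#' repertoires of different sequencing depth.
#'
#' @param sizes Integer vector of clone abundances.
#' @param m Target molecule count (`m <= sum(sizes)`).
#' @param seed Optional integer seed applied locally for reproducible
#'   draws.
#' @return Integer vector of subsampled clone abundances (clones drawn zero
#'   times are absent).
#' @export
subsample_repertoire <- function(sizes, m, seed = NULL) {
  total <- sum(sizes)
  if (m > total) stop("cannot subsample ", m, " molecules from ", total)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  molecules <- rep(seq_along(sizes), sizes)
  drawn <- sample(molecules, m, replace = FALSE)
  as.integer(table(drawn))
}

#' Remove clonotypes shared with other repertoires
#'
#' Drops from `naive` every clonotype also present in any of the
#' `memory_sets` — used to purge a naive compartment of memory cells that
#' re-express the naive surface phenotype. Abundances of survivors are
#' untouched.
#'
#' @param naive data.table of clonotypes with the five identifier fields
#'   (or a `cdr3_aa` column when `key = "cdr3"`) and `abundance`.
#' @param memory_sets List of clonotype tables in the same format.
#' @param key `"identifier"` (nucleotide-level five-part identifier,
#'   default) or `"cdr3"` (amino-acid level).
#' @return The filtered `naive` table.
#' @export
remove_shared <- function(naive, memory_sets,
                          key = c("identifier", "cdr3")) {
  key <- match.arg(key)
  naive <- as.data.table(naive)
  key_of <- function(d) {
    d <- as.data.table(d)
    if (key == "cdr3") d$cdr3_aa
    else identifier_key(d$v_index, d$j_index, d$v_deletions,
                        d$j_deletions, d$insert)
  }
  seen <- unique(unlist(lapply(memory_sets, key_of)))
  naive[!key_of(naive) %in% seen]
}

#' Search repertoires for annotated CDR3 sequences
#'
#' @param repertoires Named list of CDR3 tables (columns `cdr3_aa`,
#'   `frequency`), e.g. the `table` component of [translate_repertoire()].
#' @param query_cdr3s Character vector of amino-acid CDR3 sequences.
#' @param top_k Optionally keep only the `top_k` queries with the highest
#'   row maximum (for compact reporting).
#' @return Numeric matrix, queries x repertoires, of summed frequencies of
#'   exact matches (0 when absent).
#' @export
search_annotated_cdr3 <- function(repertoires, query_cdr3s, top_k = NULL) {
  stopifnot(length(names(repertoires)) == length(repertoires))
  m <- matrix(0, nrow = length(query_cdr3s), ncol = length(repertoires),
              dimnames = list(query_cdr3s, names(repertoires)))
  for (r in seq_along(repertoires)) {
    tab <- as.data.table(repertoires[[r]])
    agg <- tab[, .(frequency = sum(frequency)), by = cdr3_aa]
    hit <- match(query_cdr3s, agg$cdr3_aa)
    m[!is.na(hit), r] <- agg$frequency[hit[!is.na(hit)]]
  }
  if (!is.null(top_k) && nrow(m) > top_k) {
    ord <- order(apply(m, 1L, max), decreasing = TRUE)
    m <- m[ord[seq_len(top_k)], , drop = FALSE]
  }
  m
}
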