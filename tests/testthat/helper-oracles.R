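# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain R loops, full pairwise scans, naive BFS.

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# All tag occurrences at Hamming distance <= max_mm, by scanning every
# position of every tag.
oracle_tag_scan <- function(read, tags, max_mm = 1L) {
  out <- NULL
  rch <- strsplit(read, "")[[1]]
  for (t in seq_along(tags)) {
    tch <- strsplit(tags[t], "")[[1]]
    L <- length(tch)
    if (L > length(rch)) next
    for (p in 0:(length(rch) - L)) {
      mm <- sum(rch[(p + 1):(p + L)] != tch)
      if (mm <= max_mm)
        out <- rbind(out, data.frame(tag = t, pos = p, mm = mm))
    }
  }
  out
}

# Mismatches between two sequences: Hamming over the shared prefix plus the
# length difference.
oracle_seq_mm <- function(a, b) {
  la <- nchar(a); lb <- nchar(b); m <- min(la, lb)
  d <- abs(la - lb)
  if (m > 0)
    d <- d + oracle_hamming(substr(a, 1, m), substr(b, 1, m))
  d
}

oracle_divergence <- function(a, b) {
  L <- max(nchar(a), nchar(b))
  if (L == 0) return(0)
  oracle_seq_mm(a, b) / L
}

# Enumerate every valid (v_del, j_del, insert) decomposition of the read
# segment between the two tags and return the canonical one (minimal v_del,
# then minimal j_del).
oracle_decompose <- function(intertag, v_index, j_index, ref = toy) {
  v <- ref$v_genes; j <- ref$j_genes
  v_suffix <- substr(v$sequence[v_index + 1], v$tag_offset[v_index + 1] +
                       nchar(v$tag[v_index + 1]) + 1,
                     nchar(v$sequence[v_index + 1]))
  j_prefix <- substr(j$sequence[j_index + 1], 1, j$tag_offset[j_index + 1])
  S <- nchar(v_suffix); P <- nchar(j_prefix); L <- nchar(intertag)
  for (vd in 0:S) {
    vpart <- substr(v_suffix, 1, S - vd)
    if (S - vd > L) next
    if (vpart != substr(intertag, 1, S - vd)) next
    for (jd in 0:P) {
      jpart <- substr(j_prefix, jd + 1, P)
      klen <- P - jd
      if ((S - vd) + klen > L) next
      if (jpart != substr(intertag, L - klen + 1, L)) next
      return(list(v_deletions = vd, j_deletions = jd,
                  insert = substr(intertag, S - vd + 1, L - klen)))
    }
  }
  NULL
}

# Naive implementation of the three collapsing passes. Records must carry
# columns umi, intertag, id_key (records failing the UMI gate are assumed
# already removed).
oracle_collapse <- function(rec, max_div = 0.10, umi_mm = 2L, tcr_mm = 2L) {
  rec <- as.data.frame(rec)
  # (a)-(b): greedy clustering within each UMI group
  entries <- NULL
  for (u in unique(rec$umi)) {
    grp <- rec[rec$umi == u, ]
    agg <- aggregate(list(n = rep(1L, nrow(grp))),
                     by = list(intertag = grp$intertag,
                               id_key = grp$id_key), FUN = sum)
    agg <- agg[order(-agg$n, agg$intertag), ]
    while (nrow(agg) > 0) {
      ref_seq <- agg$intertag[1]
      div <- vapply(agg$intertag, function(s)
        oracle_divergence(s, ref_seq), numeric(1))
      take <- div < max_div
      take[1] <- TRUE
      entries <- rbind(entries, data.frame(
        umi = u, intertag = ref_seq, id_key = agg$id_key[1],
        n_reads = sum(agg$n[take])))
      agg <- agg[!take, ]
    }
  }
  # (c): single-linkage over (same-or-similar TCR) x (close UMI)
  n <- nrow(entries)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    same_tcr <- entries$id_key[a] == entries$id_key[b] ||
      oracle_seq_mm(entries$intertag[a], entries$intertag[b]) <= tcr_mm
    close_umi <- oracle_hamming(entries$umi[a], entries$umi[b]) <= umi_mm
    adj[a, b] <- same_tcr && close_umi
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (a in seq_len(n)) {
    if (!is.na(comp[a])) next
    cid <- cid + 1L
    queue <- a
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[x])) next
      comp[x] <- cid
      queue <- c(queue, which(adj[x, ] & is.na(comp)))
    }
  }
  mol <- NULL
  for (cc in seq_len(cid)) {
    sel <- entries[comp == cc, ]
    sel <- sel[order(-sel$n_reads, sel$id_key), ]
    mol <- rbind(mol, data.frame(id_key = sel$id_key[1],
                                 n_reads = sum(sel$n_reads)))
  }
  agg <- aggregate(list(abundance = rep(1L, nrow(mol)),
                        reads_absorbed = mol$n_reads),
                   by = list(id_key = mol$id_key),
                   FUN = sum)
  agg[order(agg$id_key), ]
}

oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) s <- s + abs(x[a] - x[b])
  s / (2 * n^2 * mean(x))
}
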