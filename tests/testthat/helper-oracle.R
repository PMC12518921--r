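# Brute-force agglomerative single-linkage clustering, independent of
# hclust: repeatedly merge the pair of clusters with the smallest minimum
# pairwise Euclidean distance between member profiles, breaking ties toward
# the lowest-index pair, until k clusters remain.
oracleSingleLinkage <- function(v, k) {
  n <- nrow(v)
  d <- as.matrix(stats::dist(v))
  clusters <- lapply(seq_len(n), identity)
  while (length(clusters) > k) {
    best <- list(d = Inf, a = 0L, b = 0L)
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        m <- min(d[clusters[[a]], clusters[[b]]])
        if (m < best$d) best <- list(d = m, a = a, b = b)
      }
    }
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Canonical form of a flat clustering: renumber labels by first appearance,
# so two clusterings are equal up to relabeling iff their canonical forms
# are identical.
canonicalLabels <- function(x) match(x, unique(x))
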