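# Symmetric random PAE-like matrix (entries in [0, 31.75], zero diagonal).
randomSymPae <- function(L, id = "rand") {
  m <- matrix(runif(L * L, 0, 31.75), L, L)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  PaeMatrix(m, proteinId = id, symmetrized = TRUE)
}

# Symmetric matrix where the only low-PAE contacts are the given undirected
# edges (plus the diagonal); everything else is `high`.
contactGraphPae <- function(L, edges, low = 2, high = 20, id = "graph") {
  m <- matrix(high, L, L)
  if (length(edges)) {
    for (e in edges) {
      m[e[1], e[2]] <- low
      m[e[2], e[1]] <- low
    }
  }
  diag(m) <- 0
  PaeMatrix(m, proteinId = id, symmetrized = TRUE)
}

# Near-diagonal band matrix: low PAE only for |i - j| <= width.
bandPae <- function(L, width = 2, low = 2, high = 20, id = "band") {
  m <- matrix(high, L, L)
  m[abs(outer(seq_len(L), seq_len(L), "-")) <= width] <- low
  diag(m) <- 0
  PaeMatrix(m, proteinId = id, symmetrized = TRUE)
}

# ResidueLabels with domain/non_domain runs from a compact spec like
# list(c("D", 30), c("N", 10), c("D", 40)): D runs get successive domain
# indices, N runs are non_domain, X runs are disordered.
labelsFromRuns <- function(runs) {
  tag <- character(0); index <- integer(0); d <- 0L
  for (r in runs) {
    n <- as.integer(r[2])
    if (r[1] == "D") {
      d <- d + 1L
      tag <- c(tag, rep("domain", n)); index <- c(index, rep(d, n))
    } else if (r[1] == "N") {
      tag <- c(tag, rep("non_domain", n)); index <- c(index, rep(NA_integer_, n))
    } else {
      tag <- c(tag, rep("disordered", n)); index <- c(index, rep(NA_integer_, n))
    }
  }
  spaedr:::ResidueLabels(tag = tag, index = index)
}

# Compact run view of labels, e.g. "D1:30 non_domain:10 D2:40".
labelRuns <- function(labels) {
  key <- spaedr:::.labelKey(labels)
  r <- rle(key)
  paste(sprintf("%s:%d", r$values, r$lengths), collapse = " ")
}
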