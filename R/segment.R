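#' @include AllGenerics.R
NULL

# Maximal runs of identical keys: data.frame(start, end, key), 1-based.
.runsOf <- function(key) {
  r <- rle(key)
  e <- cumsum(r$lengths)
  data.frame(start = e - r$lengths + 1L, end = e, key = r$values,
             stringsAsFactors = FALSE)
}

# Collapse tag/index into one key per residue ("D3", "C7", "non_domain", ...).
.labelKey <- function(labels) {
  ifelse(labels@tag == "domain", paste0("D", labels@index),
         ifelse(labels@tag == "cluster", paste0("C", labels@index),
                labels@tag))
}

# Inverse of .labelKey for domain/non_domain/linker/disordered keys.
.keyToLabels <- function(key) {
  isD <- startsWith(key, "D")
  tag <- ifelse(isD, "domain", key)
  index <- rep(NA_integer_, length(key))
  index[isD] <- as.integer(sub("^D", "", key[isD]))
  ResidueLabels(tag = tag, index = index)
}

# Renumber domain indices 1..n by position of each domain's first residue.
.renumberDomains <- function(labels) {
  dom <- labels@tag == "domain"
  if (!any(dom)) return(labels)
  first <- tapply(which(dom), labels@index[dom], min)
  remap <- integer(0)
  remap[as.integer(names(sort(first)))] <- seq_along(first)
  labels@index[dom] <- remap[labels@index[dom]]
  labels
}

#' Cluster residues by their PAE profiles
#'
#' Step 1 of the segmentation. Each residue is represented by its full row of
#' the symmetrized PAE matrix (its error profile against every other
#' residue); residues are grouped by agglomerative single-linkage clustering
#' of the Euclidean distances between profiles, and the tree is cut at the
#' smallest height that yields at most `maxclust` flat clusters, with
#' `maxclust = max(2, round(maxClusterFraction * L))` (one tenth of the chain
#' length by default). The cap is deliberately generous relative to the 1-4
#' domains expected of an endolysin: compact domains come out as long,
#' coherent clusters, while linkers and floppy termini shatter into many
#' small, often singleton clusters that later steps recognise as non-domain.
#'
#' @param sym a symmetrized [PaeMatrix-class].
#' @param params a [SpaedParams-class].
#' @return A [ResidueLabels-class] with per-residue `cluster` tags, indices
#'   numbered by first residue of appearance.
#' @export
clusterResidues <- function(sym, params = SpaedParams()) {
  stopifnot(is(sym, "PaeMatrix"), is(params, "SpaedParams"))
  if (!sym@symmetrized)
    stop("clusterResidues needs a symmetrized matrix; call symmetrize() first")
  L <- nrow(sym@values)
  if (L < 2L) stop("protein too short")
  maxclust <- max(2L, as.integer(round(params@maxClusterFraction * L)))
  k <- min(maxclust, L)
  hc <- stats::hclust(stats::dist(sym@values), method = "single")
  # cut at the smallest height giving <= k flat clusters: threshold at the
  # (L-k)-th merge height; tied merges at that height all happen, so the
  # number of clusters can fall below k (e.g. zero-distance blocks)
  cl <- if (k == L) seq_len(L)
        else stats::cutree(hc, h = hc$height[L - k])
  cl <- match(cl, unique(cl))  # renumber by first appearance
  ResidueLabels(tag = rep("cluster", L), index = cl)
}

#' Promote large clusters to domains
#'
#' Step 2. Clusters with strictly more than `minDomainCluster` residues
#' (default 25) become predicted domains, numbered from the N-terminus; all
#' remaining residues are tagged `non_domain`. The 25-residue cut-off
#' reflects the smallest expected domain size (>30 residues) with a buffer
#' for residues the preliminary clustering misplaces.
#'
#' @param labels a [ResidueLabels-class] with `cluster` tags.
#' @param params a [SpaedParams-class].
#' @return A [ResidueLabels-class] with `domain`/`non_domain` tags. If no
#'   cluster exceeds the threshold all residues are `non_domain` (the caller
#'   decides what that means; see [spaedSegment()]).
#' @export
assignDomains <- function(labels, params = SpaedParams()) {
  stopifnot(is(labels, "ResidueLabels"), is(params, "SpaedParams"))
  if (!all(labels@tag == "cluster"))
    stop("assignDomains expects preliminary cluster labels")
  sizes <- table(labels@index)
  domClusters <- as.integer(names(sizes))[sizes > params@minDomainCluster]
  tag <- ifelse(labels@index %in% domClusters, "domain", "non_domain")
  index <- ifelse(tag == "domain", labels@index, NA_integer_)
  .renumberDomains(ResidueLabels(tag = tag, index = index))
}

#' Decide whether a terminal region is disordered
#'
#' The compactness filter of step 3. A residue of the region is "poorly
#' connected" when at most `disorderNeighborMax` other residues of the same
#' region have a PAE below `lowPae` with it (default: at most 5 neighbours
#' below 5 Angstrom). If strictly more than `disorderFraction` (default 80%)
#' of the region's residues are poorly connected, every residue is close in
#' space only to its sequence neighbours and the region lacks tertiary
#' structure, i.e. it is disordered.
#'
#' @param region integer(2), first and last residue (1-based, inclusive) of a
#'   contiguous interval.
#' @param sym a symmetrized [PaeMatrix-class].
#' @param params a [SpaedParams-class].
#' @return `TRUE` when the region is disordered.
#' @export
isDisordered <- function(region, sym, params = SpaedParams()) {
  stopifnot(is(sym, "PaeMatrix"), is(params, "SpaedParams"))
  s <- as.integer(region[1L]); e <- as.integer(region[2L])
  if (is.na(s) || is.na(e) || e < s) stop("empty region")
  if (s < 1L || e > nrow(sym@values)) stop("region outside the chain")
  sub <- sym@values[s:e, s:e, drop = FALSE]
  # diagonal is 0 and always < lowPae; subtract the self-contact
  neighbors <- rowSums(sub < params@lowPae) - 1L
  mean(neighbors <= params@disorderNeighborMax) > params@disorderFraction
}

# Shared by correctEnds for one terminus. `positions` are the residues of the
# maximal terminal non-domain run, ordered from the terminus inward;
# `adjacent` is the index of the domain next to the run.
.resolveTerminalRun <- function(labels, positions, adjacent, sym, params) {
  runLen <- length(positions)
  mergeIt <- runLen < params@terminalMergeLen ||
    !isDisordered(range(positions), sym, params)
  if (mergeIt) {
    labels@tag[positions] <- "domain"
    labels@index[positions] <- adjacent
  } else {
    labels@tag[positions] <- "disordered"
    labels@index[positions] <- NA_integer_
  }
  labels
}

#' Resolve terminal non-domain runs
#'
#' Step 3, applied to the N-terminus first and then the C-terminus. The
#' maximal run of `non_domain` residues touching a terminus is absorbed into
#' the nearest domain when it is strictly shorter than `terminalMergeLen`
#' residues (default 20). Longer runs are tested with [isDisordered()]:
#' disordered runs are tagged `disordered`, compact ones are a less packed
#' but still ordered part of the neighbouring domain and are merged into it.
#'
#' @param labels a [ResidueLabels-class] with `domain`/`non_domain` tags; at
#'   least one domain must exist.
#' @param sym a symmetrized [PaeMatrix-class].
#' @param params a [SpaedParams-class].
#' @return The updated [ResidueLabels-class].
#' @export
correctEnds <- function(labels, sym, params = SpaedParams()) {
  stopifnot(is(labels, "ResidueLabels"))
  if (!any(labels@tag == "domain"))
    stop("correctEnds needs at least one domain")
  L <- length(labels@tag)
  # N-terminus
  if (labels@tag[1L] == "non_domain") {
    e <- which(labels@tag != "non_domain")[1L] - 1L
    if (labels@tag[e + 1L] == "domain")
      labels <- .resolveTerminalRun(labels, 1L:e, labels@index[e + 1L],
                                    sym, params)
  }
  # C-terminus
  if (labels@tag[L] == "non_domain") {
    s <- max(which(labels@tag != "non_domain")) + 1L
    if (labels@tag[s - 1L] == "domain")
      labels <- .resolveTerminalRun(labels, s:L, labels@index[s - 1L],
                                    sym, params)
  }
  labels
}

#' Make every domain contiguous
#'
#' Step 4, the artifact repair pass. Scanning from the N-terminus, (1) any
#' single run of residues (non-domain or belonging to another domain) lying
#' strictly between two runs of the same domain is relabelled to that domain;
#' then (2) a domain whose residues still form several runs keeps only its
#' longest run (ties resolved toward the N-terminus) and the other runs
#' revert to `non_domain`. The two rules are iterated to a fixed point, after
#' which every domain occupies exactly one contiguous stretch and domains are
#' renumbered 1..n by position.
#'
#' @param labels a [ResidueLabels-class] with `domain`/`non_domain` (and
#'   possibly `disordered`) tags.
#' @return The repaired [ResidueLabels-class].
#' @export
correctArtifacts <- function(labels) {
  stopifnot(is(labels, "ResidueLabels"))
  key <- .labelKey(labels)
  repeat {
    runs <- .runsOf(key)
    n <- nrow(runs)
    changed <- FALSE
    # rule 1: absorb a single foreign run sandwiched inside one domain
    if (n >= 3L) {
      for (i in 2L:(n - 1L)) {
        k <- runs$key[i - 1L]
        if (startsWith(k, "D") && runs$key[i + 1L] == k &&
            runs$key[i] != k && runs$key[i] != "disordered") {
          key[runs$start[i]:runs$end[i]] <- k
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) {
      # rule 2: a split domain keeps its longest run (N-terminal-most on ties)
      domRuns <- runs[startsWith(runs$key, "D"), , drop = FALSE]
      for (k in unique(domRuns$key)) {
        rk <- domRuns[domRuns$key == k, , drop = FALSE]
        if (nrow(rk) > 1L) {
          lens <- rk$end - rk$start + 1L
          keep <- which.max(lens)  # first maximum: N-terminal-most
          for (j in seq_len(nrow(rk))[-keep])
            key[rk$start[j]:rk$end[j]] <- "non_domain"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  .renumberDomains(.keyToLabels(key))
}

#' Adjust domain-linker boundaries
#'
#' Step 5. A residue that truly belongs to a domain has a low PAE (<
#' `lowPae`) with roughly as many residues as the domain contains, whereas a
#' linker residue is in contact with only a handful. For every interior
#' `non_domain` run flanked by two domains, residues are therefore walked in
#' from the left edge (joining the left domain) and then from the right edge
#' (joining the right domain) for as long as their chain-wide count of
#' low-PAE partners is at least `linkerSupport` (default 25); each walk stops
#' at its first failing residue and the walks never pass each other (the left
#' walk has priority). Surviving residues are tagged `linker`; a run may be
#' consumed entirely, leaving the two domains adjacent.
#'
#' @param labels a [ResidueLabels-class] with contiguous domains.
#' @param sym a symmetrized [PaeMatrix-class].
#' @param params a [SpaedParams-class].
#' @return The updated [ResidueLabels-class].
#' @export
adjustLinkers <- function(labels, sym, params = SpaedParams()) {
  stopifnot(is(labels, "ResidueLabels"), is(sym, "PaeMatrix"))
  # chain-wide low-PAE support per residue (diagonal self-contact excluded)
  support <- rowSums(sym@values < params@lowPae) - 1L
  key <- .labelKey(labels)
  runs <- .runsOf(key)
  n <- nrow(runs)
  for (i in seq_len(n)) {
    if (runs$key[i] != "non_domain" || i == 1L || i == n) next
    kl <- runs$key[i - 1L]; kr <- runs$key[i + 1L]
    if (!startsWith(kl, "D") || !startsWith(kr, "D")) next
    s <- runs$start[i]; e <- runs$end[i]
    left <- s
    while (left <= e && support[left] >= params@linkerSupport) {
      key[left] <- kl
      left <- left + 1L
    }
    right <- e
    while (right >= left && support[right] >= params@linkerSupport) {
      key[right] <- kr
      right <- right - 1L
    }
    if (left <= right) key[left:right] <- "linker"
  }
  .keyToLabels(key)
}

# Convert final labels to a Segmentation. Leftover non_domain runs (rare,
# only after degenerate repairs) fall back to linker when flanked by two
# domains and to disordered otherwise; adjacent runs of the same non-domain
# kind are merged into one region.
.labelsToSegmentation <- function(labels, proteinId) {
  key <- .labelKey(labels)
  runs <- .runsOf(key)
  n <- nrow(runs)
  kind <- character(n)
  for (i in seq_len(n)) {
    k <- runs$key[i]
    kind[i] <- if (startsWith(k, "D")) "domain"
      else if (k == "linker") "linker"
      else if (k == "disordered") "disordered"
      else if (i > 1L && i < n && startsWith(runs$key[i - 1L], "D") &&
               startsWith(runs$key[i + 1L], "D")) "linker"
      else "disordered"
  }
  # merge adjacent regions of the same non-domain kind
  keep <- rep(TRUE, n)
  for (i in seq_len(n)[-1L]) {
    if (kind[i] != "domain" && kind[i] == kind[i - 1L]) {
      runs$start[i] <- runs$start[i - 1L]
      keep[i - 1L] <- FALSE
    }
  }
  runs <- runs[keep, , drop = FALSE]
  kind <- kind[keep]
  Segmentation(proteinId, length(labels@tag),
               start = runs$start, end = runs$end, kind = kind)
}

#' Segment a protein from its PAE matrix
#'
#' The full pipeline: symmetrize the matrix (if needed), cluster residues by
#' their PAE profiles ([clusterResidues()]), promote large clusters to
#' domains ([assignDomains()]), resolve terminal runs ([correctEnds()]),
#' repair clustering artifacts so domains are contiguous
#' ([correctArtifacts()]), and refine domain-linker boundaries
#' ([adjustLinkers()]). The result is an ordered tiling of the chain into
#' domains, linkers and terminal disordered regions. The pipeline is fully
#' deterministic: identical input and parameters give identical output.
#'
#' Degenerate inputs are resolved by policy rather than error: if no cluster
#' is large enough to seed a domain, the whole chain becomes a single region
#' -- of kind `domain` when the chain is longer than `minDomainCluster`
#' residues, of kind `disordered` otherwise -- so that a segmentation always
#' tiles the protein. Chains of fewer than 2 residues are rejected.
#'
#' @param pae a [PaeMatrix-class], raw or symmetrized.
#' @param params a [SpaedParams-class]; see that class for all thresholds.
#' @return A [Segmentation-class].
#' @examples
#' arch <- Architecture(c("domain", "linker", "domain"), c(150, 8, 120),
#'                      seed = 7)
#' sim <- generatePae(arch)
#' spaedSegment(sim$pae)
#' @export
spaedSegment <- function(pae, params = SpaedParams()) {
  stopifnot(is(pae, "PaeMatrix"), is(params, "SpaedParams"))
  sym <- if (pae@symmetrized) pae else symmetrize(pae)
  L <- nrow(sym@values)
  labels <- clusterResidues(sym, params)
  labels <- assignDomains(labels, params)
  if (!any(labels@tag == "domain")) {
    kind <- if (L > params@minDomainCluster) "domain" else "disordered"
    return(Segmentation(pae@proteinId, L, start = 1L, end = L, kind = kind))
  }
  labels <- correctEnds(labels, sym, params)
  labels <- correctArtifacts(labels)
  # longest-run pruning can expose new terminal non-domain runs; give them
  # the same treatment as step 3
  if (labels@tag[1L] == "non_domain" || labels@tag[L] == "non_domain")
    labels <- correctEnds(labels, sym, params)
  labels <- adjustLinkers(labels, sym, params)
  .labelsToSegmentation(labels, pae@proteinId)
}
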