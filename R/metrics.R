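#' @include AllGenerics.R
NULL

# Domain residue intervals of a segmentation: data.frame(start, end).
.domainIntervals <- function(seg) {
  tab <- regionTable(seg)
  tab[tab$kind == "domain", c("start", "end"), drop = FALSE]
}

# Internal boundary positions (half-integers between residues) of the domain
# edges, protein termini excluded.
.boundaries <- function(seg) {
  d <- .domainIntervals(seg)
  if (nrow(d) == 0L) return(numeric(0))
  b <- c(d$start - 0.5, d$end + 0.5)
  b <- b[b > 0.5 & b < length(seg) + 0.5]
  sort(unique(b))
}

# Best one-to-one assignment total of a (small) score matrix, by exhaustive
# branch over rows; rows may stay unmatched.
.maxAssignment <- function(m) {
  if (nrow(m) == 0L || ncol(m) == 0L) return(0)
  best <- .maxAssignment(m[-1L, , drop = FALSE])  # row 1 unmatched
  for (j in seq_len(ncol(m))) {
    v <- m[1L, j] + .maxAssignment(m[-1L, -j, drop = FALSE])
    if (v > best) best <- v
  }
  best
}

.checkComparable <- function(pred, ref) {
  stopifnot(is(pred, "Segmentation"), is(ref, "Segmentation"))
  if (length(pred) != length(ref))
    stop("predicted and reference segmentations have different lengths")
}

#' Intersection-over-union of matched domains
#'
#' Domains (linkers and disordered regions excluded) of the predicted and
#' reference segmentations are matched one-to-one so as to maximize the
#' summed per-pair IoU, where
#' \eqn{IoU(d_p, d_r) = |d_p \cap d_r| / |d_p \cup d_r|} over the two
#' domains' residue sets. The score is the matched sum divided by
#' `max(nPred, nRef)`: unmatched domains contribute zero, so over- and
#' under-segmentation are penalized symmetrically. 1 means a perfect
#' overlap. The matching is exhaustive (domain counts are small).
#'
#' @param pred,ref [Segmentation-class] objects of equal length.
#' @return numeric(1) in `[0, 1]`. If neither segmentation contains a
#'   domain the score is 1; if exactly one does, 0.
#' @examples
#' a <- Segmentation("x", 100, 1, 100, "domain")
#' b <- Segmentation("x", 100, c(1, 81), c(80, 100), c("domain", "disordered"))
#' iouScore(b, a)   # 80 / 100
#' @export
iouScore <- function(pred, ref) {
  .checkComparable(pred, ref)
  dp <- .domainIntervals(pred)
  dr <- .domainIntervals(ref)
  np <- nrow(dp); nr <- nrow(dr)
  if (np == 0L && nr == 0L) return(1)
  if (np == 0L || nr == 0L) return(0)
  m <- matrix(0, np, nr)
  for (i in seq_len(np)) {
    for (j in seq_len(nr)) {
      inter <- max(0L, min(dp$end[i], dr$end[j]) -
                       max(dp$start[i], dr$start[j]) + 1L)
      uni <- (dp$end[i] - dp$start[i] + 1L) +
             (dr$end[j] - dr$start[j] + 1L) - inter
      m[i, j] <- inter / uni
    }
  }
  .maxAssignment(m) / max(np, nr)
}

#' Domain boundary distance score
#'
#' Boundaries are the internal domain edges of each segmentation
#' (half-integer positions between residues; chain termini do not count).
#' Each boundary scores `max(0, 1 - d/8)` against the other segmentation's
#' boundary set, where `d` is the residue distance to the nearest boundary:
#' a perfect prediction earns one point and every residue of displacement
#' costs 1/8. The accuracy component averages predicted boundaries against
#' the reference, the sensitivity component reference boundaries against the
#' prediction, and the DBD score is the mean of the two. If both boundary
#' sets are empty the score is 1; if exactly one is empty, 0.
#'
#' @param pred,ref [Segmentation-class] objects of equal length.
#' @return numeric(1) in `[0, 1]`.
#' @export
dbdScore <- function(pred, ref) {
  .checkComparable(pred, ref)
  bp <- .boundaries(pred)
  br <- .boundaries(ref)
  if (length(bp) == 0L && length(br) == 0L) return(1)
  if (length(bp) == 0L || length(br) == 0L) return(0)
  score <- function(b, against)
    mean(vapply(b, function(x) max(0, 1 - min(abs(x - against)) / 8),
                numeric(1)))
  (score(bp, br) + score(br, bp)) / 2
}

#' Boundary accuracy and sensitivity permissibility curves
#'
#' For each permissibility distance `X = 0..maxDist`, the accuracy curve is
#' the fraction of predicted boundaries lying within `X` residues of some
#' reference boundary, and the sensitivity curve the fraction of reference
#' boundaries within `X` residues of some predicted boundary. Both curves
#' are non-decreasing in `X`. `accuracyAt["0"]` is the exact-boundary
#' accuracy. When both boundary sets are empty the curves are identically 1;
#' when exactly one is empty, identically 0 (matching the [dbdScore()]
#' conventions).
#'
#' @param pred,ref [Segmentation-class] objects of equal length.
#' @param maxDist largest permissibility distance (default 7 residues).
#' @return A list with named numeric vectors `accuracyAt` and
#'   `sensitivityAt` (names `"0"` .. `"maxDist"`).
#' @export
boundaryCurves <- function(pred, ref, maxDist = 7L) {
  .checkComparable(pred, ref)
  stopifnot(maxDist >= 0L)
  bp <- .boundaries(pred)
  br <- .boundaries(ref)
  dists <- 0:maxDist
  curve <- function(b, against) {
    v <- if (length(b) == 0L && length(against) == 0L) {
      rep(1, length(dists))
    } else if (length(b) == 0L || length(against) == 0L) {
      rep(0, length(dists))
    } else {
      nearest <- vapply(b, function(x) min(abs(x - against)), numeric(1))
      vapply(dists, function(X) mean(nearest <= X), numeric(1))
    }
    names(v) <- as.character(dists)
    v
  }
  list(accuracyAt = curve(bp, br), sensitivityAt = curve(br, bp))
}

#' Score one predicted segmentation against a reference
#'
#' Bundles [iouScore()], [dbdScore()] and [boundaryCurves()] into an
#' [EvalReport-class].
#'
#' @param pred,ref [Segmentation-class] objects of equal length.
#' @param maxDist largest permissibility distance for the curves.
#' @return An [EvalReport-class].
#' @export
evaluateSegmentation <- function(pred, ref, maxDist = 7L) {
  .checkComparable(pred, ref)
  cur <- boundaryCurves(pred, ref, maxDist)
  new("EvalReport",
      proteinId = proteinId(pred),
      iou = iouScore(pred, ref),
      dbd = dbdScore(pred, ref),
      accuracyAt = cur$accuracyAt,
      sensitivityAt = cur$sensitivityAt,
      nPredDomains = as.integer(nDomains(pred)),
      nRefDomains = as.integer(nDomains(ref)))
}

#' Aggregate evaluation reports over proteins
#'
#' Arithmetic mean and population standard deviation (denominator n) of the
#' IoU and DBD scores over a set of per-protein reports, plus the
#' accuracy/sensitivity curves averaged per permissibility distance.
#'
#' @param reports non-empty list of [EvalReport-class] objects.
#' @return A list with elements `n`, `meanIou`, `sdIou`, `meanDbd`, `sdDbd`,
#'   `accuracyAt`, `sensitivityAt`.
#' @export
aggregateReports <- function(reports) {
  if (length(reports) == 0L) stop("no reports to aggregate")
  stopifnot(all(vapply(reports, is, logical(1), "EvalReport")))
  iou <- vapply(reports, function(r) r@iou, numeric(1))
  dbd <- vapply(reports, function(r) r@dbd, numeric(1))
  sdPop <- function(x) sqrt(mean((x - mean(x))^2))
  acc <- rowMeans(vapply(reports, function(r) r@accuracyAt,
                         reports[[1L]]@accuracyAt))
  sen <- rowMeans(vapply(reports, function(r) r@sensitivityAt,
                         reports[[1L]]@sensitivityAt))
  list(n = length(reports),
       meanIou = mean(iou), sdIou = sdPop(iou),
       meanDbd = mean(dbd), sdDbd = sdPop(dbd),
       accuracyAt = acc, sensitivityAt = sen)
}
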