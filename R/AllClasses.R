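#' @import methods
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

.REGION_KINDS <- c("domain", "linker", "disordered")

# ---------------------------------------------------------------------------
# PaeMatrix
# ---------------------------------------------------------------------------

#' Predicted aligned error matrix for one protein chain
#'
#' Holds the square matrix of expected pairwise positional errors (in
#' Angstrom) that AlphaFold-family predictors report alongside a structure
#' model. Entry \eqn{(i,j)} is the expected error in the position of residue
#' \eqn{j} when the prediction is aligned on residue \eqn{i}; it is low for
#' residue pairs packed in the same rigid body and high between independently
#' placed domains, which is the signal the segmentation algorithm exploits.
#'
#' @slot proteinId character(1), identifier of the chain (by default the
#'   file stem of the JSON the matrix was read from).
#' @slot values numeric L x L matrix of non-negative errors in Angstrom.
#'   Producers cap the PAE (AlphaFold2 at 31.75 A); entries above 40 are
#'   rejected as malformed.
#' @slot symmetrized logical(1), `TRUE` once the matrix has been replaced by
#'   the average of itself and its transpose (see [symmetrize()]).
#'
#' @seealso [readPae()], [symmetrize()], [spaedSegment()]
#' @export
setClass("PaeMatrix",
  slots = c(
    proteinId   = "character",
    values      = "matrix",
    symmetrized = "logical"
  )
)

setValidity("PaeMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("malformed PAE: values must be numeric")
  if (length(dim(v)) != 2L || nrow(v) != ncol(v))
    return("malformed PAE: matrix must be square")
  if (anyNA(v) || any(!is.finite(v)))
    return("malformed PAE: non-finite entries")
  if (any(v < 0) || any(v > 40))
    return("malformed PAE: entries outside [0, 40]")
  if (length(object@proteinId) != 1L)
    return("proteinId must be a single string")
  if (length(object@symmetrized) != 1L || is.na(object@symmetrized))
    return("symmetrized must be TRUE or FALSE")
  if (object@symmetrized && !all(v == t(v)))
    return("symmetrized flag set but matrix is not symmetric")
  TRUE
})

#' Construct a PaeMatrix
#'
#' @param values numeric square matrix of PAE values in Angstrom.
#' @param proteinId identifier for the chain.
#' @param symmetrized whether `values` is already symmetric (checked).
#' @return A [PaeMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 4, 2, 0), 2, 2)
#' PaeMatrix(m, proteinId = "toy")
#' @export
PaeMatrix <- function(values, proteinId = "protein", symmetrized = FALSE) {
  values <- as.matrix(values)
  dimnames(values) <- NULL
  storage.mode(values) <- "double"
  new("PaeMatrix", proteinId = as.character(proteinId), values = values,
      symmetrized = symmetrized)
}

# ---------------------------------------------------------------------------
# SpaedParams
# ---------------------------------------------------------------------------

#' Tunable thresholds of the segmentation algorithm
#'
#' All knobs of the PAE-clustering segmentation in one object. The defaults
#' are tuned for phage endolysins and similar modular proteins with compact,
#' well-separated domains; they can be loosened to detect disordered termini
#' or linkers more sensitively, or adapted to other protein families.
#'
#' @slot maxClusterFraction fraction of the chain length used as the maximum
#'   number of flat clusters (default 0.10, i.e. one cluster per ten
#'   residues; the cut is `max(2, round(maxClusterFraction * L))`).
#' @slot minDomainCluster preliminary clusters with strictly more residues
#'   than this become domains (default 25; a real domain is expected to span
#'   more than 30 residues, leaving a buffer for clustering errors).
#' @slot terminalMergeLen terminal non-domain runs strictly shorter than this
#'   are absorbed into the nearest domain without further checks (default 20).
#' @slot lowPae PAE threshold in Angstrom below which two residues count as
#'   "in contact" (default 5).
#' @slot disorderNeighborMax a residue is poorly connected when it has at
#'   most this many low-PAE neighbours inside its region (default 5).
#' @slot disorderFraction a terminal region is disordered when strictly more
#'   than this fraction of its residues are poorly connected (default 0.80).
#' @slot linkerSupport a residue at a domain-linker boundary is claimed by
#'   the domain when it has low PAE with at least this many residues of the
#'   whole chain (default 25).
#'
#' @seealso [spaedSegment()]
#' @export
setClass("SpaedParams",
  slots = c(
    maxClusterFraction = "numeric",
    minDomainCluster   = "integer",
    terminalMergeLen   = "integer",
    lowPae             = "numeric",
    disorderNeighborMax = "integer",
    disorderFraction   = "numeric",
    linkerSupport      = "integer"
  )
)

setValidity("SpaedParams", function(object) {
  f <- object@maxClusterFraction
  if (length(f) != 1L || is.na(f) || f <= 0 || f > 1)
    return("maxClusterFraction must be in (0, 1]")
  for (s in c("minDomainCluster", "terminalMergeLen", "disorderNeighborMax",
              "linkerSupport")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      return(sprintf("%s must be an integer >= 1", s))
  }
  if (length(object@lowPae) != 1L || is.na(object@lowPae) ||
      object@lowPae <= 0)
    return("lowPae must be > 0")
  df <- object@disorderFraction
  if (length(df) != 1L || is.na(df) || df <= 0 || df >= 1)
    return("disorderFraction must be in (0, 1)")
  TRUE
})

#' @param maxClusterFraction,minDomainCluster,terminalMergeLen,lowPae,disorderNeighborMax,disorderFraction,linkerSupport
#'   see the slot documentation in [SpaedParams-class].
#' @return A [SpaedParams-class] object.
#' @examples
#' SpaedParams()                      # endolysin defaults
#' SpaedParams(linkerSupport = 15)    # more aggressive boundary adjustment
#' @rdname SpaedParams-class
#' @export
SpaedParams <- function(maxClusterFraction = 0.10,
                        minDomainCluster = 25L,
                        terminalMergeLen = 20L,
                        lowPae = 5,
                        disorderNeighborMax = 5L,
                        disorderFraction = 0.80,
                        linkerSupport = 25L) {
  new("SpaedParams",
      maxClusterFraction = as.numeric(maxClusterFraction),
      minDomainCluster = as.integer(minDomainCluster),
      terminalMergeLen = as.integer(terminalMergeLen),
      lowPae = as.numeric(lowPae),
      disorderNeighborMax = as.integer(disorderNeighborMax),
      disorderFraction = as.numeric(disorderFraction),
      linkerSupport = as.integer(linkerSupport))
}

# ---------------------------------------------------------------------------
# ResidueLabels
# ---------------------------------------------------------------------------

#' Per-residue labels during segmentation
#'
#' Intermediate state of the segmentation pipeline: each residue carries a
#' tag, and for `cluster` / `domain` tags an index. Tags move through the
#' stages cluster -> (domain | non_domain) -> (domain | linker | disordered).
#'
#' @slot tag character vector, one of `"cluster"`, `"domain"`,
#'   `"non_domain"`, `"linker"`, `"disordered"` per residue.
#' @slot index integer vector, cluster or domain index where applicable
#'   (`NA` otherwise).
#' @export
setClass("ResidueLabels",
  slots = c(tag = "character", index = "integer")
)

setValidity("ResidueLabels", function(object) {
  ok <- c("cluster", "domain", "non_domain", "linker", "disordered")
  if (length(object@tag) != length(object@index))
    return("tag and index must have equal length")
  if (!all(object@tag %in% ok))
    return(paste("tags must be one of:", paste(ok, collapse = ", ")))
  need <- object@tag %in% c("cluster", "domain")
  if (any(is.na(object@index[need])))
    return("cluster/domain labels need an index")
  TRUE
})

ResidueLabels <- function(tag, index = rep(NA_integer_, length(tag))) {
  new("ResidueLabels", tag = as.character(tag), index = as.integer(index))
}

# ---------------------------------------------------------------------------
# Segmentation
# ---------------------------------------------------------------------------

#' Segmentation of a protein chain into domains, linkers and disordered ends
#'
#' An ordered, non-overlapping set of regions that tiles residues
#' `1..length(x)` exactly. Regions are stored as an [IRanges::IRanges] with a
#' `kind` metadata column (`"domain"`, `"linker"` or `"disordered"`). Domains
#' are implicitly numbered 1..n from the N- to the C-terminus by their order
#' of appearance; two domains may abut directly (a linker may shrink to
#' nothing during boundary adjustment).
#'
#' @slot proteinId character(1) chain identifier.
#' @slot length integer(1), number of residues L.
#' @slot regions [IRanges::IRanges] with `mcols(regions)$kind`.
#'
#' @seealso [spaedSegment()], [regions()], [formatChopping()]
#' @export
setClass("Segmentation",
  slots = c(
    proteinId = "character",
    length    = "integer",
    regions   = "IRanges"
  )
)

setValidity("Segmentation", function(object) {
  r <- object@regions
  L <- object@length
  if (length(L) != 1L || is.na(L) || L < 1L)
    return("length must be a positive integer")
  if (length(r) == 0L) return("segmentation has no regions")
  kind <- mcols(r)$kind
  if (is.null(kind) || !all(kind %in% .REGION_KINDS))
    return("every region needs kind domain/linker/disordered")
  s <- IRanges::start(r); e <- IRanges::end(r)
  if (s[1L] != 1L || e[length(r)] != L)
    return("regions must cover residues 1..L")
  if (length(r) > 1L && !all(s[-1L] == e[-length(r)] + 1L))
    return("regions must be sorted, contiguous and non-overlapping")
  TRUE
})

#' Construct a Segmentation
#'
#' @param proteinId chain identifier.
#' @param length number of residues L.
#' @param start,end 1-based inclusive region bounds (parallel vectors).
#' @param kind region kinds, `"domain"`, `"linker"` or `"disordered"`.
#' @return A [Segmentation-class] object.
#' @examples
#' Segmentation("toy", 100,
#'               start = c(1, 61, 69),
#'               end   = c(60, 68, 100),
#'               kind  = c("domain", "linker", "domain"))
#' @export
Segmentation <- function(proteinId, length, start, end, kind) {
  r <- IRanges(start = as.integer(start), end = as.integer(end))
  mcols(r)$kind <- as.character(kind)
  new("Segmentation", proteinId = as.character(proteinId),
      length = as.integer(length), regions = r)
}

# ---------------------------------------------------------------------------
# Architecture
# ---------------------------------------------------------------------------

#' Declared domain architecture for the synthetic PAE generator
#'
#' An ordered description of a (possibly multi-domain) chain: an optional
#' N-terminal disordered stretch, domains separated by linkers, and an
#' optional C-terminal disordered stretch. Element length bounds mirror what
#' is typical in modular proteins: domains 30-300 residues, linkers 3-30,
#' disordered termini 20-80.
#'
#' @slot elements data.frame with columns `kind` (one of `"domain"`,
#'   `"linker"`, `"disordered_n"`, `"disordered_c"`) and `length` (residues).
#' @slot seed integer(1) RNG seed used by [generatePae()].
#'
#' @seealso [randomArchitecture()], [generatePae()]
#' @export
setClass("Architecture",
  slots = c(elements = "data.frame", seed = "integer")
)

setValidity("Architecture", function(object) {
  el <- object@elements
  if (!all(c("kind", "length") %in% names(el)))
    return("elements needs columns kind and length")
  k <- el$kind; n <- nrow(el); len <- el$length
  if (!all(k %in% c("domain", "linker", "disordered_n", "disordered_c")))
    return("unknown element kind")
  if (!any(k == "domain")) return("architecture needs at least one domain")
  if (any(k == "disordered_n") &&
      (sum(k == "disordered_n") > 1L || k[1L] != "disordered_n"))
    return("disordered_n only allowed as the first element")
  if (any(k == "disordered_c") &&
      (sum(k == "disordered_c") > 1L || k[n] != "disordered_c"))
    return("disordered_c only allowed as the last element")
  lk <- which(k == "linker")
  if (length(lk) &&
      (any(lk == 1L) || any(lk == n) ||
       !all(k[lk - 1L] == "domain" & k[lk + 1L] == "domain")))
    return("linkers must sit between two domains")
  bad <- (k == "domain" & (len < 30 | len > 300)) |
         (k == "linker" & (len < 3 | len > 30)) |
         (k %in% c("disordered_n", "disordered_c") & (len < 20 | len > 80))
  if (any(bad)) return("element length outside the allowed range")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' Construct an Architecture
#'
#' @param kind character vector of element kinds (N- to C-terminal order).
#' @param length integer vector of element lengths in residues.
#' @param seed RNG seed consumed by [generatePae()].
#' @return An [Architecture-class] object.
#' @examples
#' Architecture(c("domain", "linker", "domain"), c(150, 8, 120), seed = 7)
#' @export
Architecture <- function(kind, length, seed = 1L) {
  new("Architecture",
      elements = data.frame(kind = as.character(kind),
                            length = as.integer(length)),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# EvalReport
# ---------------------------------------------------------------------------

#' Evaluation of a predicted segmentation against a reference
#'
#' Scores for one protein: the intersection-over-union (IoU) of matched
#' domain residue sets, the domain-boundary-distance (DBD) score, and the
#' boundary accuracy/sensitivity permissibility curves for distances
#' 0..maxDist residues.
#'
#' @slot proteinId character(1).
#' @slot iou,dbd numeric(1) in `[0, 1]`.
#' @slot accuracyAt,sensitivityAt named numeric vectors (names `"0"` ..
#'   `"maxDist"`), non-decreasing in the permissibility distance.
#' @slot nPredDomains,nRefDomains integer(1).
#'
#' @seealso [evaluateSegmentation()], [aggregateReports()]
#' @export
setClass("EvalReport",
  slots = c(
    proteinId     = "character",
    iou           = "numeric",
    dbd           = "numeric",
    accuracyAt    = "numeric",
    sensitivityAt = "numeric",
    nPredDomains  = "integer",
    nRefDomains   = "integer"
  )
)

setValidity("EvalReport", function(object) {
  for (s in c("iou", "dbd")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single value in [0, 1]", s))
  }
  if (length(object@accuracyAt) != length(object@sensitivityAt))
    return("curves must have matching lengths")
  if (is.unsorted(object@accuracyAt) || is.unsorted(object@sensitivityAt))
    return("curves must be non-decreasing in the permissibility distance")
  TRUE
})
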