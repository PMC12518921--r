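#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' @param x a [PaeMatrix-class] or [Segmentation-class] object.
#' @return `proteinId` returns the chain identifier; `paeValues` the raw
#'   numeric matrix; `isSymmetrized` the symmetrization flag; `regions` the
#'   [IRanges::IRanges] of regions (with a `kind` metadata column);
#'   `regionTable` a plain `data.frame` with columns `start`, `end`, `kind`;
#'   `nDomains` the number of domain regions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("paeValues", function(x) standardGeneric("paeValues"))

#' @rdname accessors
#' @export
setGeneric("isSymmetrized", function(x) standardGeneric("isSymmetrized"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname accessors
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))

#' Symmetrize a PAE matrix
#'
#' The raw PAE matrix is generally asymmetric (the expected error of residue
#' j under alignment on residue i differs from the converse). The
#' segmentation algorithm consumes the average of the matrix and its
#' transpose, \eqn{(\mathrm{pae} + \mathrm{pae}^T)/2}, which makes the
#' residue-pair error a single symmetric quantity. The operation is
#' idempotent and leaves the diagonal unchanged.
#'
#' @param x a [PaeMatrix-class].
#' @return A [PaeMatrix-class] with symmetric values and
#'   `isSymmetrized(x) == TRUE`.
#' @examples
#' p <- PaeMatrix(matrix(c(0, 4, 2, 0), 2, 2, byrow = TRUE))
#' paeValues(symmetrize(p))   # off-diagonal entries both (4+2)/2 = 3
#' @export
setGeneric("symmetrize", function(x) standardGeneric("symmetrize"))
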