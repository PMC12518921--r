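#' @include AllGenerics.R
NULL

# Reshape the flat (residue1, residue2, value) dialect into an L x L matrix.
.paeFromFlat <- function(obj) {
  vkey <- intersect(c("pae", "predicted_aligned_error", "distance"),
                    names(obj))
  vkey <- vkey[1L]
  r1 <- as.integer(obj$residue1)
  r2 <- as.integer(obj$residue2)
  vals <- as.numeric(obj[[vkey]])
  if (length(r1) != length(vals) || length(r2) != length(vals))
    stop("malformed PAE: index/value arrays of unequal length")
  L <- max(r1, r2)
  if (length(vals) != L * L)
    stop("malformed PAE: flat dialect does not cover all residue pairs")
  m <- matrix(NA_real_, L, L)
  m[cbind(r1, r2)] <- vals
  if (anyNA(m)) stop("malformed PAE: flat dialect does not cover all residue pairs")
  m
}

.asPaeMatrixValues <- function(x) {
  if (!is.matrix(x))
    stop("malformed PAE: matrix is ragged or not two-dimensional")
  if (nrow(x) != ncol(x)) stop("malformed PAE: matrix must be square")
  x
}

#' Read a PAE matrix from an AlphaFold-family JSON file
#'
#' Auto-detects the common JSON dialects, tried in this order:
#' \enumerate{
#'   \item an object with key `pae` holding an L x L array (ColabFold,
#'     AlphaFold3);
#'   \item an object -- possibly wrapped in a one-element list -- with key
#'     `predicted_aligned_error` holding an L x L array (AlphaFold DB / AF2);
#'   \item an object with flat arrays `residue1`, `residue2` and one of
#'     `pae`/`predicted_aligned_error`/`distance`, reshaped to L x L (older
#'     AlphaFold DB dialect).
#' }
#' Files with any other extension than `.json` are read as a plain
#' whitespace-delimited L x L matrix (a convenience for small fixtures).
#' Multi-chain inputs are accepted as one concatenated chain; the algorithm
#' is chain-agnostic.
#'
#' @param path path to the PAE file.
#' @param proteinId chain identifier; defaults to the file stem.
#' @return A [PaeMatrix-class] with `isSymmetrized(x) == FALSE`. Values are
#'   kept at the producer's precision (no rounding).
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"pae": [[0, 7], [5, 0]]}', f)
#' readPae(f)
#' @seealso [writePae()], [symmetrize()]
#' @export
readPae <- function(path, proteinId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(proteinId))
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  if (!grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    return(PaeMatrix(.asPaeMatrixValues(m), proteinId = proteinId))
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  # unwrap the one-element list some producers emit
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L)
    obj <- obj[[1L]]
  if (!is.list(obj) || is.null(names(obj)))
    stop("unrecognized PAE dialect in ", path)
  m <- if ("pae" %in% names(obj) && !("residue1" %in% names(obj))) {
    .asPaeMatrixValues(obj$pae)
  } else if ("predicted_aligned_error" %in% names(obj) &&
             !("residue1" %in% names(obj))) {
    .asPaeMatrixValues(obj$predicted_aligned_error)
  } else if (all(c("residue1", "residue2") %in% names(obj)) &&
             any(c("pae", "predicted_aligned_error", "distance") %in%
                 names(obj))) {
    .paeFromFlat(obj)
  } else {
    stop("unrecognized PAE dialect in ", path)
  }
  PaeMatrix(m, proteinId = proteinId)
}

#' Write a PAE matrix as ColabFold-style JSON
#'
#' Emits dialect `{"pae": [[...], ...]}` at full double precision, so that
#' a write/read round trip reproduces the matrix bit-for-bit. Used for
#' fixtures and regression tests.
#'
#' @param pae a [PaeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePae <- function(pae, path) {
  stopifnot(is(pae, "PaeMatrix"))
  # 17 significant digits guarantee an exact double round trip
  jsonlite::write_json(list(pae = pae@values), path, digits = I(17),
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname symmetrize
setMethod("symmetrize", "PaeMatrix", function(x) {
  v <- (x@values + t(x@values)) / 2
  new("PaeMatrix", proteinId = x@proteinId, values = v, symmetrized = TRUE)
})
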