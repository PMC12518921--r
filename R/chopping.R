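#' @include AllGenerics.R
NULL

#' Chopping strings: compact text encoding of a segmentation
#'
#' A chopping is a semicolon-separated list of `start-end:kind` fields,
#' 1-based inclusive, sorted and contiguous, covering the whole chain, e.g.
#' `"1-24:disordered;25-180:domain;181-188:linker;189-305:domain"`.
#' `formatChopping` and `parseChopping` are exact inverses on every valid
#' segmentation.
#'
#' @param seg a [Segmentation-class].
#' @return `formatChopping` returns character(1).
#' @examples
#' s <- Segmentation("x", 100, c(1, 61, 69), c(60, 68, 100),
#'                   c("domain", "linker", "domain"))
#' formatChopping(s)
#' identical(parseChopping(formatChopping(s), "x", 100), s)
#' @export
formatChopping <- function(seg) {
  stopifnot(is(seg, "Segmentation"))
  tab <- regionTable(seg)
  paste(sprintf("%d-%d:%s", tab$start, tab$end, tab$kind), collapse = ";")
}

#' @param chopping character(1) chopping string.
#' @param proteinId chain identifier for the parsed segmentation.
#' @param length chain length in residues (checked against the chopping).
#' @return `parseChopping` returns a [Segmentation-class].
#' @rdname formatChopping
#' @export
parseChopping <- function(chopping, proteinId, length) {
  fields <- strsplit(as.character(chopping), ";", fixed = TRUE)[[1L]]
  m <- regmatches(fields,
                  regexec("^([0-9]+)-([0-9]+):(domain|linker|disordered)$",
                          fields))
  if (any(vapply(m, base::length, integer(1)) != 4L))
    stop("malformed chopping: ", chopping)
  Segmentation(proteinId, length,
               start = vapply(m, function(x) as.integer(x[2L]), integer(1)),
               end   = vapply(m, function(x) as.integer(x[3L]), integer(1)),
               kind  = vapply(m, function(x) x[4L], character(1)))
}

#' Read and write chopping TSV files
#'
#' The tabular interchange format used by the batch front ends: a
#' tab-separated file with columns `protein_id`, `length`, `n_domains` and
#' `chopping` (see [formatChopping()]). TSV is used rather than CSV because
#' protein identifiers may contain commas.
#'
#' @param path file path.
#' @return `readChoppingTsv` returns a named list of
#'   [Segmentation-class] objects (names are protein ids).
#' @export
readChoppingTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character"))
  need <- c("protein_id", "length", "chopping")
  if (!all(need %in% names(tab)))
    stop("chopping TSV needs columns: ", paste(need, collapse = ", "))
  segs <- lapply(seq_len(nrow(tab)), function(i)
    parseChopping(tab$chopping[i], tab$protein_id[i], tab$length[i]))
  names(segs) <- tab$protein_id
  segs
}

#' @param segs list of [Segmentation-class] objects.
#' @rdname readChoppingTsv
#' @export
writeChoppingTsv <- function(segs, path) {
  tab <- data.frame(
    protein_id = vapply(segs, proteinId, character(1)),
    length = vapply(segs, base::length, integer(1)),
    n_domains = vapply(segs, nDomains, integer(1)),
    chopping = vapply(segs, formatChopping, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
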