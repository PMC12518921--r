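#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("proteinId", "PaeMatrix", function(x) x@proteinId)

#' @rdname accessors
setMethod("proteinId", "Segmentation", function(x) x@proteinId)

#' @rdname accessors
setMethod("paeValues", "PaeMatrix", function(x) x@values)

#' @rdname accessors
setMethod("isSymmetrized", "PaeMatrix", function(x) x@symmetrized)

#' @rdname accessors
setMethod("regions", "Segmentation", function(x) x@regions)

#' @rdname accessors
setMethod("regionTable", "Segmentation", function(x) {
  r <- x@regions
  data.frame(start = IRanges::start(r), end = IRanges::end(r),
             kind = mcols(r)$kind, stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("nDomains", "Segmentation", function(x) {
  sum(mcols(x@regions)$kind == "domain")
})

#' Number of residues
#'
#' `length` on a [PaeMatrix-class] or [Segmentation-class] is the number of
#' residues L of the chain; on [ResidueLabels-class] the number of labelled
#' residues.
#'
#' @param x the object.
#' @return integer(1).
#' @export
setMethod("length", "PaeMatrix", function(x) nrow(x@values))

#' @rdname length-PaeMatrix-method
#' @export
setMethod("length", "Segmentation", function(x) as.integer(x@length))

#' @rdname length-PaeMatrix-method
#' @export
setMethod("length", "ResidueLabels", function(x) length(x@tag))

setMethod("show", "PaeMatrix", function(object) {
  cat(sprintf("PaeMatrix '%s': %d x %d residues, %s\n",
              object@proteinId, nrow(object@values), ncol(object@values),
              if (object@symmetrized) "symmetrized" else "raw"))
  cat(sprintf("  PAE range: %.2f - %.2f Angstrom\n",
              min(object@values), max(object@values)))
})

setMethod("show", "SpaedParams", function(object) {
  cat("SpaedParams:\n")
  cat(sprintf("  maxClusterFraction:  %g\n", object@maxClusterFraction))
  cat(sprintf("  minDomainCluster:    %d\n", object@minDomainCluster))
  cat(sprintf("  terminalMergeLen:    %d\n", object@terminalMergeLen))
  cat(sprintf("  lowPae:              %g A\n", object@lowPae))
  cat(sprintf("  disorderNeighborMax: %d\n", object@disorderNeighborMax))
  cat(sprintf("  disorderFraction:    %g\n", object@disorderFraction))
  cat(sprintf("  linkerSupport:       %d\n", object@linkerSupport))
})

setMethod("show", "Segmentation", function(object) {
  tab <- regionTable(object)
  cat(sprintf("Segmentation '%s': %d residues, %d domain(s)\n",
              object@proteinId, object@length, nDomains(object)))
  d <- 0L
  for (i in seq_len(nrow(tab))) {
    lab <- tab$kind[i]
    if (lab == "domain") { d <- d + 1L; lab <- sprintf("domain %d", d) }
    cat(sprintf("  %5d-%5d  %s\n", tab$start[i], tab$end[i], lab))
  }
})

setMethod("show", "ResidueLabels", function(object) {
  cat(sprintf("ResidueLabels: %d residues\n", length(object@tag)))
  print(table(object@tag))
})

setMethod("show", "Architecture", function(object) {
  el <- object@elements
  cat(sprintf("Architecture: %d residues, seed %d\n",
              sum(el$length), object@seed))
  cat(" ", paste(sprintf("%s(%d)", el$kind, el$length), collapse = " - "),
      "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport '%s': IoU %.4f, DBD %.4f (%d pred / %d ref domains)\n",
              object@proteinId, object@iou, object@dbd,
              object@nPredDomains, object@nRefDomains))
  cat("  accuracy at 0..:   ",
      paste(sprintf("%.2f", object@accuracyAt), collapse = " "), "\n")
  cat("  sensitivity at 0..:",
      paste(sprintf("%.2f", object@sensitivityAt), collapse = " "), "\n")
})
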