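#' @include AllGenerics.R
NULL

.fmt4 <- function(x) formatC(x, format = "f", digits = 4)

#' Segment a PAE file or a folder of PAE files
#'
#' Reads every PAE file under `inputPath` (or the single file it names),
#' segments each chain with [spaedSegment()], and writes one row per protein
#' to a chopping TSV (columns `protein_id`, `length`, `n_domains`,
#' `chopping`), ordered lexicographically by protein id so repeated runs are
#' byte-identical. Per-protein failures (malformed files, chains too short)
#' are logged to standard error and skipped; they are fatal only when no
#' input could be processed at all.
#'
#' @param inputPath a PAE file or a directory of PAE files (`.json`, `.pae`
#'   or `.txt`; see [readPae()] for the dialects).
#' @param outputPath path of the TSV to write.
#' @param params a [SpaedParams-class].
#' @return Invisibly, the named list of [Segmentation-class] results.
#' @seealso [runEval()]
#' @export
runSegment <- function(inputPath, outputPath, params = SpaedParams()) {
  files <- if (dir.exists(inputPath)) {
    list.files(inputPath, pattern = "\\.(json|pae|txt)$", full.names = TRUE,
               ignore.case = TRUE)
  } else if (file.exists(inputPath)) {
    inputPath
  } else {
    character(0)
  }
  if (length(files) == 0L) stop("no readable inputs under ", inputPath)
  segs <- list()
  nFail <- 0L
  for (f in files) {
    seg <- tryCatch(spaedSegment(readPae(f), params), error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(seg)) nFail <- nFail + 1L
    else segs[[proteinId(seg)]] <- seg
  }
  if (length(segs) == 0L)
    stop("no readable inputs under ", inputPath)
  segs <- segs[order(names(segs), method = "radix")]
  writeChoppingTsv(segs, outputPath)
  message(sprintf("segmented %d protein(s), skipped %d", length(segs), nFail))
  invisible(segs)
}

#' Evaluate predicted choppings against reference choppings
#'
#' Scores every protein present in both TSVs with [evaluateSegmentation()]
#' and writes a report TSV: one row per protein plus `AGGREGATE_MEAN` and
#' `AGGREGATE_SD` rows (mean and population SD of IoU and DBD, curves
#' averaged per permissibility distance). Proteins present in only one file
#' are reported as skipped on standard error. Numbers are written with four
#' decimals so repeated runs are byte-identical.
#'
#' @param predTsv,refTsv chopping TSV paths (see [readChoppingTsv()]).
#' @param reportPath path of the evaluation TSV to write.
#' @param maxDist largest permissibility distance for the curves.
#' @return Invisibly, a list with `reports` (per-protein
#'   [EvalReport-class]), `aggregate` (see [aggregateReports()]) and
#'   `skipped` (ids present in only one input).
#' @export
runEval <- function(predTsv, refTsv, reportPath, maxDist = 7L) {
  preds <- readChoppingTsv(predTsv)
  refs <- readChoppingTsv(refTsv)
  shared <- sort(intersect(names(preds), names(refs)), method = "radix")
  skipped <- sort(c(setdiff(names(preds), names(refs)),
                    setdiff(names(refs), names(preds))), method = "radix")
  if (length(shared) == 0L)
    stop("no shared protein ids between ", predTsv, " and ", refTsv)
  reports <- list()
  for (id in shared) {
    er <- tryCatch(evaluateSegmentation(preds[[id]], refs[[id]], maxDist),
                   error = function(e) {
                     message("skipping ", id, ": ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(er)) reports[[id]] <- er
  }
  skipped <- c(skipped, setdiff(shared, names(reports)))
  if (length(reports) == 0L) stop("no comparable protein ids")
  agg <- aggregateReports(reports)
  dists <- as.integer(names(reports[[1L]]@accuracyAt))
  row <- function(id, npd, nrd, iou, dbd, acc, sen) {
    c(protein_id = id, n_pred_domains = npd, n_ref_domains = nrd,
      iou = .fmt4(iou), dbd = .fmt4(dbd),
      stats::setNames(.fmt4(acc), paste0("acc_", dists)),
      stats::setNames(.fmt4(sen), paste0("sens_", dists)))
  }
  rows <- lapply(reports, function(r)
    row(r@proteinId, r@nPredDomains, r@nRefDomains, r@iou, r@dbd,
        r@accuracyAt, r@sensitivityAt))
  rows <- c(rows, list(
    row("AGGREGATE_MEAN", "", "", agg$meanIou, agg$meanDbd,
        agg$accuracyAt, agg$sensitivityAt),
    row("AGGREGATE_SD", "", "", agg$sdIou, agg$sdDbd,
        rep(NA_real_, length(dists)), rep(NA_real_, length(dists)))))
  tab <- do.call(rbind, rows)
  utils::write.table(as.data.frame(tab, stringsAsFactors = FALSE),
                     reportPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(skipped))
    message("skipped (present in only one file or not comparable): ",
            paste(skipped, collapse = ", "))
  invisible(list(reports = reports, aggregate = agg, skipped = skipped))
}
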