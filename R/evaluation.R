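#' Sample-wise confusion counts between two masks
#'
#' Compares a predicted and a reference 0/1 mask element-wise; the
#' positive class is label 1 (inside an episode).
#'
#' @param pred,ref integer 0/1 masks of equal length.
#' @return Named list with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusionCounts <- function(pred, ref) {
  pred <- as.integer(pred)
  ref <- as.integer(ref)
  if (length(pred) != length(ref))
    stop("mask lengths differ: ", length(pred), " vs ", length(ref))
  if (any(!pred %in% c(0L, 1L)) || any(!ref %in% c(0L, 1L)))
    stop("mask labels must all be 0 or 1")
  list(tp = sum(pred == 1L & ref == 1L),
       fp = sum(pred == 1L & ref == 0L),
       tn = sum(pred == 0L & ref == 0L),
       fn = sum(pred == 0L & ref == 1L))
}

#' Segmentation metrics from confusion counts
#'
#' Computes sensitivity `Se = TP/(TP+FN)`, positive predictivity
#' `PP = TP/(TP+FP)`, specificity `Sp = TN/(TN+FP)`, negative
#' predictivity `NP = TN/(TN+FN)` and the Dice coefficient
#' `2*TP/(2*TP+FP+FN)`. A metric whose denominator is zero is reported
#' as `NA` (undefined), never as an error.
#'
#' @param counts a list as returned by [confusionCounts()].
#' @return Named numeric vector `c(se, pp, sp, np, dice)`, entries in
#'   \eqn{[0, 1]} or `NA`.
#' @examples
#' segMetrics(list(tp = 91, fp = 7, tn = 13, fn = 9))
#' @export
segMetrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, c(
    se = ratio(tp, tp + fn),
    pp = ratio(tp, tp + fp),
    sp = ratio(tn, tn + fp),
    np = ratio(tn, tn + fn),
    dice = ratio(2 * tp, 2 * tp + fp + fn)))
}

#' Dice coefficient of two masks
#'
#' Computed directly in vector form,
#' \eqn{2 \sum y_t y_p / \sum (y_t + y_p)}, which for 0/1 masks equals
#' `2*TP / (2*TP + FP + FN)`. When both masks are all-zero the
#' denominator vanishes and `NA` is returned.
#'
#' @param yt reference 0/1 mask.
#' @param yp predicted 0/1 mask, same length.
#' @return Dice coefficient in \eqn{[0, 1]}, or `NA`.
#' @export
diceCoefficient <- function(yt, yp) {
  yt <- as.numeric(yt)
  yp <- as.numeric(yp)
  if (length(yt) != length(yp))
    stop("mask lengths differ: ", length(yt), " vs ", length(yp))
  den <- sum(yt + yp)
  if (den == 0) return(NA_real_)
  2 * sum(yt * yp) / den
}

#' Evaluate a segmenter over a labelled corpus
#'
#' Applies `segmenter` to every record, compares the predicted masks with
#' the reference annotations, and reports both pooled (micro-averaged:
#' counts summed over all samples of all records, the headline figure)
#' and per-record macro-averaged metrics, plus a per-record table.
#' Records whose metric is undefined (zero denominator) are excluded from
#' the macro average, and their number is reported.
#'
#' @param segmenter a function mapping an [AudioRecord-class] to a 0/1
#'   mask, e.g. `dspSegment` or `function(r) predictMask(model, r)`.
#' @param corpus list of [AnnotatedRecord-class] objects.
#' @return List with elements `pooled` (named metric vector), `macro`
#'   (per-record mean of each metric over records where it is defined),
#'   `perRecord` (data frame of patient, side, diagnosis and metrics) and
#'   `nUndefined` (per-metric count of undefined records).
#' @export
evaluateCorpus <- function(segmenter, corpus) {
  if (length(corpus) == 0L) stop("corpus is empty")
  total <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  rows <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    ann <- corpus[[i]]
    stopifnot(is(ann, "AnnotatedRecord"))
    pred <- segmenter(audioRecord(ann))
    cc <- confusionCounts(pred, mask(ann))
    total <- Map(`+`, total, cc)
    met <- segMetrics(cc)
    rows[[i]] <- data.frame(patientId = patientId(ann), side = side(ann),
                            diagnosis = diagnosis(ann),
                            nSegmentsRef = length(maskToSegments(mask(ann))),
                            nSegmentsPred = length(maskToSegments(pred)),
                            t(met))
  }
  perRecord <- do.call(rbind, rows)
  metCols <- c("se", "pp", "sp", "np", "dice")
  macro <- vapply(metCols,
                  function(m) mean(perRecord[[m]], na.rm = TRUE), numeric(1))
  nUndef <- vapply(metCols,
                   function(m) sum(is.na(perRecord[[m]])), integer(1))
  list(pooled = segMetrics(total), macro = macro, perRecord = perRecord,
       nUndefined = nUndef)
}

#' Format corpus metrics as a comparison table
#'
#' Arranges pooled metrics of one or more evaluated methods as a data
#' frame with one row per metric (PP, Sp, Se, NP, Dice) and one column
#' per method — the layout conventionally used to compare segmentation
#' methods.
#'
#' @param ... named results of [evaluateCorpus()].
#' @param which `"pooled"` (default) or `"macro"`.
#' @return Data frame with a `Metric` column and one column per method.
#' @export
metricsTable <- function(..., which = c("pooled", "macro")) {
  which <- match.arg(which)
  results <- list(...)
  if (is.null(names(results)) || any(names(results) == ""))
    stop("every result must be named, e.g. metricsTable(dsp = res)")
  rowsOrder <- c(pp = "Positive Predictivity (PP)",
                 sp = "Specificity (Sp)",
                 se = "Sensitivity (Se)",
                 np = "Negative Predictivity (NP)",
                 dice = "Dice coefficient (Dice)")
  out <- data.frame(Metric = unname(rowsOrder))
  for (nm in names(results)) {
    v <- results[[nm]][[which]]
    out[[nm]] <- round(unname(v[names(rowsOrder)]), 4)
  }
  out
}
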