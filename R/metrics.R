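# population standard deviation (divisor n, not n - 1)
popSD <- function(x) sqrt(mean((x - mean(x))^2))

.checkMasks <- function(pred, true) {
  if (!identical(dim(pred), dim(true)))
    stop("mask shapes differ")
  list(p = pred != 0, t = true != 0)
}

#' Sample-wise intersection over union
#'
#' `|A & B| / |A | B|` for one predicted/true mask pair.  When both masks
#' are empty the score is 1 (perfect agreement on absence); when exactly
#' one is empty it is 0.
#'
#' @param pred,true binary masks (any 0/non-0 numeric or logical arrays
#'   of the same shape).
#' @return scalar in \[0, 1\].
#' @examples
#' iou(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))  # 1/3
#' @export
iou <- function(pred, true) {
  m <- .checkMasks(pred, true)
  inter <- sum(m$p & m$t)
  uni <- sum(m$p | m$t)
  if (uni == 0) 1 else inter / uni
}

#' Sample-wise Dice similarity coefficient
#'
#' `2 |A & B| / (|A| + |B|)`; both-empty pairs score 1, one-empty pairs 0.
#'
#' @inheritParams iou
#' @return scalar in \[0, 1\].
#' @export
dsc <- function(pred, true) {
  m <- .checkMasks(pred, true)
  denom <- sum(m$p) + sum(m$t)
  if (denom == 0) 1 else 2 * sum(m$p & m$t) / denom
}

#' Aggregate per-sample metrics into a report
#'
#' Every test sample enters with equal weight, so small targets count as
#' much as large ones; the summary statistics are the mean and the
#' population standard deviation of the sample-wise values.
#'
#' @param iouValues,dscValues numeric vectors of per-sample scores (equal
#'   length, at least one sample).
#' @return a [`MetricsReport-class`].
#' @export
aggregateMetrics <- function(iouValues, dscValues) {
  if (length(iouValues) < 1L)
    stop("at least one sample is required")
  new("MetricsReport", iou = iouValues, dsc = dscValues)
}

#' Summary statistics of a metrics report
#'
#' @param report a [`MetricsReport-class`].
#' @return list with `meanIoU`, `sdIoU`, `meanDSC`, `sdDSC`, `n`.
#' @export
metricsSummary <- function(report) {
  list(meanIoU = mean(report@iou), sdIoU = popSD(report@iou),
       meanDSC = mean(report@dsc), sdDSC = popSD(report@dsc),
       n = length(report@iou))
}

#' Evaluate a model on a set of samples
#'
#' Runs the model on each sample, binarizes the predicted probabilities at
#' `threshold`, and collects sample-wise IoU/DSC.
#'
#' @param model a [`HybridSegModel-class`].
#' @param samples list with arrays `x` `(H, W, 1, n)` and `y`
#'   `(H, W, 1, n)` (as from [stackSamples()]), or a list of
#'   [`SegmentationSample-class`] objects plus a `task`.
#' @param threshold binarization threshold for predictions (default 0.5).
#' @param batchSize forward-pass batch size.
#' @return a [`MetricsReport-class`].
#' @export
evaluateModel <- function(model, samples, threshold = 0.5, batchSize = 16L) {
  n <- dim(samples$x)[4]
  iouv <- numeric(n); dscv <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    prob <- segForward(model, samples$x[, , , idx, drop = FALSE])
    for (k in seq_along(idx)) {
      pm <- prob[, , 1, k] >= threshold
      tm <- samples$y[, , 1, idx[k]] != 0
      iouv[idx[k]] <- iou(pm, tm)
      dscv[idx[k]] <- dsc(pm, tm)
    }
  }
  aggregateMetrics(iouv, dscv)
}

#' Write per-sample metrics and a summary
#'
#' Writes one CSV row per sample (`sample`, `iou`, `dsc`) and a JSON
#' summary with the means and population standard deviations.
#'
#' @param report a [`MetricsReport-class`].
#' @param csvPath path of the per-sample CSV.
#' @param jsonPath optional path of the summary JSON.
#' @return invisibly, the summary list.
#' @export
writeMetrics <- function(report, csvPath, jsonPath = NULL) {
  df <- data.frame(sample = seq_along(report@iou),
                   iou = report@iou, dsc = report@dsc)
  utils::write.csv(df, csvPath, row.names = FALSE)
  s <- metricsSummary(report)
  if (!is.null(jsonPath))
    jsonlite::write_json(s, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(s)
}
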