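## Evaluation metrics from pixel confusion counts.

#' Pixel confusion counts of a predicted mask against ground truth
#'
#' @param pred,gt binary 0/1 matrices of identical dimensions.
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' pred <- matrix(0, 10, 10); pred[1:3, 1:3] <- 1
#' gt <- matrix(0, 10, 10); gt[1:3, 2:4] <- 1
#' confusionCounts(pred, gt) # TP=6 FP=3 FN=3 TN=88
#' @export
confusionCounts <- function(pred, gt) {
    if (!identical(dim(pred), dim(gt)))
        stop("pred and gt must have identical dimensions")
    .assertMask(pred, "pred"); .assertMask(gt, "gt")
    tp <- as.numeric(sum(pred == 1 & gt == 1))
    fp <- as.numeric(sum(pred == 1 & gt == 0))
    fn <- as.numeric(sum(pred == 0 & gt == 1))
    tn <- as.numeric(sum(pred == 0 & gt == 0))
    new("ConfusionCounts", tp = tp, tn = tn, fp = fp, fn = fn)
}

.safeRatio <- function(num, den) if (den > 0) num / den else NA_real_

#' Segmentation metrics from confusion counts
#'
#' Computes accuracy (TP+TN)/total, sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), Dice 2TP/(2TP+FN+FP) and IoU TP/(TP+FP+FN). Any ratio with a
#' zero denominator is undefined and reported as \code{NA}.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return A \linkS4class{MetricsReport}.
#' @examples
#' computeMetrics(new("ConfusionCounts", tp = 6, fp = 3, fn = 3, tn = 88))
#' @export
computeMetrics <- function(counts) {
    tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
    total <- tp + tn + fp + fn
    if (total <= 0) stop("all-zero confusion counts")
    new("MetricsReport",
        acc = .safeRatio(tp + tn, total),
        sen = .safeRatio(tp, tp + fn),
        spe = .safeRatio(tn, tn + fp),
        dic = .safeRatio(2 * tp, 2 * tp + fn + fp),
        iou = .safeRatio(tp, tp + fp + fn))
}

#' Metrics of a predicted mask against ground truth
#'
#' Convenience composition of \code{\link{confusionCounts}} and
#' \code{\link{computeMetrics}}.
#'
#' @inheritParams confusionCounts
#' @return A \linkS4class{MetricsReport}.
#' @export
maskMetrics <- function(pred, gt) computeMetrics(confusionCounts(pred, gt))

#' Write per-sample metrics reports to CSV
#'
#' One row per sample with columns sample_id, acc, sen, spe, dic, iou;
#' undefined metrics are written as empty cells.
#'
#' @param reports named list of \linkS4class{MetricsReport} objects (names are
#'   sample ids) or a data.frame with the report columns.
#' @param path output CSV path.
#' @return The data.frame written, invisibly.
#' @export
writeMetricsCsv <- function(reports, path) {
    df <- if (is.data.frame(reports)) reports else {
        rows <- lapply(reports, metricsVector)
        data.frame(sample_id = names(reports),
                   do.call(rbind, rows), row.names = NULL)
    }
    write.csv(df, path, row.names = FALSE, na = "")
    invisible(df)
}
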