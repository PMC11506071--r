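# Bundled reference confusion summaries.
#
# Two per-class confusion-matrix summaries published for a seven-class
# laryngeal segmentation evaluation (test splits of 300 and 1035 video
# frames; cells are per-image pixel counts averaged over the split, so
# TP+TN+FP+FN ~ 98,304 = 384 x 256 pixels). They serve as golden fixtures:
# applying this package's accuracy / precision / recall operations to the
# printed cells must reproduce the printed metric columns after rounding.

#' Load a bundled reference confusion summary
#'
#' @param split `"300"` or `"1035"`: which published test split to load.
#' @return Data frame with columns `Cls, Count, F1, TP, TN, FP, FN, ACC,
#'   IoU, bbIoU, mAUC, Precision, Recall` (one row per class, class 6
#'   first).
#' @export
#' @examples
#' ref <- reference_metrics("300")
#' accuracy(c(tp = ref$TP[1], tn = ref$TN[1], fp = ref$FP[1], fn = ref$FN[1]))
reference_metrics <- function(split = c("300", "1035")) {
  split <- match.arg(split)
  path <- system.file("extdata", paste0("reference_metrics_", split, ".csv"),
                      package = "larynet", mustWork = TRUE)
  utils::read.csv(path)
}
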