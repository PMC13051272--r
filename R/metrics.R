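# Confusion-matrix evaluation for binary canopy segmentation. Foreground
# (canopy, mask value 1) is the positive class; background metrics are
# computed symmetrically and the "m" variants are unweighted means over
# the two classes.

#' Pixel confusion matrix of a binary prediction
#'
#' @param pred,truth `H x W` matrices with values in `{0, 1}` (1 = canopy).
#' @return A `confusion_matrix` list with counts `tp`, `fn`, `fp`, `tn`
#'   summing to the number of evaluated pixels.
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    .err("prediction/truth shape mismatch", "canopyseg_contract_error")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    .err("confusion expects {0,1} masks", "canopyseg_contract_error")
  tp <- sum(pred == 1 & truth == 1)
  fn <- sum(pred == 0 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

# Merge per-sample confusion matrices by summing counts.
confusion_sum <- function(cms) {
  structure(list(tp = sum(vapply(cms, `[[`, 0, "tp")),
                 fn = sum(vapply(cms, `[[`, 0, "fn")),
                 fp = sum(vapply(cms, `[[`, 0, "fp")),
                 tn = sum(vapply(cms, `[[`, 0, "tn"))),
            class = "confusion_matrix")
}

.ratio <- function(num, den) if (den == 0) 1 else num / den

#' Segmentation metrics from a confusion matrix
#'
#' Per-class intersection-over-union (foreground `tp / (tp + fp + fn)`,
#' background symmetrically), pixel accuracy, precision and recall, plus
#' their unweighted two-class means. A class absent from both prediction
#' and truth (empty union) contributes the identity value 1; the report
#' flags when that convention fired.
#'
#' @param cm a [confusion()] result.
#' @return A `metrics_report` list: `iou_per_class`, `miou`, `pa`,
#'   `pa_per_class`, `mpa`, `precision_per_class`, `mprecision`,
#'   `recall_per_class`, `mrecall`, `absent_class`.
#' @export
compute_metrics <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n <= 0) .err("empty confusion matrix", "canopyseg_contract_error")
  iou_fg <- .ratio(cm$tp, cm$tp + cm$fp + cm$fn)
  iou_bg <- .ratio(cm$tn, cm$tn + cm$fn + cm$fp)
  pa <- (cm$tp + cm$tn) / n
  pa_fg <- .ratio(cm$tp, cm$tp + cm$fn)
  pa_bg <- .ratio(cm$tn, cm$tn + cm$fp)
  prec_fg <- .ratio(cm$tp, cm$tp + cm$fp)
  prec_bg <- .ratio(cm$tn, cm$tn + cm$fn)
  rec_fg <- .ratio(cm$tp, cm$tp + cm$fn)
  rec_bg <- .ratio(cm$tn, cm$tn + cm$fp)
  structure(list(
    iou_per_class = c(foreground = iou_fg, background = iou_bg),
    miou = (iou_fg + iou_bg) / 2,
    pa = pa,
    pa_per_class = c(foreground = pa_fg, background = pa_bg),
    mpa = (pa_fg + pa_bg) / 2,
    precision_per_class = c(foreground = prec_fg, background = prec_bg),
    mprecision = (prec_fg + prec_bg) / 2,
    recall_per_class = c(foreground = rec_fg, background = rec_bg),
    mrecall = (rec_fg + rec_bg) / 2,
    absent_class = c(foreground = (cm$tp + cm$fp + cm$fn) == 0,
                     background = (cm$tn + cm$fn + cm$fp) == 0)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> mIoU %.4f | PA %.4f | mPA %.4f | ",
                     "mPrec %.4f | mRec %.4f\n"),
              x$miou, x$pa, x$mpa, x$mprecision, x$mrecall))
  cat(sprintf("  IoU fg %.4f / bg %.4f\n",
              x$iou_per_class[1], x$iou_per_class[2]))
  invisible(x)
}

#' Mean per-pixel cross-entropy of 2-class logits against a binary mask
#'
#' Softmax over the two channels per pixel, then the mean of
#' `-log p(true class)`; always non-negative.
#'
#' @param logits `H x W x 2` array (channel 1 = background, 2 = canopy).
#' @param mask `H x W` matrix with values in `{0, 1}`.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(logits, mask) {
  ag_reset()
  on.exit(ag_reset())
  op_softmax_ce(logits, mask)$value
}
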