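# Global (whole-image) overlap metrics between a binary prediction and a
# binary ground truth: Dice, sensitivity, positive predictive value and the
# Jaccard index. Zero-denominator cases return NA ("undefined") rather than
# 0, so that "nothing to find" is distinguishable from "found nothing", and
# dataset averages skip undefined values.

check_binary <- function(m, what = "mask") {
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1)))
    stop(what, " must be binary (0/1); found values: ",
         paste(utils::head(setdiff(v, c(0, 1)), 5), collapse = ", "))
  invisible(TRUE)
}

#' Select classes of a label mask into a binary mask
#'
#' Maps a multi-class integer mask to 1 where its value lies in `class_ids`
#' and 0 elsewhere. This is how per-class evaluation masks (e.g. tumor core
#' as the union of label 1 and label 3) are formed.
#'
#' @param mask Integer array (2-D or 3-D); 0 is background.
#' @param class_ids Non-empty vector of class ids to select.
#' @return Binary array of the same shape.
#' @export
binarize <- function(mask, class_ids) {
  if (length(class_ids) == 0) stop("class_ids must be non-empty")
  out <- array(as.numeric(mask %in% class_ids), dim(mask) %||% length(mask))
  out
}

#' Pixelwise confusion counts
#'
#' @param pred,gt Binary arrays of identical shape.
#' @return Named numeric vector with elements `TP`, `FP`, `FN` satisfying
#'   `TP + FN = |gt|` and `TP + FP = |pred|`.
#' @export
confusion_counts <- function(pred, gt) {
  check_same_shape(pred, gt)
  check_binary(pred, "pred"); check_binary(gt, "gt")
  tp <- sum(pred * gt)
  c(TP = tp, FP = sum(pred) - tp, FN = sum(gt) - tp)
}

#' Dice coefficient
#'
#' `2 |pred n gt| / (|pred| + |gt|)`. Returns `NA` when both masks are
#' empty (undefined rather than a perfect score on lesion-free images).
#'
#' @param pred,gt Binary arrays of identical shape.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
dice <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  den <- 2 * cc["TP"] + cc["FP"] + cc["FN"]
  if (den == 0) return(NA_real_)
  unname(2 * cc["TP"] / den)
}

#' Sensitivity (recall): `TP / (TP + FN)`; `NA` when the ground truth is empty.
#' @inheritParams dice
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
sensitivity <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  if (cc["TP"] + cc["FN"] == 0) return(NA_real_)
  unname(cc["TP"] / (cc["TP"] + cc["FN"]))
}

#' Positive predictive value (precision): `TP / (TP + FP)`; `NA` when the
#' prediction is empty.
#' @inheritParams dice
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
ppv <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  if (cc["TP"] + cc["FP"] == 0) return(NA_real_)
  unname(cc["TP"] / (cc["TP"] + cc["FP"]))
}

#' Jaccard index (intersection over union); `NA` when both masks are empty.
#' @inheritParams dice
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
jaccard <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  den <- cc["TP"] + cc["FP"] + cc["FN"]
  if (den == 0) return(NA_real_)
  unname(cc["TP"] / den)
}

#' Full metric report for one binary mask pair
#'
#' @inheritParams dice
#' @return A one-row data frame with dice, ppv, sensitivity, jaccard and the
#'   TP/FP/FN pixel counts.
#' @export
evaluate_masks <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  data.frame(dice = dice(pred, gt), ppv = ppv(pred, gt),
             sensitivity = sensitivity(pred, gt), jaccard = jaccard(pred, gt),
             TP = unname(cc["TP"]), FP = unname(cc["FP"]),
             FN = unname(cc["FN"]))
}
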