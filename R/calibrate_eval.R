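# Per-class confidence-threshold calibration by dice maximization on a 0.01
# grid, and the multi-label evaluation suite: confusion matrix with the
# missed-label/false-positive attribution rule, mean-of-diagonal accuracy,
# per-class dice, multilocalization strata, co-occurrence and cell-line
# stratified summaries.

#' Dice coefficient of sample-level presence calls for one class
#'
#' `2*TP / (2*TP + FP + FN)`; identical to the per-class F1 score.  A class
#' never present and never predicted returns 0 (zero-denominator
#' convention, so absent rare classes are not inflated).
#'
#' @param predicted Binary vector of presence calls over samples.
#' @param truth Binary vector of true presence, same length.
#' @return Scalar in `[0, 1]`.
#' @export
dice_for_class <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  den <- 2 * tp + fp + fn
  if (den == 0) return(0)
  2 * tp / den
}

#' Calibrate per-class confidence thresholds by dice maximization
#'
#' For each class independently, every threshold on the grid 0.00, 0.01,
#' ..., 1.00 is tried; the one maximizing the dice coefficient of
#' `confidence >= threshold` against the truth is kept.  Ties resolve to
#' the smallest grid value.  Calibration is meant to be run on training
#' predictions only.
#'
#' @param confidences n x 13 matrix of confidences in `[0, 1]`.
#' @param truths n x 13 binary matrix.
#' @param grid_step Grid spacing (default 0.01).
#' @return Named numeric 13-vector of thresholds on the grid.
#' @export
calibrate_thresholds <- function(confidences, truths, grid_step = 0.01) {
  stopifnot(nrow(confidences) >= 1, all(dim(confidences) == dim(truths)))
  grid <- seq(0, 1, by = grid_step)
  th <- vapply(seq_len(ncol(confidences)), function(ci) {
    conf <- confidences[, ci]; tru <- truths[, ci]
    dice <- vapply(grid, function(t0)
      dice_for_class(as.integer(conf >= t0), tru), numeric(1))
    grid[which.max(dice)]   # which.max returns the first (smallest) maximizer
  }, numeric(1))
  nm <- colnames(confidences)
  if (is.null(nm) && ncol(confidences) == n_classes()) nm <- organelle_classes()
  setNames(th, nm)
}

#' Binarize confidences with per-class thresholds
#'
#' A class is called present when its confidence is greater than or equal
#' to its threshold (inclusive rule).
#'
#' @param confidences n x 13 confidence matrix.
#' @param thresholds 13-vector of per-class thresholds.
#' @return n x 13 binary matrix.
#' @export
apply_thresholds <- function(confidences, thresholds) {
  stopifnot(ncol(confidences) == length(thresholds))
  out <- t(t(confidences) >= thresholds) * 1L
  dimnames(out) <- dimnames(confidences)
  out
}

# Convert an n x 13 binary matrix to a list of class-code sets.
presence_to_sets <- function(mat) {
  cls <- colnames(mat) %||% organelle_classes()
  lapply(seq_len(nrow(mat)), function(i) cls[mat[i, ] > 0])
}

#' Multi-label confusion matrix
#'
#' For each sample with true set T and predicted set P: every correctly
#' found class (T intersect P) increments its diagonal cell; every missed
#' true class gets one hit from every predicted false positive.  Rows are
#' normalized by the number of samples containing the true class, so the
#' diagonal reads as the fraction of samples of a class in which that class
#' was found; rows need not sum to 1.
#'
#' @param true_sets,predicted_sets Equal-length lists of class-code
#'   character vectors (see [presence_to_sets()]).
#' @return List of class `protloc_confusion` with `counts`, `row_totals`
#'   and `normalized` (13 x 13).
#' @export
multilabel_confusion <- function(true_sets, predicted_sets) {
  if (!length(true_sets)) stop("empty sample list")
  if (length(true_sets) != length(predicted_sets)) stop("length mismatch")
  cls <- organelle_classes()
  counts <- matrix(0, 13, 13, dimnames = list(true = cls, predicted = cls))
  row_totals <- setNames(numeric(13), cls)
  for (i in seq_along(true_sets)) {
    T0 <- true_sets[[i]]; P0 <- predicted_sets[[i]]
    row_totals[T0] <- row_totals[T0] + 1
    for (c0 in intersect(T0, P0)) counts[c0, c0] <- counts[c0, c0] + 1
    missed <- setdiff(T0, P0); false_pos <- setdiff(P0, T0)
    for (c0 in missed) for (c1 in false_pos)
      counts[c0, c1] <- counts[c0, c1] + 1
  }
  normalized <- counts / ifelse(row_totals > 0, row_totals, NA)
  structure(list(counts = counts, row_totals = row_totals,
                 normalized = normalized), class = "protloc_confusion")
}

#' Unweighted mean of the normalized confusion diagonal
#'
#' Classes absent from the truth (row total 0) are dropped from the mean
#' with a warning.
#'
#' @param confusion A `protloc_confusion` from [multilabel_confusion()].
#' @return Scalar class-average accuracy in `[0, 1]`.
#' @export
mean_diag_accuracy <- function(confusion) {
  keep <- confusion$row_totals > 0
  if (!any(keep)) stop("no class present in the truth")
  if (!all(keep))
    warning("classes absent from truth excluded from the mean: ",
            paste(names(which(!keep)), collapse = ", "))
  mean(diag(confusion$normalized)[keep])
}

#' Correct-classification fraction stratified by localization count
#'
#' Samples are grouped by how many classes they truly contain (1-4).  Under
#' the default `"exact"` rule a sample is correct when the predicted set
#' equals the true set; `"all_found"` instead requires every true class to
#' be retrieved (false positives allowed).
#'
#' @param true_sets,predicted_sets Lists of class-code vectors.
#' @param rule `"exact"` or `"all_found"`.
#' @return Data frame with `k`, `n`, `correct`, `fraction` (NA for empty
#'   strata).
#' @export
accuracy_by_multiloc <- function(true_sets, predicted_sets,
                                 rule = c("exact", "all_found")) {
  rule <- match.arg(rule)
  ks <- vapply(true_sets, length, integer(1))
  ok <- vapply(seq_along(true_sets), function(i) {
    T0 <- true_sets[[i]]; P0 <- predicted_sets[[i]]
    if (rule == "exact") setequal(T0, P0) else all(T0 %in% P0)
  }, logical(1))
  out <- data.frame(k = 1:4, n = 0L, correct = 0L, fraction = NA_real_)
  for (k in 1:4) {
    sel <- ks == k
    out$n[k] <- sum(sel)
    out$correct[k] <- sum(ok[sel])
    if (out$n[k] > 0) out$fraction[k] <- out$correct[k] / out$n[k]
  }
  out
}

#' Class co-occurrence matrix
#'
#' Entry (r, c) is the fraction of samples containing class r that also
#' contain class c; the diagonal is 1 for every represented class.
#'
#' @param true_sets List of class-code vectors.
#' @return 13 x 13 numeric matrix (rows of unrepresented classes are NA).
#' @export
cooccurrence_matrix <- function(true_sets) {
  if (!length(true_sets)) stop("empty sample list")
  cls <- organelle_classes()
  both <- matrix(0, 13, 13, dimnames = list(cls, cls))
  for (s in true_sets)
    both[s, s] <- both[s, s] + 1
  n_with <- diag(both)
  both / ifelse(n_with > 0, n_with, NA)
}

#' Cell-line-stratified mean dice
#'
#' Thresholded predictions are scored per group: for each of the
#' `n_major` most frequent group tags (and one pooled `"other"` group for
#' the rest), the unweighted mean over classes of [dice_for_class()]
#' restricted to that group's samples.  Classes absent from a group's truth
#' and never predicted there contribute 0 by the dice convention; classes
#' absent from the whole evaluation truth are dropped.
#'
#' @param confidences n x 13 confidence matrix.
#' @param truths n x 13 binary matrix.
#' @param thresholds 13-vector of calibrated thresholds.
#' @param group_tags Character vector of per-sample group labels
#'   (cell-line tags).
#' @param n_major Number of majority groups reported separately.
#' @return Named numeric vector of per-group mean dice.
#' @export
groupwise_dice <- function(confidences, truths, thresholds, group_tags,
                           n_major = 3) {
  if (length(group_tags) != nrow(confidences))
    stop("group_tags must align with samples")
  pred <- apply_thresholds(confidences, thresholds)
  tab <- sort(table(group_tags), decreasing = TRUE)
  major <- names(tab)[seq_len(min(n_major, length(tab)))]
  groups <- ifelse(group_tags %in% major, group_tags, "other")
  level_order <- c(major, if (any(groups == "other")) "other")
  keep_cls <- colSums(truths) > 0
  vapply(level_order, function(g0) {
    sel <- groups == g0
    mean(vapply(which(keep_cls), function(ci)
      dice_for_class(pred[sel, ci], truths[sel, ci]), numeric(1)))
  }, numeric(1))
}

#' Full evaluation report
#'
#' Bundles the multi-label confusion matrix, per-class dice, class-average
#' accuracy, mean dice, multilocalization strata and co-occurrence, plus
#' cell-line-stratified dice when group tags are supplied.
#'
#' @param confidences n x 13 confidence matrix for the evaluated split.
#' @param truths n x 13 binary truth matrix.
#' @param thresholds Calibrated 13-vector (from the training split).
#' @param group_tags Optional per-sample cell-line tags.
#' @return Object of class `protloc_eval_report`.
#' @export
evaluate_predictions <- function(confidences, truths, thresholds,
                                 group_tags = NULL) {
  pred <- apply_thresholds(confidences, thresholds)
  true_sets <- presence_to_sets(truths)
  pred_sets <- presence_to_sets(pred)
  confusion <- multilabel_confusion(true_sets, pred_sets)
  keep <- colSums(truths) > 0
  per_class_dice <- setNames(rep(NA_real_, n_classes()), organelle_classes())
  for (ci in which(keep))
    per_class_dice[ci] <- dice_for_class(pred[, ci], truths[, ci])
  rep_out <- list(
    confusion = confusion,
    per_class_dice = per_class_dice,
    mean_dice = mean(per_class_dice[keep]),
    mean_diag_accuracy = suppressWarnings(mean_diag_accuracy(confusion)),
    by_multiloc = accuracy_by_multiloc(true_sets, pred_sets),
    cooccurrence = cooccurrence_matrix(true_sets),
    thresholds = thresholds)
  if (!is.null(group_tags))
    rep_out$by_group_dice <- groupwise_dice(confidences, truths, thresholds,
                                            group_tags)
  structure(rep_out, class = "protloc_eval_report")
}

#' Write an evaluation report as JSON plus CSV matrices
#' @param report A `protloc_eval_report`.
#' @param out_dir Directory for `eval_report.json`,
#'   `confusion_normalized.csv` and `cooccurrence.csv`.
#' @export
write_eval_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    mean_diag_accuracy = report$mean_diag_accuracy,
    mean_dice = report$mean_dice,
    per_class_dice = as.list(report$per_class_dice),
    thresholds = as.list(report$thresholds),
    by_multiloc = report$by_multiloc,
    by_group_dice = if (!is.null(report$by_group_dice))
      as.list(report$by_group_dice))
  jsonlite::write_json(json, file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(report$confusion$normalized,
            file.path(out_dir, "confusion_normalized.csv"))
  write.csv(report$cooccurrence, file.path(out_dir, "cooccurrence.csv"))
  invisible(out_dir)
}
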