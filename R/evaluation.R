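#' Pixel-level evaluation
#'
#' Confusion counting against ground-truth masks, the four standard metrics
#' (detection rate TPR, false-alarm rate FPR, precision, and their
#' harmonic-mean summary F-score), unweighted per-image averaging, a
#' 50-threshold ROC curve with trapezoidal AUC, and the error-overlay
#' rendering (false negatives red, false positives blue, true negatives
#' white, true positives in their original color).
#'
#' Degenerate denominators follow a fixed policy: an image without skin
#' pixels contributes no TPR/F-score to the averages (it is excluded rather
#' than fabricated from 0/0); precision is defined as 0 when nothing was
#' predicted positive.
#'
#' @name evaluation
NULL

#' Pixel confusion counts between predicted and true masks
#'
#' @param pred,truth `H x W` 0/1 matrices of equal dimensions.
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN`; the four
#'   counts partition the pixels.
#' @export
confusion <- function(pred, truth) {
  check_mask(pred, what = "pred")
  check_mask(truth, what = "truth")
  if (!all(dim(pred) == dim(truth)))
    stopf("pred (%d x %d) and truth (%d x %d) dimensions differ",
          nrow(pred), ncol(pred), nrow(truth), ncol(truth))
  structure(list(TP = sum(pred == 1 & truth == 1),
                 FP = sum(pred == 1 & truth == 0),
                 FN = sum(pred == 0 & truth == 1),
                 TN = sum(pred == 0 & truth == 0)),
            class = "confusion_counts")
}

#' Detection metrics from confusion counts
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`,
#' `precision = TP / (TP + FP)` (0 when nothing predicted positive), and
#' `F = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and TPR.
#' `TPR` and `f_score` are `NA` for an image without skin pixels.
#'
#' @param counts A `confusion_counts` (or list with `TP`, `FP`, `FN`, `TN`).
#' @return A `metric_set` list: `TPR`, `FPR`, `precision`, `f_score`.
#' @export
metrics <- function(counts) {
  with(counts, {
    n_s <- TP + FN
    n_ns <- FP + TN
    structure(list(
      TPR = if (n_s > 0) TP / n_s else NA_real_,
      FPR = if (n_ns > 0) FP / n_ns else NA_real_,
      precision = if (TP + FP > 0) TP / (TP + FP) else 0,
      f_score = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN)
                else NA_real_),
      class = "metric_set")
  })
}

#' Unweighted mean of per-image metric sets
#'
#' Images whose metric is undefined (`NA`, e.g. TPR of a skin-free image)
#' are excluded from that metric's mean; exclusions are reported in the
#' `n_used` attribute.
#'
#' @param per_image Non-empty list of `metric_set`s.
#' @return A `metric_set` of arithmetic means.
#' @export
average_over_images <- function(per_image) {
  if (!is.list(per_image) || length(per_image) == 0L)
    stopf("need a non-empty list of metric sets")
  if (inherits(per_image, "metric_set")) per_image <- list(per_image)
  fields <- c("TPR", "FPR", "precision", "f_score")
  out <- list()
  used <- integer(0)
  for (f in fields) {
    v <- vapply(per_image, function(m) as.numeric(m[[f]]), numeric(1))
    keep <- !is.na(v)
    if (!any(keep))
      stopf("metric %s is undefined for every image", f)
    out[[f]] <- mean(v[keep])
    used[f] <- sum(keep)
  }
  structure(out, class = "metric_set", n_used = used)
}

#' ROC curve over classification thresholds
#'
#' Posteriors are computed once per test image; TPR and FPR are averaged
#' over images at each of `n_thresholds` equally spaced thresholds spanning
#' `[0, 1]` (endpoints included). AUC integrates TPR over FPR by the
#' trapezoidal rule with `(0,0)` and `(1,1)` anchors appended.
#'
#' @param model A `skin_model`.
#' @param pairs List of `list(image =, mask =)` test pairs.
#' @param space Feature space (see [predict_mask()]).
#' @param n_thresholds Number of thresholds (default 50).
#' @return A `roc_curve`: `thresholds`, `tpr`, `fpr` (per threshold,
#'   image-averaged) and `auc`.
#' @export
roc_curve <- function(model, pairs, space, n_thresholds = 50L) {
  if (!is.list(pairs) || length(pairs) == 0L) stopf("empty test set")
  thresholds <- seq(1, 0, length.out = n_thresholds)
  tpr_m <- matrix(NA_real_, length(pairs), n_thresholds)
  fpr_m <- matrix(NA_real_, length(pairs), n_thresholds)
  for (i in seq_along(pairs)) {
    img <- pairs[[i]]$image %||% pairs[[i]][[1]]
    msk <- pairs[[i]]$mask %||% pairs[[i]][[2]]
    check_mask(msk, img)
    post <- posterior_map(model, img, space)
    truth <- as.vector(msk)
    p <- as.vector(post)
    n_s <- sum(truth == 1)
    n_ns <- sum(truth == 0)
    for (t in seq_len(n_thresholds)) {
      hit <- p >= thresholds[t]
      if (n_s > 0) tpr_m[i, t] <- sum(hit & truth == 1) / n_s
      if (n_ns > 0) fpr_m[i, t] <- sum(hit & truth == 0) / n_ns
    }
  }
  tpr <- colMeans(tpr_m, na.rm = TRUE)
  fpr <- colMeans(fpr_m, na.rm = TRUE)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = trapezoid_auc(fpr, tpr)),
            class = "roc_curve")
}

# Trapezoidal area under (fpr, tpr) sorted by fpr, anchored at (0,0), (1,1).
trapezoid_auc <- function(fpr, tpr) {
  ok <- is.finite(fpr) & is.finite(tpr)
  x <- c(0, fpr[ok], 1)
  y <- c(0, tpr[ok], 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Overlay prediction errors on an image
#'
#' Correctly detected skin keeps its original color; false negatives are
#' painted pure red, false positives pure blue, and true negatives white.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param pred,truth `H x W` 0/1 masks.
#' @return An `H x W x 3` annotated RGB array.
#' @export
annotate_errors <- function(image, pred, truth) {
  check_rgb_image(image)
  check_mask(pred, image, what = "pred")
  check_mask(truth, image, what = "truth")
  out <- image
  fn <- pred == 0 & truth == 1
  fp <- pred == 1 & truth == 0
  tn <- pred == 0 & truth == 0
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[fn] <- if (ch == 1) 1 else 0
    plane[fp] <- if (ch == 3) 1 else 0
    plane[tn] <- 1
    out[, , ch] <- plane
  }
  out
}

#' Evaluate a model image-by-image on test pairs
#'
#' Runs [predict_mask()] on every pair and returns the per-image metric
#' sets alongside their unweighted average.
#'
#' @inheritParams roc_curve
#' @param threshold Posterior threshold (default 0.5).
#' @return List with `per_image` (list of `metric_set`) and `average`.
#' @export
evaluate_pairs <- function(model, pairs, space, threshold = 0.5) {
  if (!is.list(pairs) || length(pairs) == 0L) stopf("empty test set")
  per_image <- lapply(pairs, function(p) {
    img <- p$image %||% p[[1]]
    msk <- p$mask %||% p[[2]]
    metrics(confusion(predict_mask(model, img, space, threshold), msk))
  })
  list(per_image = per_image, average = average_over_images(per_image))
}
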