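#' ROC curve over labeled fatigue scores
#'
#' Builds the receiver operating characteristic of the combined deviation
#' `D_C` as a fatigue classifier: for every distinct score used as a
#' candidate threshold `t`, an epoch is called fatigued when its score is
#' strictly greater than `t`. The area under the curve is computed by the
#' trapezoid rule and equals the Mann-Whitney pair statistic (ties counted
#' one half).
#'
#' @param scores numeric vector of per-epoch `D_C` values.
#' @param labels vector of class labels, coercible to factor with levels
#'   `alert` (negative) and `fatigued` (positive).
#' @return an `roc_curve` object: data.frame `points` with columns
#'   `threshold`, `tpr`, `fpr` (thresholds descending from `+Inf`), plus
#'   `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c("alert", "alert", "fatigued", "fatigued"))$auc
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.character(labels)
  ok <- labels %in% c("alert", "fatigued")
  if (!all(ok)) stop("labels must be 'alert' or 'fatigued'")
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- scores[labels == "fatigued"]
  neg <- scores[labels == "alert"]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be present to build an ROC curve")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  pts <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f (%d fatigued / %d alert)\n",
              nrow(x$points), x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Select the fatigue alarm threshold
#'
#' Either the Youden operating point (the candidate threshold maximizing
#' `TPR - FPR`, ties broken toward the lowest threshold) or a fixed value.
#' The package default fixed threshold is 6.0, the operating point used by
#' the monitoring pipeline when no calibration data are supplied.
#'
#' @param roc an [roc_curve()] (required for `method = "youden"`).
#' @param method `"youden"` or `"fixed"`.
#' @param fixed_value threshold used when `method = "fixed"` (default 6.0).
#' @return the selected threshold (scalar), with attribute `method`.
#' @export
select_threshold <- function(roc = NULL, method = c("youden", "fixed"),
                             fixed_value = 6.0) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value) || !is.finite(fixed_value)) {
      stop("`fixed_value` must be given for method = 'fixed'")
    }
    return(structure(fixed_value, method = "fixed"))
  }
  if (!inherits(roc, "roc_curve")) stop("`roc` must be an roc_curve object")
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  j <- pts$tpr - pts$fpr
  best <- which(j >= max(j) - 1e-12)
  thr <- min(pts$threshold[best])            # ties -> lowest threshold
  structure(thr, method = "youden", youden_j = max(j))
}

#' Fatigue alarm decision
#'
#' Fatigue is declared when the combined deviation is strictly greater than
#' the threshold; a score exactly at the threshold does not alarm.
#'
#' @param d_c combined deviation value(s), or a `fatigue_scores` frame.
#' @param threshold alarm threshold (default 6.0).
#' @return logical vector of alarm decisions.
#' @examples
#' detect_fatigue(c(5.9, 6.0, 6.1), threshold = 6.0)
#' @export
detect_fatigue <- function(d_c, threshold = 6.0) {
  if (is.data.frame(d_c)) d_c <- d_c$d_c
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  d_c > threshold
}
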