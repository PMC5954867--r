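#' Fit the alert-state baseline model
#'
#' Characterizes the alert state by the sample mean and a shrunk sample
#' covariance of the theta- and alpha-band feature vectors over artifact-free
#' alert epochs: `mu_theta`, `N` for the theta band and `mu_alpha`, `C` for
#' the alpha band. Shrinkage pulls the covariance toward its own diagonal,
#' `(1 - lambda) S + lambda diag(S)`, which keeps the matrix invertible when
#' the baseline has few epochs; a tiny absolute ridge is always added so the
#' model is positive-definite even for degenerate (constant) baselines.
#'
#' @param features a `band_features` data.frame (see [extract_features()])
#'   of alert epochs; at least 2 rows.
#' @param shrinkage shrinkage weight lambda in `[0, 1]` (default 0.1).
#' @return a `baseline_model`: list with `mu_alpha`, `C`, `mu_theta`, `N`,
#'   `shrinkage`, `n_epochs_used`.
#' @export
fit_baseline <- function(features, shrinkage = 0.1) {
  if (!is.data.frame(features)) stop("`features` must be a band_features frame")
  if (nrow(features) < 2) {
    stop("insufficient baseline: need >= 2 alert epochs, got ", nrow(features))
  }
  if (shrinkage < 0 || shrinkage > 1) stop("`shrinkage` must lie in [0, 1]")
  shrink_cov <- function(M) {
    S <- stats::cov(M)
    Sh <- (1 - shrinkage) * S + shrinkage * diag(diag(S), nrow(S))
    ridge <- 1e-8 * max(1, mean(diag(S)))
    Sh + diag(ridge, nrow(S))
  }
  Xa <- as.matrix(features[, feature_cols(features, "alpha"), drop = FALSE])
  Xt <- as.matrix(features[, feature_cols(features, "theta"), drop = FALSE])
  structure(list(
    mu_alpha = colMeans(Xa), C = shrink_cov(Xa),
    mu_theta = colMeans(Xt), N = shrink_cov(Xt),
    shrinkage = shrinkage, n_epochs_used = nrow(features)
  ), class = "baseline_model")
}

#' Mahalanobis distance of a feature vector from a baseline distribution
#'
#' Computes `sqrt((x - mu)' cov^{-1} (x - mu))`: the covariance-weighted
#' deviation of an observed spectral feature vector from the alert-state
#' mean. Unitless; zero iff `x == mu`.
#'
#' @param x numeric feature vector.
#' @param mu mean vector of the same length.
#' @param cov positive-definite covariance matrix.
#' @return the distance (a non-negative scalar).
#' @examples
#' mahalanobis_distance(c(2, 1), c(0, 0), diag(c(2, 1)))  # sqrt(3)
#' @export
mahalanobis_distance <- function(x, mu, cov) {
  x <- as.numeric(x); mu <- as.numeric(mu)
  if (length(x) != length(mu) || length(x) != nrow(cov) ||
      nrow(cov) != ncol(cov)) {
    stop("dimension mismatch between `x`, `mu` and `cov`")
  }
  ch <- tryCatch(chol(cov), error = function(e) {
    stop(sprintf(
      "covariance is not positive-definite (condition number %.3g)",
      kappa(cov)))
  })
  d <- x - mu
  # quadratic form via the Cholesky factor: ||L^{-T} d||
  z <- backsolve(ch, d, transpose = TRUE)
  sqrt(sum(z^2))
}

#' Combined fatigue deviation
#'
#' The convex combination of the alpha- and theta-band Mahalanobis
#' deviations, `D_C = sigma * D_alpha + (1 - sigma) * D_theta`, with
#' `0 <= sigma <= 1`. The combined statistic always lies between the two
#' band deviations.
#'
#' @param d_alpha,d_theta non-negative band deviations.
#' @param sigma weight on the alpha band, in `[0, 1]` (default 0.5).
#' @return the combined deviation.
#' @export
combined_deviation <- function(d_alpha, d_theta, sigma = 0.5) {
  if (any(sigma < 0 | sigma > 1)) stop("`sigma` must lie in [0, 1]")
  if (any(d_alpha < 0) || any(d_theta < 0)) stop("distances must be >= 0")
  sigma * d_alpha + (1 - sigma) * d_theta
}

#' Score epochs against the alert baseline
#'
#' For each epoch's feature vector, computes the alpha- and theta-band
#' Mahalanobis deviations from the baseline and the combined statistic
#' `D_C` (see [combined_deviation()]). Large `D_C` indicates spectra that
#' have drifted away from the alert state.
#'
#' @param features a `band_features` data.frame (one or more epochs).
#' @param baseline a [fit_baseline()] model.
#' @param sigma alpha-band weight in `[0, 1]` (default 0.5).
#' @return a `fatigue_scores` data.frame: `epoch`, `d_alpha`, `d_theta`,
#'   `sigma`, `d_c`.
#' @export
score_epochs <- function(features, baseline, sigma = 0.5) {
  stopifnot(inherits(baseline, "baseline_model"))
  if (sigma < 0 || sigma > 1) stop("`sigma` must lie in [0, 1]")
  ca <- feature_cols(features, "alpha")
  ct <- feature_cols(features, "theta")
  if (length(ca) != length(baseline$mu_alpha) ||
      length(ct) != length(baseline$mu_theta)) {
    stop("feature dimensions do not match the baseline model")
  }
  out <- data.frame(
    epoch = features$epoch,
    d_alpha = apply(features[, ca, drop = FALSE], 1, mahalanobis_distance,
                    mu = baseline$mu_alpha, cov = baseline$C),
    d_theta = apply(features[, ct, drop = FALSE], 1, mahalanobis_distance,
                    mu = baseline$mu_theta, cov = baseline$N)
  )
  out$sigma <- sigma
  out$d_c <- combined_deviation(out$d_alpha, out$d_theta, sigma)
  class(out) <- c("fatigue_scores", "data.frame")
  out
}

#' Serialize / restore a baseline model as JSON
#'
#' The JSON schema stores the per-band means, covariance matrices
#' (row-major), shrinkage and dimensions, so a baseline calibrated once can
#' be reused across monitoring sessions.
#'
#' @param baseline a `baseline_model`.
#' @param path file path.
#' @return `write_baseline`: `path` invisibly; `read_baseline`: the model.
#' @export
write_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "baseline_model"))
  obj <- list(
    dims = length(baseline$mu_alpha),
    mu_alpha = unname(baseline$mu_alpha), C = unname(baseline$C),
    mu_theta = unname(baseline$mu_theta), N = unname(baseline$N),
    shrinkage = baseline$shrinkage, n_epochs_used = baseline$n_epochs_used,
    feature_names_alpha = names(baseline$mu_alpha),
    feature_names_theta = names(baseline$mu_theta)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mu_alpha = stats::setNames(as.numeric(obj$mu_alpha),
                               obj$feature_names_alpha),
    C = matrix(unlist(obj$C), nrow = obj$dims),
    mu_theta = stats::setNames(as.numeric(obj$mu_theta),
                               obj$feature_names_theta),
    N = matrix(unlist(obj$N), nrow = obj$dims),
    shrinkage = obj$shrinkage, n_epochs_used = obj$n_epochs_used
  ), class = "baseline_model")
}

#' Exponentially smooth fatigue scores over epochs
#'
#' Per-epoch band spectra from short windows carry few spectral degrees of
#' freedom, so instantaneous deviations are noisy; a real-time monitor
#' therefore tracks an exponentially weighted moving average,
#' `y[t] = lambda * x[t] + (1 - lambda) * y[t - 1]`. Smoothing is linear, so
#' the identity `d_c = sigma * d_alpha + (1 - sigma) * d_theta` is preserved
#' row by row. `lambda = 1` disables smoothing.
#'
#' @param scores a `fatigue_scores` frame from [score_epochs()], or a
#'   numeric vector of `D_C` values.
#' @param lambda weight on the current epoch, in `(0, 1]` (default 0.5,
#'   i.e. a mean lag of one epoch).
#' @return the smoothed scores, same shape as the input.
#' @export
smooth_scores <- function(scores, lambda = 0.5) {
  if (lambda <= 0 || lambda > 1) stop("`lambda` must lie in (0, 1]")
  sm <- function(x) {
    y <- x
    if (length(x) > 1) {
      for (i in 2:length(x)) y[i] <- lambda * x[i] + (1 - lambda) * y[i - 1]
    }
    y
  }
  if (is.numeric(scores)) return(sm(scores))
  stopifnot(is.data.frame(scores))
  for (col in c("d_alpha", "d_theta", "d_c")) scores[[col]] <- sm(scores[[col]])
  scores
}
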