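#' Ordinary least-squares fit of one learning-curve phase
#'
#' Fits `value ~ trial` by OLS over an inclusive trial range of a trial
#' series (errors, completion time, or perceived fatigue per trial) and
#' reports slope, intercept and R-squared. On noise-free linear data the fit
#' is exact and R-squared is 1. When the responses have zero variance,
#' R-squared is defined as 1 if the residuals are all zero (a constant series
#' is fit perfectly by a flat line).
#'
#' @param series a `trial_series` data.frame with columns `trial`, `value`
#'   (see [simulate_trials()]), or any data.frame with those columns.
#' @param start,end 1-based inclusive trial range; defaults to the full
#'   series.
#' @return a `phase_fit`: list with `start_trial`, `end_trial`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @examples
#' ph <- data.frame(start = 13, end = 20, intercept = -5.96, slope = 0.62)
#' fit_phase(simulate_trials(ph, noise_sd = 0))$slope
#' @export
fit_phase <- function(series, start = NULL, end = NULL) {
  if (!all(c("trial", "value") %in% names(series))) {
    stop("`series` must have columns `trial` and `value`")
  }
  if (is.null(start)) start <- min(series$trial)
  if (is.null(end)) end <- max(series$trial)
  sub <- series[series$trial >= start & series$trial <= end, , drop = FALSE]
  if (nrow(sub) < 2) {
    stop("need >= 2 trials in [", start, ", ", end, "], got ", nrow(sub))
  }
  fit <- stats::lm(value ~ trial, data = sub)
  co <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((sub$value - mean(sub$value))^2)
  r2 <- if (sst > 0) 1 - sse / sst else if (sse <= 1e-24) 1 else
    stop("zero variance in `value` with nonzero residuals: R^2 undefined")
  structure(list(
    start_trial = as.integer(start), end_trial = as.integer(end),
    slope = unname(co["trial"]), intercept = unname(co["(Intercept)"]),
    r_squared = r2, n = nrow(sub)
  ), class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf(
    "<phase_fit> trials %d-%d: value = %.4g %+.4g * trial (R^2 = %.3f, n = %d)\n",
    x$start_trial, x$end_trial, x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Segment a trial series into linear learning-curve phases
#'
#' Learning curves on repeated simulator trials typically show an
#' acquisition phase (performance improving), a plateau, and a late
#' deterioration attributed to fatigue; each phase is well described by its
#' own line. Given explicit breakpoints this fits one OLS line per segment.
#' In `"auto"` mode, every placement of up to `max_phases - 1` breakpoints
#' (minimum segment length `min_length`) is scanned exhaustively and the
#' placement minimizing the total sum of squared errors is returned; ties
#' are broken toward fewer phases, then toward earlier breakpoints.
#'
#' @param series a trial series (columns `trial`, `value`).
#' @param breakpoints either `"auto"`, or an increasing vector of last trials
#'   of each non-final phase (e.g. `c(7, 12)` for phases 1-7, 8-12,
#'   13-end).
#' @param max_phases maximum number of phases in auto mode (default 3).
#' @param min_length minimum trials per phase in auto mode (default 3).
#' @return a list of [fit_phase()] results, with attribute `total_sse`.
#' @export
segment_phases <- function(series, breakpoints = "auto", max_phases = 3,
                           min_length = 3) {
  trials <- sort(series$trial)
  lo <- min(trials); hi <- max(trials)
  fit_segments <- function(bps) {
    bounds <- c(lo - 1, bps, hi)
    fits <- lapply(seq_len(length(bounds) - 1), function(i) {
      fit_phase(series, start = bounds[i] + 1, end = bounds[i + 1])
    })
    attr(fits, "total_sse") <- sum(vapply(fits, function(f) {
      sub <- series[series$trial >= f$start_trial &
                      series$trial <= f$end_trial, ]
      sum((sub$value - (f$intercept + f$slope * sub$trial))^2)
    }, numeric(1)))
    fits
  }
  if (!identical(breakpoints, "auto")) {
    bps <- as.numeric(breakpoints)
    if (length(bps) > 0) {
      if (is.unsorted(bps, strictly = TRUE) || any(bps < lo) || any(bps >= hi)) {
        stop("`breakpoints` must be strictly increasing and inside (",
             lo, ", ", hi, ")")
      }
    }
    return(fit_segments(bps))
  }
  if (hi - lo + 1 < min_length) stop("series too short for auto segmentation")
  best <- NULL; best_sse <- Inf; best_k <- Inf; best_bps <- NULL
  for (k in 1:max_phases) {                   # k phases -> k - 1 breakpoints
    cand <- breakpoint_candidates(lo, hi, k, min_length)
    for (bps in cand) {
      fits <- fit_segments(bps)
      sse <- attr(fits, "total_sse")
      better <- sse < best_sse - 1e-10 ||
        (abs(sse - best_sse) <= 1e-10 &&
           (k < best_k || (k == best_k && earlier_bps(bps, best_bps))))
      if (better) {
        best <- fits; best_sse <- sse; best_k <- k; best_bps <- bps
      }
    }
  }
  best
}

# all placements of k-1 breakpoints with segments of >= min_length trials;
# a breakpoint b means one phase ends at trial b
breakpoint_candidates <- function(lo, hi, k, min_length) {
  if (k == 1) return(list(numeric(0)))
  positions <- seq(lo + min_length - 1, hi - min_length)
  if (length(positions) == 0 || length(positions) < k - 1) return(list())
  combos <- utils::combn(positions, k - 1, simplify = FALSE)
  Filter(function(bps) {
    lens <- diff(c(lo - 1, bps, hi))
    all(lens >= min_length)
  }, combos)
}

earlier_bps <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (length(a) != length(b)) return(length(a) < length(b))
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}
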