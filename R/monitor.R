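#' Monitor configuration
#'
#' Collects the tunable parameters of the end-to-end fatigue monitor.
#'
#' @param epoch_length analysis epoch length in seconds (default 2).
#' @param sigma alpha-band weight of the combined deviation (default 0.5).
#' @param threshold alarm threshold on `D_C` (default 6.0).
#' @param artifact_cutoff amplitude rule in uV (default 50).
#' @param channel analysis channel index (default 1).
#' @param clean run blind-source-separation artifact removal on the input
#'   before epoching (default `TRUE`).
#' @param baseline_epochs number of leading artifact-free epochs used to fit
#'   the alert baseline when none is supplied (default 30).
#' @param debounce number of consecutive threshold exceedances required
#'   before an alarm is raised (default 1, i.e. no debouncing).
#' @param smooth_lambda EWMA weight for [smooth_scores()] applied to the
#'   deviations before the alarm decision; 1 (default) disables smoothing.
#' @param wavelet,shrinkage passed to [decompose()] / [fit_baseline()].
#' @return a `monitor_config` list.
#' @export
monitor_config <- function(epoch_length = 2, sigma = 0.5, threshold = 6.0,
                           artifact_cutoff = 50, channel = 1, clean = TRUE,
                           baseline_epochs = 30, debounce = 1,
                           smooth_lambda = 1, wavelet = "db20",
                           shrinkage = 0.1) {
  if (sigma < 0 || sigma > 1) stop("`sigma` must lie in [0, 1]")
  if (artifact_cutoff <= 0) stop("`artifact_cutoff` must be > 0")
  if (debounce < 1) stop("`debounce` must be >= 1")
  if (smooth_lambda <= 0 || smooth_lambda > 1) {
    stop("`smooth_lambda` must lie in (0, 1]")
  }
  structure(list(epoch_length = epoch_length, sigma = sigma,
                 threshold = threshold, artifact_cutoff = artifact_cutoff,
                 channel = channel, clean = clean,
                 baseline_epochs = baseline_epochs, debounce = debounce,
                 smooth_lambda = smooth_lambda, wavelet = wavelet,
                 shrinkage = shrinkage),
            class = "monitor_config")
}

#' Run the end-to-end fatigue monitor over a recording
#'
#' Streams a recording through the full pipeline: optional
#' blind-source-separation cleaning, epoching, the 50 uV artifact rule
#' (contaminated epochs are skipped, not scored), wavelet extraction of the
#' theta/alpha rhythms, Mahalanobis scoring against the alert baseline, and
#' the threshold alarm. One log row is produced per epoch in input order;
#' an alarm event is recorded for exactly the scored epochs whose `D_C`
#' strictly exceeds the threshold (after optional debouncing). The run is
#' deterministic for file input.
#'
#' @param record an [eeg_record()] (e.g. from [read_recording()]).
#' @param baseline a [fit_baseline()] model, or `NULL` to fit one from the
#'   first `baseline_epochs` artifact-free epochs of this recording.
#' @param config a [monitor_config()].
#' @param log_path optional path; when given, the per-epoch log is written
#'   as JSON lines (one object per epoch).
#' @return a `monitor_result`: list with `log` (data.frame: `epoch`,
#'   `start_s`, `skipped`, `d_alpha`, `d_theta`, `d_c`, `alarm`), `alarms`
#'   (data.frame: `epoch`, `start_s`, `d_c`, `threshold`), `baseline`,
#'   `summary` (list: `epochs`, `skipped`, `alarms`, `threshold`).
#' @export
run_monitor <- function(record, baseline = NULL, config = monitor_config(),
                        log_path = NULL) {
  stopifnot(inherits(record, "eeg_record"), inherits(config, "monitor_config"))
  if (config$clean) {
    record <- remove_artifacts_bss(record, cutoff = config$artifact_cutoff)
  }
  eps <- epoch_stream(record, config$epoch_length)
  mask <- flag_artifacts(record, cutoff = config$artifact_cutoff,
                         epoch_length = config$epoch_length)
  skipped <- mask$epochs[seq_along(eps)]
  feats_list <- vector("list", length(eps))
  for (i in seq_along(eps)) {
    if (skipped[i]) next
    d <- decompose(eps[[i]]$samples[config$channel, ],
                   rate = record$sampling_rate, wavelet = config$wavelet)
    feats_list[[i]] <- band_feature_vector(d, epoch_index = eps[[i]]$index)
  }
  scored_idx <- which(!skipped)
  if (length(scored_idx) == 0) stop("every epoch is artifact-contaminated")
  feats <- do.call(rbind, feats_list[scored_idx])
  class(feats) <- c("band_features", "data.frame")
  if (is.null(baseline)) {
    k <- min(config$baseline_epochs, nrow(feats))
    if (k < 2) {
      stop("no baseline supplied and fewer than 2 clean epochs available; ",
           "run calibration first")
    }
    baseline <- fit_baseline(feats[seq_len(k), , drop = FALSE],
                             shrinkage = config$shrinkage)
  }
  sc <- score_epochs(feats, baseline, sigma = config$sigma)
  if (config$smooth_lambda < 1) {
    sc <- smooth_scores(sc, lambda = config$smooth_lambda)
  }
  raw_alarm <- detect_fatigue(sc$d_c, config$threshold)
  alarm <- debounce_alarms(raw_alarm, config$debounce)
  log <- data.frame(
    epoch = vapply(eps, `[[`, integer(1), "index"),
    start_s = vapply(eps, `[[`, numeric(1), "start_offset"),
    skipped = skipped, d_alpha = NA_real_, d_theta = NA_real_,
    d_c = NA_real_, alarm = FALSE
  )
  log$d_alpha[scored_idx] <- sc$d_alpha
  log$d_theta[scored_idx] <- sc$d_theta
  log$d_c[scored_idx] <- sc$d_c
  log$alarm[scored_idx] <- alarm
  alarms <- log[log$alarm, c("epoch", "start_s", "d_c")]
  alarms$threshold <- rep(config$threshold, nrow(alarms))
  rownames(alarms) <- NULL
  if (!is.null(log_path)) {
    con <- file(log_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
    }
  }
  structure(list(
    log = log, alarms = alarms, baseline = baseline,
    summary = list(epochs = nrow(log), skipped = sum(skipped),
                   alarms = nrow(alarms), threshold = config$threshold)
  ), class = "monitor_result")
}

# alarm only after k consecutive raw exceedances (k = 1: passthrough)
debounce_alarms <- function(raw, k) {
  if (k <= 1) return(raw)
  run <- 0L
  out <- logical(length(raw))
  for (i in seq_along(raw)) {
    run <- if (raw[i]) run + 1L else 0L
    out[i] <- run >= k
  }
  out
}

#' @export
print.monitor_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<monitor_result> %d epochs (%d skipped as artifact), %d alarm(s) at D_C > %g\n",
    s$epochs, s$skipped, s$alarms, s$threshold))
  invisible(x)
}

#' Audit a monitor log for alarm/threshold consistency
#'
#' Re-checks, post hoc, that every alarm row of a monitor log has
#' `d_c > threshold` and every non-skipped, non-alarm row does not (for
#' debounce 1), and that scored rows plus skipped rows account for every
#' epoch.
#'
#' @param result a `monitor_result`.
#' @return `TRUE` invisibly; stops with a message on an inconsistent log.
#' @export
audit_monitor_log <- function(result) {
  stopifnot(inherits(result, "monitor_result"))
  log <- result$log
  thr <- result$summary$threshold
  if (any(log$alarm & !(log$d_c > thr))) {
    stop("audit failed: alarm row with d_c <= threshold")
  }
  if (nrow(log) != result$summary$epochs ||
      sum(log$skipped) != result$summary$skipped) {
    stop("audit failed: log/summary epoch accounting mismatch")
  }
  if (any(log$skipped & log$alarm)) stop("audit failed: skipped epoch alarmed")
  invisible(TRUE)
}
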