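#' Configuration for the synthetic EEG generator
#'
#' The generator emulates band-structured scalp EEG: one narrowband component
#' per classical rhythm (delta 1-4, theta 4-7, alpha 8-11, beta 12-30 Hz),
#' each synthesized as band-pass-filtered white noise at a target RMS
#' amplitude, plus broadband noise. Narrowband noise (rather than pure
#' sinusoids) is used so that band spectra have nonzero within-band variance,
#' which the covariance-based fatigue baseline requires.
#'
#' Default amplitudes give a total RMS near 10 uV, typical of forehead
#' dry-electrode recordings, and keep a clean signal comfortably below the
#' 50 uV artifact criterion.
#'
#' @param sampling_rate sampling rate in Hz (default 512).
#' @param duration total duration in seconds.
#' @param band_amplitudes named numeric vector of per-band RMS amplitudes in
#'   uV; names among `delta`, `theta`, `alpha`, `beta`.
#' @param noise_rms broadband white-noise RMS in uV.
#' @param epoch_length epoch length in seconds used to align the fatigue
#'   trajectory (one drift value per epoch).
#' @param fatigue_effect fractional reduction of theta/alpha amplitude at
#'   drift level 1 (default 0.5, i.e. band power falls to 25%).
#' @param fatigue_direction `-1` (default): theta/alpha power decreases with
#'   fatigue, the direction assumed throughout this package; `+1` reverses
#'   the sign for sensitivity analyses.
#' @param mains_freq mains frequency in Hz used by [inject_artifacts()].
#' @param seed integer seed; every generator draw is a deterministic function
#'   of (config, seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 512, duration = 60,
                       band_amplitudes = c(delta = 5, theta = 5,
                                           alpha = 6, beta = 3),
                       noise_rms = 2, epoch_length = 2,
                       fatigue_effect = 0.5, fatigue_direction = -1,
                       mains_freq = 50, seed = 1L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("invalid configuration: `sampling_rate` must be > 0")
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid configuration: `duration` must be > 0")
  }
  if (any(band_amplitudes < 0) || noise_rms < 0) {
    stop("invalid configuration: amplitudes must be >= 0")
  }
  if (!fatigue_direction %in% c(-1, 1)) {
    stop("`fatigue_direction` must be -1 or +1")
  }
  structure(list(
    sampling_rate = sampling_rate, duration = duration,
    band_amplitudes = band_amplitudes, noise_rms = noise_rms,
    epoch_length = epoch_length, fatigue_effect = fatigue_effect,
    fatigue_direction = fatigue_direction, mains_freq = mains_freq,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_band_edges <- list(delta = c(1, 4), theta = c(4, 7),
                       alpha = c(8, 11), beta = c(12, 30))

#' Simulate a band-structured EEG session with a fatigue trajectory
#'
#' Generates a single-channel EEG recording whose theta and alpha power is
#' modulated epoch-by-epoch by a drift trajectory in `[0, 1]`: at drift 0 the
#' band powers are stationary (the "alert" state), and at drift d the theta
#' and alpha amplitudes are scaled by `1 - fatigue_effect * d` (default
#' direction: relative theta/alpha power decreases as fatigue grows). Epochs
#' with drift 0 are labeled `alert`, all others `fatigued`.
#'
#' @param config a [sim_config()].
#' @param trajectory numeric vector of per-epoch drift levels in `[0, 1]`;
#'   length must equal `duration / epoch_length`. Default: all zero (fully
#'   alert session).
#' @return an `eeg_session`: list with `record` (an [eeg_record()]),
#'   `labels` (factor `alert`/`fatigued` per epoch), `drift` (the
#'   trajectory), and `epoch_length`.
#' @examples
#' ses <- simulate_eeg(sim_config(duration = 8, seed = 7))
#' table(ses$labels)
#' @export
simulate_eeg <- function(config, trajectory = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$sampling_rate
  n <- as.integer(round(config$duration * rate))
  w <- as.integer(round(config$epoch_length * rate))
  n_ep <- n %/% w
  if (n_ep < 1) stop("duration shorter than one epoch")
  if (is.null(trajectory)) trajectory <- rep(0, n_ep)
  if (length(trajectory) != n_ep) {
    stop("trajectory length (", length(trajectory),
         ") must equal the number of epochs (", n_ep, ")")
  }
  if (any(trajectory < 0 | trajectory > 1)) {
    stop("drift levels must lie in [0, 1]")
  }
  set.seed(config$seed)
  n_used <- n_ep * w
  x <- numeric(n_used)
  # per-epoch amplitude gain, 1 at drift 0
  gain <- 1 + config$fatigue_direction * config$fatigue_effect * trajectory
  gain_series <- rep(gain, each = w)
  for (band in names(config$band_amplitudes)) {
    amp <- config$band_amplitudes[[band]]
    if (amp <= 0) next
    comp <- narrowband_noise(n_used, rate, sim_band_edges[[band]])
    comp <- comp * (amp / stats::sd(comp))
    if (band %in% c("theta", "alpha")) comp <- comp * gain_series
    x <- x + comp
  }
  if (config$noise_rms > 0) {
    x <- x + stats::rnorm(n_used, sd = config$noise_rms)
  }
  rec <- eeg_record(matrix(x, nrow = 1), rate, channel_labels = "Fp")
  structure(list(
    record = rec,
    labels = factor(ifelse(trajectory == 0, "alert", "fatigued"),
                    levels = c("alert", "fatigued")),
    drift = trajectory,
    epoch_length = config$epoch_length,
    config = config
  ), class = "eeg_session")
}

# white noise band-passed with a zero-phase 4th-order Butterworth filter
narrowband_noise <- function(n, rate, band) {
  ny <- rate / 2
  hi <- min(band[2], 0.95 * ny)
  z <- stats::rnorm(n)
  zero_phase_bandpass(z, c(band[1], hi), rate)
}

#' Inject artifact events into a recording
#'
#' Adds seeded artifact events of one kind on top of an existing recording:
#' `blink` (300 ms raised-cosine pulse, peak drawn uniformly in 100-150 uV,
#' random sign), `spike` (brief 40 ms triangular muscle-like transient, peak
#' 80-150 uV), or `line` (1 s burst of a mains-frequency sinusoid, 30 uV
#' amplitude). Blink and spike events always exceed the 50 uV artifact
#' criterion; events are placed on disjoint intervals.
#'
#' @param record an [eeg_record()] (events are added to every channel).
#' @param kind `"blink"`, `"spike"` or `"line"`.
#' @param count number of events (>= 0).
#' @param seed integer seed for placement and amplitudes.
#' @param mains_freq mains frequency in Hz for `kind = "line"`.
#' @return the modified [eeg_record()], with an `artifact_events` attribute:
#'   data.frame of `kind`, `start_s`, `end_s`, `peak_uv`.
#' @export
inject_artifacts <- function(record, kind = c("blink", "spike", "line"),
                             count, seed = 1L, mains_freq = 50) {
  stopifnot(inherits(record, "eeg_record"))
  kind <- match.arg(kind)
  if (count < 0) stop("`count` must be >= 0")
  events <- data.frame(kind = character(0), start_s = numeric(0),
                       end_s = numeric(0), peak_uv = numeric(0))
  if (count == 0) {
    attr(record, "artifact_events") <- events
    return(record)
  }
  rate <- record$sampling_rate
  n <- n_samples(record)
  dur_s <- switch(kind, blink = 0.3, spike = 0.04, line = 1.0)
  w <- max(2L, as.integer(round(dur_s * rate)))
  # place events on disjoint slots: split the record into 2*count slots and
  # use every other one, so events can never touch
  n_slots <- 2L * count
  slot_len <- n %/% n_slots
  if (slot_len < w) {
    stop("record too short for ", count, " disjoint ", kind, " events")
  }
  set.seed(as.integer(seed))
  starts <- vapply(seq_len(count), function(i) {
    s0 <- (2L * (i - 1L)) * slot_len
    s0 + sample.int(slot_len - w + 1L, 1L)
  }, numeric(1))
  tpulse <- (seq_len(w) - 1) / rate
  for (s in starts) {
    idx <- s:(s + w - 1L)
    peak <- switch(kind,
      blink = stats::runif(1, 100, 150) * sample(c(-1, 1), 1),
      spike = stats::runif(1, 80, 150) * sample(c(-1, 1), 1),
      line = 30)
    shape <- switch(kind,
      blink = 0.5 * (1 - cos(2 * pi * tpulse / dur_s)),        # raised cosine
      spike = 1 - abs(2 * tpulse / dur_s - 1),                 # triangle
      line = sin(2 * pi * mains_freq * tpulse))
    pulse <- peak * shape
    record$samples[, idx] <- sweep(record$samples[, idx, drop = FALSE], 2,
                                   pulse, "+")
    events <- rbind(events, data.frame(
      kind = kind, start_s = (s - 1) / rate, end_s = (s + w - 2) / rate,
      peak_uv = abs(peak)))
  }
  attr(record, "artifact_events") <- events
  record
}

#' Simulate learning-curve trial series from piecewise-linear phase models
#'
#' Generates a per-trial outcome series (errors, completion time, or
#' perceived fatigue) from contiguous linear phase models
#' `value = intercept + slope * trial + noise`. Values are clipped below at 0
#' and above at `cap`; completion times use the simulator's 300 s cap. With
#' `noise_sd = 0` the series reproduces the phase lines exactly (no rounding
#' is applied).
#'
#' @param phases data.frame with columns `start`, `end` (1-based inclusive
#'   trial range), `intercept`, `slope`. Phases must be contiguous and
#'   non-overlapping.
#' @param noise_sd standard deviation of additive Gaussian noise per trial.
#' @param cap upper clip for the generated values (e.g. 300 for completion
#'   time in seconds); default `Inf`.
#' @param seed integer seed.
#' @return data.frame of class `trial_series` with columns `trial`, `value`.
#' @examples
#' ph <- data.frame(start = 13, end = 20, intercept = -5.96, slope = 0.62)
#' simulate_trials(ph, noise_sd = 0)
#' @export
simulate_trials <- function(phases, noise_sd = 0, cap = Inf, seed = 1L) {
  req <- c("start", "end", "intercept", "slope")
  if (!is.data.frame(phases) || !all(req %in% names(phases))) {
    stop("`phases` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  phases <- phases[order(phases$start), , drop = FALSE]
  if (any(phases$end < phases$start)) stop("phase `end` must be >= `start`")
  if (nrow(phases) > 1) {
    gaps <- phases$start[-1] - phases$end[-nrow(phases)]
    if (any(gaps <= 0)) stop("phases overlap")
    if (any(gaps != 1)) stop("phases must be contiguous (end + 1 == next start)")
  }
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(phases)), function(i) {
    tr <- phases$start[i]:phases$end[i]
    v <- phases$intercept[i] + phases$slope[i] * tr
    if (noise_sd > 0) v <- v + stats::rnorm(length(tr), sd = noise_sd)
    data.frame(trial = tr, value = pmin(cap, pmax(0, v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_series", "data.frame")
  out
}
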