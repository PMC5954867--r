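# Shared fixtures, built in code at test time.

# single-channel sinusoid record
sine_record <- function(freq, rate = 512, duration = 2, amp = 10) {
  t <- seq_len(duration * rate) / rate
  eeg_record(amp * sin(2 * pi * freq * t), rate)
}

# total power fraction of a signal inside [lo, hi] Hz, by FFT periodogram
band_power_fraction <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * rate / n
  f[f > rate / 2] <- rate - f[f > rate / 2]
  sum(p[f >= lo & f <= hi]) / sum(p)
}

# brute-force pair-counting AUC: P(score_pos > score_neg), ties count 1/2
pair_auc <- function(scores, labels) {
  pos <- scores[labels == "fatigued"]
  neg <- scores[labels == "alert"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# the three learning-curve phase models reported for the averaged error,
# completion-time and fatigue series
error_phases <- data.frame(
  start = c(1, 8, 13), end = c(7, 12, 20),
  intercept = c(12.13, 3.34, -5.96), slope = c(-1.4, -0.13, 0.62))
fatigue_phases <- data.frame(
  start = c(1, 10, 14), end = c(9, 13, 20),
  intercept = c(2.35, 3.6, 3.15), slope = c(0.15, 0, 0.212))

# features from a fully alert session, small and fast
alert_features <- function(seed = 42, duration = 30) {
  ses <- simulate_eeg(sim_config(duration = duration, seed = seed))
  extract_features(ses$record)
}
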