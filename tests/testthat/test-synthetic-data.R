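test_that("identical config and seed give bitwise-identical sessions", {
  cfg <- sim_config(duration = 8, seed = 99)
  a <- simulate_eeg(cfg)
  b <- simulate_eeg(cfg)
  expect_identical(a$record$samples, b$record$samples)
  c <- simulate_eeg(sim_config(duration = 8, seed = 100))
  expect_false(identical(a$record$samples, c$record$samples))
})

test_that("invalid generator configuration is rejected", {
  expect_error(sim_config(duration = -1), "invalid configuration")
  expect_error(sim_config(sampling_rate = 0), "invalid configuration")
  expect_error(sim_config(band_amplitudes = c(alpha = -2)),
               "invalid configuration")
  cfg <- sim_config(duration = 8)
  expect_error(simulate_eeg(cfg, rep(2, 4)), "\\[0, 1\\]")
  expect_error(simulate_eeg(cfg, rep(0, 3)), "trajectory length")
})

test_that("a pure-alpha simulation concentrates power in 8-11 Hz", {
  cfg <- sim_config(duration = 8, band_amplitudes = c(alpha = 10),
                    noise_rms = 0, seed = 3)
  ses <- simulate_eeg(cfg)
  frac <- band_power_fraction(ses$record$samples[1, ], 512, 8, 11)
  expect_gte(frac, 0.9)
})

test_that("each pure-band simulation keeps >= 90% power in its band", {
  bands <- list(delta = c(1, 4), theta = c(4, 7), alpha = c(8, 11),
                beta = c(12, 30))
  for (nm in names(bands)) {
    amps <- stats::setNames(10, nm)
    ses <- simulate_eeg(sim_config(duration = 8, band_amplitudes = amps,
                                   noise_rms = 0, seed = 17))
    frac <- band_power_fraction(ses$record$samples[1, ], 512,
                                bands[[nm]][1], bands[[nm]][2])
    expect_gte(frac, 0.9)
  }
})

test_that("full drift halves labeled fatigued and lowers alpha power", {
  cfg <- sim_config(duration = 40, seed = 8)
  traj <- c(rep(0, 10), rep(1, 10))
  ses <- simulate_eeg(cfg, traj)
  expect_equal(as.character(ses$labels), rep(c("alert", "fatigued"), each = 10))
  x <- ses$record$samples[1, ]
  half <- length(x) / 2
  p1 <- band_power_fraction(x[1:half], 512, 8, 11) * mean(x[1:half]^2)
  p2 <- band_power_fraction(x[(half + 1):(2 * half)], 512, 8, 11) *
    mean(x[(half + 1):(2 * half)]^2)
  expect_lt(p2, p1)
})

test_that("artifact injection with count zero returns the input unchanged", {
  ses <- simulate_eeg(sim_config(duration = 8, seed = 5))
  out <- inject_artifacts(ses$record, "blink", 0)
  expect_identical(out$samples, ses$record$samples)
})

test_that("blink events form exactly the requested disjoint exceedances", {
  silent <- eeg_record(matrix(0, 1, 20 * 512), 512)
  out <- inject_artifacts(silent, "blink", 3, seed = 7)
  exceed <- abs(out$samples[1, ]) > 50
  runs <- rle(exceed)
  expect_equal(sum(runs$values), 3)          # three disjoint intervals
  ev <- attr(out, "artifact_events")
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$peak_uv > 50))
})

test_that("line-noise events put the dominant peak at mains frequency", {
  silent <- eeg_record(matrix(0, 1, 10 * 512), 512)
  out <- inject_artifacts(silent, "line", 2, seed = 7, mains_freq = 50)
  x <- out$samples[1, ]
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 512 / length(x)
  keep <- f > 0 & f <= 256
  expect_lt(abs(f[keep][which.max(p[keep])] - 50), 0.2)
})

test_that("trial generator reproduces phase lines exactly at zero noise", {
  ph <- data.frame(start = 13, end = 20, intercept = -5.96, slope = 0.62)
  ts <- simulate_trials(ph, noise_sd = 0)
  expect_equal(ts$value[ts$trial == 20], -5.96 + 0.62 * 20)  # 6.44
  flat <- simulate_trials(
    data.frame(start = 1, end = 10, intercept = 2, slope = 0), noise_sd = 0)
  expect_equal(flat$value, rep(2, 10))
})

test_that("completion-time generator never exceeds the 300 s cap", {
  ph <- data.frame(start = 1, end = 20, intercept = 290, slope = 2)
  ts <- simulate_trials(ph, noise_sd = 30, cap = 300, seed = 4)
  expect_true(all(ts$value <= 300))
  expect_true(all(ts$value >= 0))
})

test_that("overlapping or gapped phase tables are rejected", {
  bad <- data.frame(start = c(1, 5), end = c(6, 10),
                    intercept = 0, slope = 0)
  expect_error(simulate_trials(bad), "overlap")
  gap <- data.frame(start = c(1, 9), end = c(6, 12),
                    intercept = 0, slope = 0)
  expect_error(simulate_trials(gap), "contiguous")
})
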