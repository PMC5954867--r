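# short sessions keep the monitor tests fast; cleaning is exercised once
alert_session <- simulate_eeg(sim_config(duration = 80, seed = 81))

test_that("the monitor log is deterministic for file input", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(alert_session$record, path)
  rec <- read_recording(path)
  cfg <- monitor_config(clean = FALSE)
  r1 <- run_monitor(rec, config = cfg)
  r2 <- run_monitor(rec, config = cfg)
  expect_identical(r1$log, r2$log)
})

test_that("an alert session with a high percentile threshold stays silent", {
  quiet_runs <- 0
  for (seed in 82:87) {
    ses <- simulate_eeg(sim_config(duration = 80, seed = seed))
    f <- extract_features(ses$record)
    bl <- fit_baseline(f[1:30, ])
    sc <- score_epochs(f, bl)
    thr <- stats::quantile(sc$d_c[1:30], 0.999) * 1.5
    cfg <- monitor_config(clean = FALSE, threshold = thr)
    res <- run_monitor(ses$record, bl, cfg)
    if (res$summary$alarms == 0) quiet_runs <- quiet_runs + 1
  }
  expect_gte(quiet_runs, 5)                  # >= 95% of seeded runs silent
})

test_that("a drift step triggers the first alarm only after the step", {
  cfg <- sim_config(duration = 200, seed = 88)
  traj <- c(rep(0, 50), rep(1, 50))
  ses <- simulate_eeg(cfg, traj)
  f <- extract_features(ses$record)
  bl <- fit_baseline(f[1:30, ])
  sc <- smooth_scores(score_epochs(f, bl))
  roc <- roc_curve(sc$d_c, ses$labels)
  thr <- select_threshold(roc, "youden")
  mcfg <- monitor_config(clean = FALSE, threshold = as.numeric(thr),
                         smooth_lambda = 0.5, debounce = 2)
  res <- run_monitor(ses$record, bl, mcfg)
  expect_gt(res$summary$alarms, 0)
  expect_gte(min(res$alarms$epoch), 40)      # no alarm deep in the alert half
})

test_that("artifact-contaminated epochs are skipped and accounted for", {
  art <- inject_artifacts(alert_session$record, "blink", 2, seed = 6)
  cfg <- monitor_config(clean = FALSE, baseline_epochs = 10)
  res <- run_monitor(art, config = cfg)
  expect_gt(res$summary$skipped, 0)
  expect_true(all(is.na(res$log$d_c[res$log$skipped])))
  expect_equal(sum(!res$log$skipped) + res$summary$skipped,
               res$summary$epochs)
  expect_silent(audit_monitor_log(res))
})

test_that("cleaning inside the monitor scores blink epochs instead", {
  art <- inject_artifacts(alert_session$record, "blink", 2, seed = 6)
  res_raw <- run_monitor(art, config = monitor_config(clean = FALSE,
                                                      baseline_epochs = 10))
  res_cln <- run_monitor(art, config = monitor_config(clean = TRUE,
                                                      baseline_epochs = 10))
  expect_lt(res_cln$summary$skipped, res_raw$summary$skipped)
})

test_that("the JSON-lines log has one valid object per epoch", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  cfg <- monitor_config(clean = FALSE, baseline_epochs = 10)
  res <- run_monitor(alert_session$record, config = cfg, log_path = path)
  lines <- readLines(path)
  expect_length(lines, res$summary$epochs)
  first <- jsonlite::fromJSON(lines[1])
  expect_named(first, c("epoch", "start_s", "skipped", "d_alpha",
                        "d_theta", "d_c", "alarm"))
})

test_that("debounced alarms require consecutive exceedances", {
  raw <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(eegfatigue:::debounce_alarms(raw, 2),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(eegfatigue:::debounce_alarms(raw, 1), raw)
})

test_that("the monitor demands a fittable baseline", {
  tiny <- simulate_eeg(sim_config(duration = 4, seed = 90))
  art <- eeg_record(matrix(200, 1, n_samples(tiny$record)), 512)
  expect_error(run_monitor(art, config = monitor_config(clean = FALSE)),
               "artifact")
})

test_that("the command-line front end drives the trial pipeline", {
  cli <- system.file("cli", "eegfatigue-cli.R", package = "eegfatigue")
  expect_true(file.exists(cli))
  phases_csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(error_phases, phases_csv, row.names = FALSE)
  trials_csv <- withr::local_tempfile(fileext = ".csv")
  fits_json <- withr::local_tempfile(fileext = ".json")
  rscript <- file.path(R.home("bin"), "Rscript")
  out1 <- system2(rscript, c(cli, "simulate-trials", "--phases", phases_csv,
                             "--noise-sd", "0", "--out", trials_csv))
  out2 <- system2(rscript, c(cli, "trials-analyze", "--in", trials_csv,
                             "--breakpoints", "7,12", "--out", fits_json))
  expect_equal(out1, 0)
  expect_equal(out2, 0)
  fits <- jsonlite::read_json(fits_json, simplifyVector = TRUE)
  expect_equal(fits$slope, c(-1.4, -0.13, 0.62), tolerance = 1e-8)
})
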