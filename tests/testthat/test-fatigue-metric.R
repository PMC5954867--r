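test_that("a degenerate constant baseline still yields a usable model", {
  f <- alert_features(seed = 42, duration = 10)[rep(1, 5), ]
  f$epoch <- 0:4
  bl <- fit_baseline(f)
  expect_equal(unname(bl$mu_alpha),
               unname(unlist(f[1, c("alpha_8", "alpha_9", "alpha_10")])))
  expect_true(all(eigen(bl$C, symmetric = TRUE)$values > 0))
  expect_true(all(abs(bl$C[upper.tri(bl$C)]) < 1e-15))   # diagonal model
})

test_that("few epochs with shrinkage still give an invertible covariance", {
  f <- alert_features(seed = 7, duration = 10)   # 5 epochs later subset to 2
  bl <- fit_baseline(f[1:2, ], shrinkage = 0.1)
  ev <- eigen(bl$C, symmetric = TRUE)$values
  expect_true(all(ev > 0))
  expect_lt(max(ev) / min(ev), 1e12)             # finite condition number
  expect_true(all(eigen(bl$N, symmetric = TRUE)$values > 0))
})

test_that("baseline fitting is deterministic and demands >= 2 epochs", {
  f <- alert_features(seed = 9, duration = 12)
  expect_identical(fit_baseline(f), fit_baseline(f))
  expect_error(fit_baseline(f[1, , drop = FALSE]), "insufficient baseline")
})

test_that("the Mahalanobis distance matches hand-computable cases", {
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_distance(c(3, 4), c(0, 0), diag(2)), 5)
  expect_equal(mahalanobis_distance(c(2, 1), c(0, 0), diag(c(2, 1))),
               sqrt(3), tolerance = 1e-12)
  sing <- matrix(c(1, 1, 1, 1), 2)
  expect_error(mahalanobis_distance(c(1, 0), c(0, 0), sing),
               "condition number")
  expect_error(mahalanobis_distance(c(1, 0, 0), c(0, 0), diag(2)),
               "dimension mismatch")
})

test_that("distances are invariant under invertible linear feature maps", {
  set.seed(51)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
    x <- rnorm(3); mu <- rnorm(3)
    S <- crossprod(matrix(rnorm(9), 3)) + diag(0.5, 3)
    d0 <- mahalanobis_distance(x, mu, S)
    d1 <- mahalanobis_distance(A %*% x, A %*% mu, A %*% S %*% t(A))
    expect_equal(d1, d0, tolerance = 1e-8)
  }
})

test_that("the combined deviation is an exact convex combination", {
  expect_equal(combined_deviation(2, 4, 1), 2)
  expect_equal(combined_deviation(2, 4, 0), 4)
  expect_equal(combined_deviation(2, 4, 0.5), 3)
  expect_error(combined_deviation(2, 4, 1.5), "sigma")
  expect_error(combined_deviation(-1, 4, 0.5), ">= 0")
})

test_that("scoring the baseline means themselves gives zero deviation", {
  f <- alert_features(seed = 10, duration = 20)
  bl <- fit_baseline(f)
  mean_row <- f[1, ]
  mean_row[names(bl$mu_theta)] <- bl$mu_theta
  mean_row[names(bl$mu_alpha)] <- bl$mu_alpha
  sc <- score_epochs(mean_row, bl)
  expect_equal(sc$d_c, 0, tolerance = 1e-8)
})

test_that("self-scored baseline epochs stay within the Gaussian bound", {
  f <- alert_features(seed = 11, duration = 60)
  bl <- fit_baseline(f)
  sc <- score_epochs(f, bl)
  expect_lt(mean(sc$d_c), 3 * sqrt(3))       # approx sqrt(dim) for Gaussians
})

test_that("a drift ramp produces strongly rank-correlated fatigue scores", {
  el <- 8                                    # long epochs: stabler spectra
  cfg <- sim_config(duration = 240, epoch_length = el, seed = 11)
  nep <- 240 / el
  traj <- c(rep(0, 10), seq(0, 1, length.out = nep - 10))
  ses <- simulate_eeg(cfg, traj)
  f <- extract_features(ses$record, epoch_length = el)
  bl <- fit_baseline(f[1:10, ])
  sc <- smooth_scores(score_epochs(f, bl), lambda = 0.5)
  expect_gt(cor(ses$drift, sc$d_c, method = "spearman"), 0.8)
})

test_that("a step change in band power raises the mean score after the step", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- sim_config(duration = 60, seed = seed)
    traj <- c(rep(0, 15), rep(1, 15))
    ses <- simulate_eeg(cfg, traj)
    f <- extract_features(ses$record)
    bl <- fit_baseline(f[1:15, ])
    sc <- score_epochs(f, bl)
    if (mean(sc$d_c[16:30]) > mean(sc$d_c[1:15])) hits <- hits + 1
  }
  expect_gte(hits, 9)                        # one-sided, ~95% of seeded runs
})

test_that("score smoothing preserves the convex-combination identity", {
  f <- alert_features(seed = 12, duration = 30)
  bl <- fit_baseline(f[1:5, ])
  sc <- score_epochs(f, bl, sigma = 0.3)
  sm <- smooth_scores(sc, lambda = 0.4)
  expect_equal(sm$d_c, 0.3 * sm$d_alpha + 0.7 * sm$d_theta, tolerance = 1e-12)
  expect_identical(smooth_scores(sc, lambda = 1), sc)
})

test_that("baseline models survive a JSON round trip", {
  f <- alert_features(seed = 13, duration = 12)
  bl <- fit_baseline(f)
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline(bl, path)
  back <- read_baseline(path)
  sc1 <- score_epochs(f, bl)
  sc2 <- score_epochs(f, back)
  expect_equal(sc2$d_c, sc1$d_c, tolerance = 1e-10)
})
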