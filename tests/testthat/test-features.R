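sim_short <- function(amplitude = 120, duration = 60, seed = 21,
                      setting = build_setting("II-K")) {
  simulate_probing(setting,
                   stimulus_protocol(amplitude, targets = setting$targets),
                   integration_spec(duration = duration, seed = seed))
}

test_that("epoch extraction follows the stimulus schedule", {
  res <- sim_short(duration = 60)
  em <- extract_epochs(res)
  # onsets at 2, 4, ..., 58 -> 29 epochs of floor(0.4 / dt) samples
  expect_identical(dim(em$epochs)[2], 29L)
  expect_identical(em$window_n, as.integer(floor(0.400 / 0.00195)))
  # passive run with the same schedule gives identical epoch timing
  em0 <- extract_epochs(sim_short(amplitude = 0, duration = 60))
  expect_identical(em0$onset_times, em$onset_times)
  expect_error(extract_epochs(res, window_s = 2.5), "shorter than")
})

test_that("the full-length schedule yields 999 complete epochs", {
  # arithmetic of the 2000 s / 2 s period / 2 s start protocol
  dt <- 0.00195
  onsets <- seq(2, 2000 - 1e-12, by = 2)
  idx <- ceiling(onsets / dt - 1e-9) + 1
  window_n <- floor(0.400 / dt)
  expect_identical(sum(idx + window_n - 1 <= floor(2000 / dt)), 999L)
})

test_that("moment features agree with definitional and e1071 oracles", {
  set.seed(31)
  for (rep in 1:100) {
    x <- rnorm(204, sd = runif(1, 0.1, 5)) + runif(1, -3, 3)
    mf <- moment_features(x)
    expect_equal(mf$variance, oracle_variance(x), tolerance = 1e-12)
    expect_equal(mf$skewness, oracle_skewness(x), tolerance = 1e-12)
    expect_equal(mf$kurtosis, oracle_kurtosis(x), tolerance = 1e-12)
  }
  x <- rnorm(500)
  mf <- moment_features(x)
  expect_equal(mf$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(mf$kurtosis, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
})

test_that("moment features handle degenerate epochs", {
  mf <- moment_features(rep(2.5, 10))
  expect_identical(mf$variance, 0)
  expect_true(is.na(mf$skewness) && is.na(mf$kurtosis))
  expect_equal(moment_features(rep(c(-1, 1), 50))$skewness, 0)
  x <- rnorm(1e4)
  expect_equal(moment_features(x)$variance, 1, tolerance = 0.05)
  expect_equal(moment_features(x)$kurtosis, 3, tolerance = 0.2)
})

test_that("lag-1 autocorrelation matches closed forms and the definition", {
  n <- 204
  expect_equal(lag1_autocorrelation(rep(c(1, -1), n / 2)), -(n - 1) / n,
               tolerance = 1e-12)
  expect_gt(lag1_autocorrelation(seq_len(204)), 0.95)
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(204)
    expect_equal(lag1_autocorrelation(x), oracle_lag1(x), tolerance = 1e-12)
  }
  wn <- replicate(200, lag1_autocorrelation(rnorm(204)))
  expect_gt(mean(abs(wn) < 0.2), 0.95)   # null sd ~ 1/sqrt(n)
  expect_true(is.na(lag1_autocorrelation(rep(1, 10))))
})

test_that("mutual information behaves like a plug-in histogram estimate", {
  # identical epochs uniformly filling 2 bins carry exactly 1 bit
  x <- rep(c(0, 1), 102)
  expect_equal(mutual_information(x, x, n_bins = 2), 1, tolerance = 1e-12)
  # MI(x, x) equals the marginal plug-in entropy
  set.seed(8)
  x <- rnorm(204)
  bx <- findInterval(x, seq(min(x), max(x), length.out = 17),
                     rightmost.closed = TRUE)
  px <- table(bx) / length(bx)
  expect_equal(mutual_information(x, x), -sum(px * log2(px)),
               tolerance = 1e-10)
  # independence: small positive bias bounded by (bins-1)^2 / (2 n ln 2)
  set.seed(9)
  mis <- replicate(50, mutual_information(rnorm(2000), rnorm(2000)))
  expect_true(all(mis >= 0))
  expect_lt(mean(mis), (16 - 1)^2 / (2 * 2000 * log(2)) * 4)
  # agreement with an independent binning implementation
  for (rep in 1:20) {
    a <- rnorm(204); b <- 0.5 * a + rnorm(204)
    expect_equal(mutual_information(a, b), oracle_mi(a, b), tolerance = 1e-10)
  }
  expect_identical(mutual_information(rep(1, 50), rnorm(50)), 0)
})

test_that("moving-average smoothing is a causal FIR with prefix handling", {
  expect_equal(smooth_series(rep(3, 50)), rep(3, 50))
  x <- numeric(60); x[25] <- 1
  sm <- smooth_series(x, order = 20)
  expect_equal(sm[25:44], rep(1 / 20, 20))
  expect_equal(sm[24], 0)
  expect_equal(sm[45], 0)
  # prefix: running mean of what exists
  y <- c(2, 4, 6)
  expect_equal(smooth_series(y, order = 20), c(2, 3, 4))
  # missing values are skipped
  z <- c(1, NA, 3)
  expect_equal(smooth_series(z, order = 2), c(1, 1, 3))
  # centered option stays centred on the impulse
  smc <- smooth_series(x, order = 21, align = "centered")
  expect_equal(which(smc > 0), 15:35)
})

test_that("features are invariant to offset and transform as expected under scaling", {
  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(204); y <- rnorm(204)
    c0 <- runif(1, -10, 10); s0 <- runif(1, 0.5, 3)
    expect_equal(moment_features(x + c0)$variance, moment_features(x)$variance,
                 tolerance = 1e-9)
    expect_equal(moment_features(s0 * x)$variance,
                 s0^2 * moment_features(x)$variance, tolerance = 1e-9)
    expect_equal(moment_features(s0 * x + c0)$skewness,
                 moment_features(x)$skewness, tolerance = 1e-8)
    expect_equal(moment_features(s0 * x + c0)$kurtosis,
                 moment_features(x)$kurtosis, tolerance = 1e-8)
    expect_equal(lag1_autocorrelation(s0 * x + c0), lag1_autocorrelation(x),
                 tolerance = 1e-8)
    expect_equal(mutual_information(s0 * x + c0, y), mutual_information(x, y),
                 tolerance = 1e-9)
  }
})

test_that("the tidy feature table covers every epoch, feature and population", {
  res <- sim_short(duration = 60)
  fs <- compute_features(res)
  expect_s3_class(fs, "feature_series")
  n_ep <- 29L
  expect_identical(nrow(fs), n_ep * (4L * 2L + 1L))
  expect_setequal(unique(fs$population), c("1", "2", "pair"))
  expect_setequal(unique(fs$feature),
                  c("variance", "skewness", "kurtosis", "lag1_ac",
                    "mutual_information"))
  expect_true(all(fs$raw_value[fs$feature == "variance"] >= 0))
  mi <- fs$raw_value[fs$feature == "mutual_information"]
  expect_true(all(mi >= 0))
  l1 <- fs$raw_value[fs$feature == "lag1_ac"]
  expect_true(all(abs(l1) <= 1))
  # smoothing preserves series length and the param column tracks the ramp
  expect_false(any(is.na(fs$smoothed_value[fs$feature == "variance"])))
  k_vals <- fs$param_value[fs$population == "1" & fs$feature == "variance"]
  expect_true(all(diff(k_vals) > 0))      # K ramps upward
  expect_equal(max(k_vals), 0.5 * 58 / 60, tolerance = 0.01)
})
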