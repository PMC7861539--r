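quiet_setting <- function(cfg = coupled_config())
  model_setting("quiet", cfg, ramp = NULL, targets = integer(0))

passive <- function() stimulus_protocol(0, targets = integer(0))

test_that("noise stream has the requested moments and independence", {
  expect_identical(noise_stream(noise_spec(90, 0), 1, 100), rep(90, 100))
  x <- noise_stream(noise_spec(90, 1.3), 11, 1e6)
  expect_lt(abs(mean(x) - 90), 0.01)
  expect_equal(sd(x), 1.3, tolerance = 0.01)
  y <- noise_stream(noise_spec(90, 1.3), 12, 1e5)
  expect_lt(abs(cor(x[1:1e5], y)), 0.01)
})

test_that("simulation is deterministic given the seed", {
  s <- build_setting("II-K")
  stim <- stimulus_protocol(120, targets = s$targets)
  r1 <- simulate_probing(s, stim, integration_spec(duration = 20, seed = 5))
  r2 <- simulate_probing(s, stim, integration_spec(duration = 20, seed = 5))
  expect_identical(r1$lfp, r2$lfp)
  r3 <- simulate_probing(s, stim, integration_spec(duration = 20, seed = 6))
  expect_false(identical(r3$lfp, r1$lfp))
})

test_that("delay buffer length follows the rounding convention", {
  # tau_d = 10 ms at dt = 1.95 ms -> 5 steps
  expect_identical(round(0.010 / 0.00195), 5)
  # delayed influence: with K > 0 population 1 feels population 2 only
  # after tau_d; identical runs with different tau_d diverge
  s1 <- quiet_setting(coupled_config(tau_d = 0.010))
  s2 <- quiet_setting(coupled_config(tau_d = 0.050))
  r1 <- simulate_probing(s1, passive(), integration_spec(duration = 5, seed = 2))
  r2 <- simulate_probing(s2, passive(), integration_spec(duration = 5, seed = 2))
  expect_false(identical(r1$lfp, r2$lfp))
})

test_that("the noiseless system settles on the independently solved fixed point", {
  cfg <- coupled_config(noise_1 = noise_spec(sigma = 0),
                        noise_2 = noise_spec(sigma = 0))
  res <- simulate_probing(quiet_setting(cfg), passive(),
                          integration_spec(duration = 60, seed = 1))
  n <- nrow(res$lfp)
  tail_idx <- (n - 999):n
  expect_lt(sd(res$lfp[tail_idx, 1]), 1e-6)
  expect_lt(sd(res$lfp[tail_idx, 2]), 1e-6)
  fp <- oracle_fixed_point(cfg)
  expect_lt(abs(res$lfp[n, 1] - fp$lfp), 1e-6)
  expect_lt(abs(res$lfp[n, 2] - fp$lfp), 1e-6)
})

test_that("halving the step changes the noiseless trajectory by well under 0.5% RMS", {
  cfg <- coupled_config(noise_1 = noise_spec(sigma = 0),
                        noise_2 = noise_spec(sigma = 0))
  s <- quiet_setting(cfg)
  r1 <- simulate_probing(s, passive(), integration_spec(dt = 0.00195, duration = 10))
  r2 <- simulate_probing(s, passive(), integration_spec(dt = 0.000975, duration = 10))
  x1 <- r1$lfp[, 1]
  x2 <- r2$lfp[seq(2, nrow(r2$lfp), by = 2), 1]   # co-located samples
  m <- min(length(x1), length(x2))
  rel <- sqrt(mean((x1[1:m] - x2[1:m])^2)) / sqrt(mean(x2[1:m]^2))
  expect_lt(rel, 0.005)
})

test_that("default parameters stay in the normal background regime", {
  res <- simulate_probing(quiet_setting(), passive(),
                          integration_spec(duration = 100, seed = 3))
  expect_lt(max(abs(res$lfp[res$time > 2, ])), 5)
})

test_that("a hyperexcitable population produces sustained discharges quickly", {
  cfg <- coupled_config(params_1 = population_params(A = 5.0))
  res <- simulate_probing(quiet_setting(cfg), passive(),
                          integration_spec(duration = 60, seed = 3))
  on <- detect_ictal_onset(res)
  expect_false(is.na(on$onset_latency_s[1]))
  expect_lt(on$onset_latency_s[1], 60)
})

test_that("stimulus onsets are on the time grid and amplitude-independent", {
  s <- build_setting("II-K")
  spec <- integration_spec(duration = 20, seed = 4)
  rp <- simulate_probing(s, stimulus_protocol(120, targets = s$targets), spec)
  r0 <- simulate_probing(s, stimulus_protocol(0, targets = s$targets), spec)
  expect_identical(rp$schedule, r0$schedule)
  expect_identical(length(rp$stim_onset_times), length(rp$schedule))
  expect_identical(r0$stim_onset_times, numeric(0))  # nothing delivered
  expect_true(all(rp$schedule / spec$dt - round(rp$schedule / spec$dt) < 1e-9))
})

test_that("sqrt-dt noise scaling increases per-step noise as specified", {
  s <- quiet_setting()
  r1 <- simulate_probing(s, passive(),
                         integration_spec(duration = 20, seed = 9))
  r2 <- simulate_probing(s, passive(),
                         integration_spec(duration = 20, seed = 9,
                                          noise_mode = "sqrt_dt"))
  sd1 <- sd(r1$lfp[r1$time > 2, 1])
  sd2 <- sd(r2$lfp[r2$time > 2, 1])
  expect_gt(sd2, sd1 * 2)   # 1/sqrt(0.00195) ~ 22.6-fold input scaling
})

test_that("an unstable step size is flagged", {
  expect_warning(
    tryCatch(simulate_probing(quiet_setting(), passive(),
                              integration_spec(dt = 0.01, duration = 3)),
             error = function(e) {
               expect_match(conditionMessage(e), "diverged")
               NULL
             }),
    "2/g")
})
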