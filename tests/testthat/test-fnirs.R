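test_that("spline correction removes an injected step artifact and is idempotent", {
  fs <- 10
  set.seed(17)
  base <- 0.02 * sin(2 * pi * 0.05 * seq(0, 120 - 1 / fs, by = 1 / fs)) +
    stats::rnorm(1200, sd = 0.002)
  clean <- trace(base, fs, "od", "OD")
  # clean trace comes back unchanged
  expect_identical(motion_correct_spline(clean)$values, clean$values)
  # 0.5 OD step artifact lasting 2 s
  art <- base
  art[601:620] <- art[601:620] + 0.5
  dirty <- trace(art, fs, "od", "OD")
  fixed <- motion_correct_spline(dirty)
  resid_step <- mean(fixed$values[601:620]) - mean(base[601:620])
  expect_lt(abs(resid_step), 0.1)  # >= 80% of the 0.5 OD step removed
  # samples far from the artifact untouched
  expect_identical(fixed$values[1:500], art[1:500])
  # second pass changes nothing
  expect_identical(motion_correct_spline(fixed)$values, fixed$values)
})

test_that("band-pass rejects DC and cardiac band but passes the task band", {
  fs <- 10
  const <- trace(rep(3, 1200), fs, units = "OD")
  expect_lt(max(abs(fnirs_bandpass(const)$values)), 1e-6)
  mid <- sine_trace(0.05, amp = 1, fs = fs, dur = 600, units = "OD")
  out <- fnirs_bandpass(mid)
  # mid-passband amplitude preserved within 5%
  core <- out$values[2000:4000]
  expect_equal(max(abs(core)), 1, tolerance = 0.05)
  cardiac <- sine_trace(1, amp = 1, fs = fs, dur = 600, units = "OD")
  expect_lt(max(abs(fnirs_bandpass(cardiac)$values[2000:4000])), 0.1)
  expect_error(fnirs_bandpass(trace(1:10, 0.3)), "Nyquist")
})

test_that("Beer-Lambert inversion is the exact inverse of the forward model", {
  geom <- channel_geometry()
  fs <- 10
  zero <- od_pair(trace(rep(0, 100), fs, units = "OD"),
                  trace(rep(0, 100), fs, units = "OD"))
  h0 <- mbll(zero, geom)
  expect_true(all(h0$hbo$values == 0) && all(h0$hbr$values == 0))
  # forward-simulate a known (1.0, -0.3) umol/L state, then invert
  hbo <- trace(rep(1.0, 50), fs, units = "umol/L")
  hbr <- trace(rep(-0.3, 50), fs, units = "umol/L")
  back <- mbll(mbll_forward(hbo, hbr, geom), geom)
  expect_equal(back$hbo$values, hbo$values, tolerance = 1e-12)
  expect_equal(back$hbr$values, hbr$values, tolerance = 1e-12)
  # HbT = HbO + HbR on randomized inputs
  set.seed(23)
  r1 <- trace(stats::rnorm(200), fs, units = "umol/L")
  r2 <- trace(stats::rnorm(200), fs, units = "umol/L")
  h <- mbll(mbll_forward(r1, r2, geom), geom)
  expect_equal(h$hbt$values, h$hbo$values + h$hbr$values)
  expect_error(channel_geometry(extinction = rbind(c(1, 2), c(2, 4))),
               "singular")
})

test_that("block averaging subtracts baselines and suppresses noise ~ 1/sqrt(n)", {
  fs <- 10
  resp <- c(rep(0, 20), 2 * sin(pi * (1:100) / 100), rep(0, 80))
  one <- trace(5 + resp, fs, units = "umol/L")
  ba <- block_average(one, event_list(0, 0, "t"), 20)
  expect_equal(ba$values, resp[1:200])  # baseline (5) removed
  two <- trace(c(5 + resp, 5 + resp), fs, units = "umol/L")
  ba2 <- block_average(two, event_list(c(0, 20), c(0, 20)), 20)
  expect_equal(ba2$values, ba$values)
  # 25 noisy blocks: residual noise SD reduced ~ 5x
  set.seed(29)
  n_b <- 25
  noise_sd <- 0.5
  sig <- rep(resp, n_b) + stats::rnorm(200 * n_b, sd = noise_sd)
  onsets <- event_list((0:(n_b - 1)) * 20, (0:(n_b - 1)) * 20)
  ba25 <- block_average(trace(sig, fs, units = "umol/L"), onsets, 20)
  resid_sd <- stats::sd(ba25$values - (resp - resp[1]))
  expect_lt(resid_sd, noise_sd / 5 * 1.8)
  expect_gt(resid_sd, noise_sd / 5 / 1.8)
  expect_error(block_average(one, event_list(15, 15), 20), "out of range")
})

test_that("task-window variance has its closed forms and offset invariance", {
  fs <- 10
  expect_equal(task_variance(trace(rep(2, 500), fs), 45), 0)
  # sinusoid amplitude A over whole periods: variance A^2 / 2
  s <- sine_trace(0.2, amp = 0.8, fs = fs, dur = 60, units = "umol/L")
  expect_equal(task_variance(s, 45), 0.8^2 / 2, tolerance = 0.02)
  shifted <- s; shifted$values <- shifted$values + 3
  expect_equal(task_variance(shifted, 45), task_variance(s, 45))
  expect_error(task_variance(trace(1:10, 10), 45), "shorter")
})

test_that("the full chain recovers a known response peak within 10%", {
  sim <- simulate_hemodynamics(n_blocks = 25, amp_hbo = 1,
                               artifact = TRUE, seed = 37)
  fx <- default_config()$fnirs
  clean <- function(tr) fnirs_bandpass(
    motion_correct_spline(tr, fx$detect_window, fx$detect_threshold,
                          fx$merge_gap, fx$spline_spar), fx$low, fx$high)
  od <- od_pair(clean(sim$od$od_lambda1), clean(sim$od$od_lambda2))
  hemo <- mbll(od)
  ba <- block_average(hemo$hbo, sim$onsets, 30)
  peak_ref <- max(sim$response$values)
  expect_equal(max(ba$values), peak_ref, tolerance = 0.10)
  # linearity in the artifact- and noise-free case: doubling the input
  # concentration doubles the recovered response exactly
  run_amp <- function(a) {
    s <- simulate_hemodynamics(n_blocks = 10, amp_hbo = a, cardiac_amp = 0,
                               resp_amp = 0, artifact = FALSE, seed = 37)
    od <- od_pair(fnirs_bandpass(s$od$od_lambda1),
                  fnirs_bandpass(s$od$od_lambda2))
    block_average(mbll(od)$hbo, s$onsets, 30)$values
  }
  expect_equal(run_amp(2), 2 * run_amp(1), tolerance = 1e-8)
})
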