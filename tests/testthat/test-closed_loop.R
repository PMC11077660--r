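test_that("template capture extracts, resamples and normalizes the first burst", {
  cfg <- controller_config()
  fs <- 1000
  # everywhere below threshold: nothing recorded
  low <- trace(rep(0.1, fs), fs, units = "V")
  expect_null(capture_template(low, cfg))
  # triangular burst peaking at 0.9 V
  tri <- trace(c(rep(0, 100), seq(0, 0.9, length.out = 200),
                 seq(0.9, 0, length.out = 200), rep(0, 100)), fs,
               units = "V")
  tpl <- capture_template(tri, cfg)
  expect_length(tpl, cfg$template_len)
  expect_equal(max(tpl), 1)
  expect_true(all(tpl >= 0 & tpl <= 1))
  # half-sine burst resamples onto the analytic half-sine
  n <- 400
  half <- trace(c(rep(0, 50), 0.8 * sin(pi * (1:n) / (n + 1)), rep(0, 50)),
                fs, units = "V")
  tpl2 <- capture_template(half, controller_config(t1 = 1e-4))
  expected <- sin(pi * seq(1 / (n + 1), n / (n + 1),
                           length.out = length(tpl2)))
  expect_equal(tpl2, expected / max(expected), tolerance = 1e-3)
})

test_that("intensity modulation follows the affine template law", {
  cfg <- controller_config()
  flat <- rep(1, cfg$template_len)
  expect_true(all(modulate_intensity(flat, 0, cfg)$values ==
                    cfg$stim$count_min))
  expect_true(all(modulate_intensity(flat, 1, cfg)$values ==
                    cfg$stim$count_max))
  tpl <- seq(0, 1, length.out = cfg$template_len)
  full <- modulate_intensity(tpl, 1, cfg)$values
  half <- modulate_intensity(tpl, 0.5, cfg)$values
  expect_equal(half - cfg$stim$count_min, (full - cfg$stim$count_min) / 2)
  # empty template falls back to constant count_min
  expect_true(all(modulate_intensity(NULL, 1, cfg)$values ==
                    cfg$stim$count_min))
  # spans the stimulation window
  expect_equal(trace_duration(modulate_intensity(flat, 1, cfg)),
               cfg$stim_window)
})

test_that("gain update follows the clamped multiplicative law with deadband", {
  cfg <- controller_config()
  expect_equal(update_gain(0.8, cfg$maxaa_target, cfg), 0.8)   # zero error
  expect_equal(update_gain(0.8, cfg$maxaa_target + 1.5, cfg), 0.8)  # deadband
  # 5 degrees above target at eta 0.02: gain multiplied by 1.10
  expect_equal(update_gain(1.0, rep(cfg$maxaa_target + 5, 10), cfg), 1.10)
  # clamped at the upper bound
  expect_equal(update_gain(cfg$gain_bounds[2], cfg$maxaa_target + 5, cfg),
               cfg$gain_bounds[2])
  expect_equal(update_gain(cfg$gain_bounds[1], cfg$maxaa_target - 50, cfg),
               cfg$gain_bounds[1])
})

test_that("closed-loop runs are deterministic and respect the voltage contract", {
  p <- make_profile("foot_drop")
  a <- run_closed_loop(p, controller_config(), 40, seed = 3)
  b <- run_closed_loop(p, controller_config(), 40, seed = 3)
  expect_identical(a$log, b$log)
  # delivered peaks in {0} U [138, 240]
  dp <- a$log$delivered_peak
  expect_true(all(dp == 0 | (dp >= 138 & dp <= 240)))
  expect_true(all(a$log$gain >= 0.05 & a$log$gain <= 2))
})

test_that("an RF burst below the trigger threshold never stimulates", {
  p <- make_profile("foot_drop", list(rf_burst_amp = 0.05))
  sim <- run_closed_loop(p, controller_config(), 25, seed = 8)
  expect_true(all(!sim$log$triggered))
  expect_true(all(sim$log$delivered_peak == 0))
  expect_true(all(sim$log$fatigue_scale == 1))
})

test_that("zero learning rate reduces to open-loop template FES", {
  p <- make_profile("foot_drop")
  cfg0 <- controller_config(gain_eta = 0)
  sim <- run_closed_loop(p, cfg0, 30, seed = 6)
  expect_true(all(sim$log$gain == cfg0$gain_init))
  expect_true(any(sim$log$triggered))
})

test_that("closed-loop keeps final-window variance at or below constant-mode", {
  p <- make_profile("foot_drop")
  cl <- summary(run_closed_loop(p, controller_config(), 150, seed = 11))
  ct <- summary(run_closed_loop(p, controller_config(), 150, seed = 11,
                                mode = "constant"))
  expect_lte(cl$maxaa_var, ct$maxaa_var)
  expect_lt(cl$maxaa_mean, ct$maxaa_mean)
})

test_that("feedback pulls the final-window mean toward the target", {
  p <- make_profile("foot_drop")
  unassisted <- p$maxaa_mean
  hits <- vapply(1:8, function(s) {
    sm <- summary(run_closed_loop(p, controller_config(), 120, seed = s),
                  window = 50)
    abs(sm$maxaa_mean - 100.72) < abs(unassisted - 100.72)
  }, logical(1))
  expect_true(all(hits))
})

test_that("a healthy profile under the controller does not run away", {
  p <- make_profile("healthy")
  sim <- run_closed_loop(p, controller_config(), 60, seed = 2)
  g <- sim$log$gain
  # healthy MaxAA sits at the target: gain stays inside the deadband hold
  expect_lt(mean(abs(diff(g))), controller_config()$gain_eta * 1)
})
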