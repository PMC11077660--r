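test_that("profile defaults carry the clinical operating points", {
  fd <- make_profile("foot_drop")
  expect_equal(fd$maxaa_mean, 105.53)
  expect_equal(fd$maxaa_var, 28.84)
  h <- make_profile("healthy")
  expect_equal(h$maxaa_mean, 100.72)
  expect_lt(h$maxaa_var, fd$maxaa_var)  # healthy gait is more concentrated
  expect_lt(fd$ta_burst_amp_affected, fd$ta_burst_amp)
  expect_error(make_profile("foot_drop", list(maxaa_var = -1)),
               "variances")
  expect_error(make_profile("healthy", list(nonsense = 1)), "unknown")
  expect_equal(make_profile("healthy", list(gcd_mean = 1.1))$gcd_mean, 1.1)
})

test_that("gait generation is deterministic and handles zero steps", {
  p <- make_profile("healthy")
  expect_equal(length(generate_gait(p, 0, 1000)$ankle_left), 0)
  expect_equal(nrow(generate_gait(p, 0, 1000)$steps), 0)
  a <- generate_gait(p, 5, 500, seed = 9)
  b <- generate_gait(p, 5, 500, seed = 9)
  expect_identical(a$ankle_right$values, b$ankle_right$values)
  expect_identical(a$cycles, b$cycles)
})

test_that("IMU decomposition reconstructs the ankle trace exactly", {
  p <- make_profile("foot_drop")
  rec <- generate_gait(p, 8, 500, seed = 2)
  for (s in c("left", "right")) {
    up <- rec[[paste0("imu_up_", s)]]
    dn <- rec[[paste0("imu_down_", s)]]
    expect_equal(ankle_angle(up, dn)$values,
                 rec[[paste0("ankle_", s)]]$values)
  }
  expect_equal(sum(rec$steps$tag == "right"), 8)
})

test_that("1000 generated cycles recover the MaxAA law within 3 standard errors", {
  p <- make_profile("foot_drop")
  rec <- generate_gait(p, 1000, 200, seed = 13)
  f <- segment_gait(rec$ankle_right, prominence = 3, min_separation = 0.5)
  expect_equal(nrow(f), 1000)
  se <- sqrt(28.84 / 1000)
  expect_lt(abs(mean(f$maxaa) - 105.53), 3 * se)
  expect_lt(abs(stats::var(f$maxaa) - 28.84), 4)
})

test_that("sEMG bursts are gait-locked with the foot-drop TA asymmetry", {
  p <- make_profile("foot_drop")
  rec <- generate_semg(p, generate_gait(p, 15, 1000), seed = 4)
  env_h <- emg_envelope(rec$ta_healthy)
  env_a <- emg_envelope(rec$ta_affected)
  cyc <- rec$cycles
  peak_in <- function(env, from, to) {
    w <- cifes:::window_trace(env, from, to)
    max(w$values)
  }
  right <- cyc[cyc$side == "right", ]
  left <- cyc[cyc$side == "left", ]
  # affected TA envelope peak below healthy-side TA peak on every cycle
  pk_a <- mapply(peak_in, list(env_a), right$cycle_start, right$cycle_end)
  pk_h <- mapply(peak_in, list(env_h), left$cycle_start, left$cycle_end)
  expect_true(all(pk_a < min(pk_h)))
  # one burst per cycle per muscle
  pk <- cifes:::find_peaks(env_h$values, prominence = 0.1, min_sep = 300L)
  expect_equal(length(pk), 15)
  # inter-burst envelope stays below the 0.15 V switch threshold
  mid_stance <- right$cycle_start + 0.25 * right$gcd
  gap <- mapply(peak_in, list(emg_envelope(rec$rf_affected)),
                mid_stance - 0.05, mid_stance + 0.05)
  expect_true(all(gap < 0.15))
})

test_that("intermittent walking inserts rests without breaking step counts", {
  p <- make_profile("healthy")
  rec <- generate_gait(p, 25, 500, seed = 7, rest_prob = 0.4)
  cont <- generate_gait(p, 25, 500, seed = 7)
  expect_equal(sum(rec$steps$tag == "right"), 25)
  # rests lengthen the recording
  expect_gt(trace_duration(rec$ankle_right), trace_duration(cont$ankle_right))
  # every cycle still carries its drawn extrema at the annotated times
  cyc <- rec$cycles[rec$cycles$side == "right", ]
  fs <- rec$sampling_rate
  expect_equal(rec$ankle_right$values[round(cyc$peak_time * fs) + 1],
               cyc$maxaa)
  expect_equal(rec$ankle_right$values[round(cyc$trough_time * fs) + 1],
               cyc$minaa)
})

test_that("dose-response is saturating, monotone and zero at rest", {
  p <- make_profile("foot_drop")
  expect_equal(dose_response(p, 0), 0)
  v <- seq(0, 240, by = 5)
  a <- dose_response(p, v)
  expect_true(all(diff(a) > 0))
  expect_true(all(a <= p$response_gain))
  expect_error(dose_response(p, -5), "non-negative")
  # mean MaxAA non-increasing in V (closed-form mean on a grid)
  m <- p$maxaa_mean - dose_response(p, v) / p$response_gain *
    (p$maxaa_mean - p$healthy_ref$maxaa_mean)
  expect_true(all(diff(m) < 0))
  expect_true(all(m > p$healthy_ref$maxaa_mean))  # never overshoots
})

test_that("the calibrated voltage reproduces the assisted operating point", {
  p <- make_profile("foot_drop")
  vcal <- calibrated_voltage(p)
  expect_gte(vcal, 138); expect_lte(vcal, 240)
  set.seed(31)
  d <- plant_step_response(p, NULL, vcal, n = 2e5)
  expect_equal(mean(d$maxaa), 102.81, tolerance = 3 * sqrt(17.71 / 2e5) /
                 102.81)
  expect_equal(stats::var(d$maxaa), 17.71, tolerance = 0.02)
  # V = 0 with fresh fatigue draws the unassisted law
  d0 <- plant_step_response(p, NULL, 0, n = 2e5)
  expect_equal(mean(d0$maxaa), 105.53, tolerance = 5e-4)
  expect_equal(stats::var(d0$maxaa), 28.84, tolerance = 0.02)
  # flat (unmodulated) drive leaves the statistics at baseline
  dc <- plant_step_response(p, NULL, 240, modulation = 0, n = 2e5)
  expect_equal(mean(dc$maxaa), 105.53, tolerance = 5e-4)
  expect_error(plant_step_response(p, NULL, -1), "non-negative")
})

test_that("fatigue accumulates, recovers, and favours split channels", {
  f <- fatigue_state(2)
  expect_equal(fatigue_scale(f), 1)
  # never stimulated: scale stays 1
  for (i in 1:10) f <- update_fatigue(f, c(0, 0), 10)
  expect_equal(fatigue_scale(f), 1)

  # closed-form single-site load after continuous stimulation
  f1 <- update_fatigue(fatigue_state(1), 900, 900)
  expect_equal(f1$load, 300 * (1 - exp(-3)))
  expect_equal(fatigue_scale(f1), exp(-0.00100918 * 300 * (1 - exp(-3))))
  expect_equal(fatigue_scale(f1), 0.75, tolerance = 0.001)

  # two sites alternating at equal total charge fatigue strictly less
  f2 <- update_fatigue(fatigue_state(2), c(450, 450), 900)
  expect_gt(fatigue_scale(f2), fatigue_scale(f1))

  # splitting inequality on a grid of loads
  for (expo in c(10, 100, 400, 900)) {
    single <- update_fatigue(fatigue_state(1), expo, 900)
    split <- update_fatigue(fatigue_state(2), c(expo / 2, expo / 2), 900)
    expect_gte(fatigue_scale(split), fatigue_scale(single))
  }

  # first-order recovery: rest much longer than tau restores within 1%
  rested <- update_fatigue(f1, 0, 10 * 300)
  expect_gt(fatigue_scale(rested), 0.99)
  expect_error(update_fatigue(f1, -1, 10), ">= 0")
  expect_error(update_fatigue(f1, 20, 10), "exceed")
})

test_that("crosstalk artifact decays exponentially with electrode distance", {
  x <- trace(numeric(1000), 1000, units = "V")
  ev <- event_list(0.2, 0.6, "stim")
  near <- crosstalk_artifact(x, ev, distance = 1)
  far <- crosstalk_artifact(x, ev, distance = 10)
  expect_gt(max(abs(near$values)), max(abs(far$values)))
  expect_equal(max(abs(near$values)) / max(abs(far$values)),
               exp(9 / 2.5), tolerance = 0.05)
  # silent outside the stimulation interval
  expect_true(all(near$values[trace_times(near) > 0.65] == 0))
})
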