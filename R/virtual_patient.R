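#' Virtual-subject profile
#'
#' Generative parameters of a virtual walker. Per-cycle maximum ankle angle
#' (MaxAA), minimum ankle angle (MinAA) and gait cycle duration (GCD) are
#' drawn from normal laws with the profile's means and variances; surface EMG
#' bursts are gait-locked band-limited noise with the stated envelope
#' amplitudes; and the plant's response to stimulation is a saturating
#' Hill-type dose-response with activity-dependent fatigue.
#'
#' Foot-drop defaults encode the clinical operating points: unassisted
#' affected-side MaxAA mean/variance 105.53 deg / 28.84 deg^2, normalizing to
#' 102.81 / 17.71 at the calibrated stimulation voltage, against a healthy
#' reference mean of 100.72 deg. The affected-side tibialis anterior burst is
#' attenuated relative to the healthy side (the electromyographic signature of
#' foot drop), while the rectus femoris burst is comparable to a healthy
#' subject's.
#'
#' @param kind `"healthy"` or `"foot_drop"`.
#' @param overrides named list of field overrides.
#' @return a list of class `"subject_profile"`.
#' @examples
#' make_profile("foot_drop")$maxaa_mean
#' @export
make_profile <- function(kind = c("healthy", "foot_drop"),
                         overrides = list()) {
  kind <- match.arg(kind)
  healthy_ref <- list(maxaa_mean = 100.72, maxaa_var = 10,
                      minaa_mean = 84, minaa_var = 8,
                      gcd_mean = 1.2, gcd_var = 0.01)
  p <- if (kind == "healthy") {
    c(healthy_ref,
      list(kind = kind,
           rf_burst_amp = 0.6, ta_burst_amp = 0.6,
           ta_burst_amp_affected = 0.6,
           semg_noise_floor = 0.02,
           response_gain = 4.81, response_v50 = 193,
           variance_shrink = NA_real_,
           assisted_maxaa_mean = NA_real_, assisted_maxaa_var = NA_real_,
           healthy_ref = healthy_ref))
  } else {
    list(kind = kind,
         maxaa_mean = 105.53, maxaa_var = 28.84,
         minaa_mean = 86, minaa_var = 18,
         gcd_mean = 1.4, gcd_var = 0.04,
         rf_burst_amp = 0.7, ta_burst_amp = 0.6,
         ta_burst_amp_affected = 0.25,
         semg_noise_floor = 0.02,
         response_gain = 4.81, response_v50 = 193,
         variance_shrink = NA_real_,
         assisted_maxaa_mean = 102.81, assisted_maxaa_var = 17.71,
         healthy_ref = healthy_ref)
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown profile field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
  }
  # variance_shrink follows from the calibration identity: at the calibrated
  # voltage the MaxAA law must hit (assisted_maxaa_mean, assisted_maxaa_var).
  if (is.na(p$variance_shrink)) {
    if (p$kind == "foot_drop") {
      f_cal <- (p$maxaa_mean - p$assisted_maxaa_mean) /
        (p$maxaa_mean - p$healthy_ref$maxaa_mean)
      p$variance_shrink <- (1 - p$assisted_maxaa_var / p$maxaa_var) / f_cal
    } else p$variance_shrink <- 0.5
  }
  validate_profile(p)
  structure(p, class = "subject_profile")
}

validate_profile <- function(p) {
  vars <- c("maxaa_var", "minaa_var", "gcd_var")
  if (any(unlist(p[vars]) < 0))
    stop("variances must be non-negative", call. = FALSE)
  if (p$gcd_mean <= 0) stop("gcd_mean must be positive", call. = FALSE)
  if (p$variance_shrink < 0 || p$variance_shrink > 1)
    stop("variance_shrink must lie in [0, 1]", call. = FALSE)
  if (p$kind == "foot_drop" && p$ta_burst_amp_affected >= p$ta_burst_amp)
    stop("foot-drop profiles need affected TA burst < healthy-side TA burst",
         call. = FALSE)
  if (p$response_v50 <= 0)
    stop("response_v50 must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s\n", x$kind))
  cat(sprintf("  MaxAA ~ N(%.2f, %.2f), MinAA ~ N(%.2f, %.2f), GCD ~ N(%.2f, %.3f)\n",
              x$maxaa_mean, x$maxaa_var, x$minaa_mean, x$minaa_var,
              x$gcd_mean, x$gcd_var))
  cat(sprintf("  TA burst %.2f V (affected %.2f V), RF burst %.2f V, floor %.2f V\n",
              x$ta_burst_amp, x$ta_burst_amp_affected, x$rf_burst_amp,
              x$semg_noise_floor))
  invisible(x)
}

# --- waveform synthesis -----------------------------------------------------

# Raised-cosine gait curve through per-cycle (MaxAA_k, MinAA_k, GCD_k).
# Cycles start at a MaxAA peak; the trough sits at 55% of the cycle, so the
# dorsiflexion rise occupies the last 45%. A half-cycle lead-in rises from a
# rest level to the first peak and a matching tail descends after the last,
# keeping every peak interior. Needs n+1 peak values for n cycles.
synth_side <- function(maxes, mins, gcds, fs, lead = 0.5) {
  n <- length(gcds)
  stopifnot(n >= 1, length(maxes) == n + 1, length(mins) == n)
  lead_n <- max(2L, as.integer(round(lead * fs)))
  gcd_n <- pmax(4L, as.integer(round(gcds * fs)))
  rest_level <- mean(mins)
  # lead-in ends exactly at the first peak sample
  ramp <- rest_level + (maxes[1] - rest_level) *
    (1 - cos(pi * seq_len(lead_n) / lead_n)) / 2
  segs <- vector("list", n)
  peak_idx <- integer(n + 1)
  trough_idx <- integer(n)
  peak_idx[1] <- lead_n
  for (k in seq_len(n)) {
    len <- gcd_n[k]
    t_off <- as.integer(round(0.55 * len))
    s1 <- seq_len(t_off)
    down <- mins[k] + (maxes[k] - mins[k]) * (1 + cos(pi * s1 / t_off)) / 2
    s2 <- seq_len(len - t_off)
    up <- mins[k] + (maxes[k + 1] - mins[k]) *
      (1 - cos(pi * s2 / (len - t_off))) / 2
    segs[[k]] <- c(down, up)
    trough_idx[k] <- peak_idx[k] + t_off
    peak_idx[k + 1] <- peak_idx[k] + len
  }
  tail_seg <- maxes[n + 1] + (rest_level - maxes[n + 1]) *
    (1 - cos(pi * seq_len(lead_n) / lead_n)) / 2
  values <- c(ramp, unlist(segs), tail_seg)
  list(values = values, peak_idx = peak_idx, trough_idx = trough_idx,
       gcd_n = gcd_n)
}

draw_cycles <- function(n, mm, mv, nm, nv, gm, gv) {
  maxaa <- stats::rnorm(n, mm, sqrt(mv))
  minaa <- stats::rnorm(n, nm, sqrt(nv))
  # keep per-cycle extrema ordered (astronomically rare at the defaults)
  bad <- minaa > maxaa - 2
  minaa[bad] <- maxaa[bad] - 2
  gcd <- pmax(0.4, stats::rnorm(n, gm, sqrt(gv)))
  data.frame(maxaa = maxaa, minaa = minaa, gcd = gcd)
}

#' Generate a bilateral gait recording
#'
#' Draws per-cycle (MaxAA, MinAA, GCD) for each side from the profile's normal
#' laws — the affected (right) side uses the profile's statistics, the
#' unaffected (left) side the healthy reference — and threads a smooth
#' raised-cosine curve through them, so that gait-feature extraction recovers
#' the drawn statistics. The two IMU component traces are emitted per side
#' such that the `imu_up + imu_down + 90` reconstruction reproduces the ankle
#' trace exactly. Ground-truth swing onsets are annotated per side.
#'
#' @param profile a [make_profile()] result.
#' @param n_steps number of gait cycles per side (`>= 0`).
#' @param sampling_rate sampling rate in Hz (`>= 50`).
#' @param seed optional integer; when given, seeds the RNG. Leave `NULL` to
#'   draw from the caller's seeded stream.
#' @param rest_prob probability of pausing after each step; `0` (default)
#'   gives continuous walking, positive values emulate intermittent walking
#'   with standing rests of `rest_range` seconds at the resting ankle angle.
#' @param rest_range `c(min, max)` rest duration in seconds.
#' @return a list of class `"gait_recording"` with ankle and IMU traces per
#'   side, a `steps` [event_list()] (tags `"left"`/`"right"`), and a `cycles`
#'   data frame of the ground-truth draws.
#' @export
generate_gait <- function(profile, n_steps, sampling_rate = 1000,
                          seed = NULL, rest_prob = 0,
                          rest_range = c(1, 3)) {
  stopifnot(inherits(profile, "subject_profile"), n_steps >= 0,
            sampling_rate >= 50, rest_prob >= 0, rest_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate
  hr <- profile$healthy_ref
  mk_trace <- function(v, lab) trace(v, fs, lab, "deg")
  if (n_steps == 0) {
    z <- numeric(0)
    return(structure(list(
      ankle_left = mk_trace(z, "ankle_left"),
      ankle_right = mk_trace(z, "ankle_right"),
      imu_up_left = mk_trace(z, "imu_up_left"),
      imu_down_left = mk_trace(z, "imu_down_left"),
      imu_up_right = mk_trace(z, "imu_up_right"),
      imu_down_right = mk_trace(z, "imu_down_right"),
      steps = event_list(), sampling_rate = fs, profile = profile,
      cycles = data.frame(), n_steps = 0L), class = "gait_recording"))
  }
  sides <- list(
    left = draw_cycles(n_steps, hr$maxaa_mean, hr$maxaa_var, hr$minaa_mean,
                       hr$minaa_var, hr$gcd_mean, hr$gcd_var),
    right = draw_cycles(n_steps, profile$maxaa_mean, profile$maxaa_var,
                        profile$minaa_mean, profile$minaa_var,
                        profile$gcd_mean, profile$gcd_var))
  # quantize durations to the sample grid so extracted GCDs match exactly
  sides <- lapply(sides, function(cyc) {
    cyc$gcd <- pmax(4L, as.integer(round(cyc$gcd * fs))) / fs
    cyc
  })
  # a trough must sit clearly below BOTH adjacent peaks or the cycle has no
  # peak-trough-peak shape; clamp the rare (<~2%) offending draws to 4 deg
  # below, comfortably past the default 3 deg detection prominence
  clamp_minaa <- function(cyc, extra_peak) {
    nxt <- c(cyc$maxaa[-1], extra_peak)
    cyc$minaa <- pmin(cyc$minaa, cyc$maxaa - 4, nxt - 4)
    cyc
  }
  # walking happens in bouts: continuous walking is one bout, intermittent
  # walking pauses after a step with probability rest_prob
  draw_peak <- function(s) if (s == "left")
    stats::rnorm(1, hr$maxaa_mean, sqrt(hr$maxaa_var))
  else stats::rnorm(1, profile$maxaa_mean, sqrt(profile$maxaa_var))
  lead <- 0.5 * profile$gcd_mean
  events <- list()
  cycles <- list()
  out <- list()
  side_values <- list()
  for (s in names(sides)) {
    cyc <- sides[[s]]
    breaks <- if (rest_prob > 0 && n_steps > 1)
      which(stats::runif(n_steps - 1) < rest_prob) else integer(0)
    bout_start <- c(1L, breaks + 1L)
    bout_end <- c(breaks, n_steps)
    values <- numeric(0)
    pk_abs <- tr_abs <- end_abs <- integer(n_steps)
    for (b in seq_along(bout_start)) {
      rows <- bout_start[b]:bout_end[b]
      extra_pk <- draw_peak(s)
      cycb <- clamp_minaa(cyc[rows, , drop = FALSE], extra_pk)
      cyc$minaa[rows] <- cycb$minaa
      sv <- synth_side(c(cycb$maxaa, extra_pk), cycb$minaa, cycb$gcd, fs,
                       lead)
      offset <- length(values)
      pk_abs[rows] <- offset + sv$peak_idx[-length(sv$peak_idx)]
      end_abs[rows] <- offset + sv$peak_idx[-1]
      tr_abs[rows] <- offset + sv$trough_idx
      values <- c(values, sv$values)
      if (b < length(bout_start)) {
        rest_n <- as.integer(round(stats::runif(1, rest_range[1],
                                                rest_range[2]) * fs))
        values <- c(values, rep(values[length(values)], rest_n))
      }
    }
    side_values[[s]] <- values
    pk_t <- (pk_abs - 1) / fs
    tr_t <- (tr_abs - 1) / fs
    end_t <- (end_abs - 1) / fs
    onset <- tr_t - 0.12 * cyc$gcd       # pre-swing RF activation onset
    events[[s]] <- data.frame(onset = onset, offset = end_t, tag = s)
    cycles[[s]] <- data.frame(side = s, cycle_index = seq_len(n_steps),
                              cyc, peak_time = pk_t, trough_time = tr_t,
                              cycle_start = pk_t, cycle_end = end_t)
  }
  n_common <- max(lengths(side_values))
  for (s in names(sides)) {
    v <- side_values[[s]]
    v <- c(v, rep(v[length(v)], n_common - length(v)))
    out[[paste0("ankle_", s)]] <- mk_trace(v, paste0("ankle_", s))
    out[[paste0("imu_up_", s)]] <- mk_trace(0.6 * (v - 90),
                                            paste0("imu_up_", s))
    out[[paste0("imu_down_", s)]] <- mk_trace(0.4 * (v - 90),
                                              paste0("imu_down_", s))
  }
  ev <- do.call(rbind, events)
  structure(c(out, list(
    steps = event_list(ev$onset, ev$offset, ev$tag),
    sampling_rate = fs, profile = profile,
    cycles = do.call(rbind, cycles), n_steps = as.integer(n_steps))),
    class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s, %d steps/side @ %g Hz, %.1f s%s\n",
              x$profile$kind, x$n_steps, x$sampling_rate,
              trace_duration(x$ankle_left),
              if (!is.null(x$rf_affected)) ", with sEMG" else ""))
  invisible(x)
}

# With the rectified-mean factor sqrt(pi/2) applied to the noise carrier, the
# default conditioning chain reproduces a ~0.3 s Hann burst's amplitude at its
# envelope peak to within a few percent; every consumer is a threshold, so no
# further calibration is needed.
ENVELOPE_CAL <- 1.0

#' Add gait-locked surface EMG to a recording
#'
#' Synthesizes raw sEMG as band-limited (20-450 Hz) Gaussian noise gated by
#' Hann windows locked to the annotated gait phases: a rectus femoris (RF)
#' complex on the affected side spanning late stance into the swing onset,
#' and one tibialis anterior (TA) burst per cycle over the dorsiflexion
#' phase — full amplitude on the healthy side, attenuated on the affected
#' side for a foot-drop profile. Between bursts the traces sit at the
#' profile's noise floor, low enough that the default envelope switch never
#' false-triggers.
#'
#' @param profile a [make_profile()] result.
#' @param gait a [generate_gait()] recording with step annotations.
#' @param seed optional integer seed.
#' @return the recording with `rf_affected`, `ta_healthy`, `ta_affected`
#'   [trace()]s (volts) added.
#' @export
generate_semg <- function(profile, gait, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(gait, "gait_recording"))
  if (!is.null(seed)) set.seed(seed)
  fs <- gait$sampling_rate
  n <- length(gait$ankle_left$values)
  mk <- function(lab) trace(numeric(0), fs, lab, "V")
  if (n == 0) {
    gait$rf_affected <- mk("rf_affected")
    gait$ta_healthy <- mk("ta_healthy")
    gait$ta_affected <- mk("ta_affected")
    return(gait)
  }
  cyc <- gait$cycles
  burst_env <- function(centres, widths) {
    env <- numeric(n)
    for (i in seq_along(centres)) {
      i0 <- max(1L, 1L + as.integer(ceiling((centres[i] - widths[i] / 2) * fs)))
      i1 <- min(n, 1L + as.integer(floor((centres[i] + widths[i] / 2) * fs)))
      if (i1 < i0) next
      idx <- i0:i1
      u <- ((idx - 1) / fs - centres[i]) / widths[i]
      env[idx] <- pmax(env[idx], cos(pi * u)^2)
    }
    env
  }
  make_muscle <- function(env, amp, lab) {
    carrier <- band_noise(n, fs)
    floor_noise <- band_noise(n, fs) * profile$semg_noise_floor
    raw <- carrier * env * amp * sqrt(pi / 2) * ENVELOPE_CAL + floor_noise
    trace(raw, fs, lab, "V")
  }
  right <- cyc[cyc$side == "right", ]
  left <- cyc[cyc$side == "left", ]
  # RF: late-stance + swing-onset compound per affected cycle
  rf_env <- pmax(
    burst_env(right$trough_time - 0.12 * right$gcd, rep(0.30, nrow(right))),
    burst_env(right$trough_time, rep(0.30, nrow(right))))
  # TA: dorsiflexion burst per cycle
  ta_c_right <- right$trough_time + 0.15 * right$gcd
  ta_c_left <- left$trough_time + 0.15 * left$gcd
  gait$rf_affected <- make_muscle(rf_env, profile$rf_burst_amp, "rf_affected")
  gait$ta_healthy <- make_muscle(
    burst_env(ta_c_left, rep(0.30, nrow(left))),
    profile$ta_burst_amp, "ta_healthy")
  gait$ta_affected <- make_muscle(
    burst_env(ta_c_right, rep(0.30, nrow(right))),
    profile$ta_burst_amp_affected, "ta_affected")
  gait
}

# --- plant: dose-response and fatigue ---------------------------------------

#' Saturating stimulation dose-response
#'
#' Assistance in degrees produced by a delivered peak voltage `v`:
#' `a(V) = scale * response_gain * V^2 / (V^2 + response_v50^2)`,
#' a Hill-type curve with a slight incline followed by saturation.
#' `scale` is the fatigue response scale in (0, 1].
#'
#' @param profile a [make_profile()] result.
#' @param v voltage(s), `>= 0`.
#' @param scale fatigue response scale.
#' @return assistance in degrees, bounded by `response_gain`.
#' @export
dose_response <- function(profile, v, scale = 1) {
  stopifnot(inherits(profile, "subject_profile"))
  if (any(v < 0)) stop("voltage must be non-negative", call. = FALSE)
  scale * profile$response_gain * v^2 / (v^2 + profile$response_v50^2)
}

#' Calibrated operating voltage of a foot-drop profile
#'
#' The fresh-muscle voltage at which the MaxAA law hits the profile's
#' assisted operating point (102.81 deg mean, 17.71 deg^2 variance at the
#' defaults). Lies inside the deliverable 138-240 V band.
#'
#' @param profile a foot-drop [make_profile()] result.
#' @return voltage in V.
#' @export
calibrated_voltage <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"),
            profile$kind == "foot_drop")
  f_cal <- (profile$maxaa_mean - profile$assisted_maxaa_mean) /
    (profile$maxaa_mean - profile$healthy_ref$maxaa_mean)
  profile$response_v50 * sqrt(f_cal / (1 - f_cal))
}

#' Per-cycle gait outcome under stimulation
#'
#' Draws one (or `n`) per-cycle `(MaxAA, MinAA, GCD)` outcome(s) at a
#' delivered peak voltage. The assistance fraction
#' `f = modulation * scale * V^2 / (V^2 + v50^2)` pulls the MaxAA mean from
#' the unassisted value toward the healthy reference (never past it) and
#' shrinks the MaxAA variance by `variance_shrink * f`; MinAA and GCD means
#' are normalized by the same fraction. `modulation` is the waveform-
#' modulation depth of the drive: 1 for a template-shaped (closed-loop)
#' burst, 0 for a flat constant-intensity burst, which moves the gait
#' statistics no closer to the healthy reference than no stimulation at all.
#'
#' @param profile a [make_profile()] result.
#' @param fatigue a [fatigue_state()], or `NULL` for fresh muscle.
#' @param voltage delivered peak voltage, `>= 0`.
#' @param modulation waveform-modulation depth in `[0, 1]`.
#' @param n number of cycles to draw.
#' @return a data frame with columns `maxaa`, `minaa`, `gcd`.
#' @export
plant_step_response <- function(profile, fatigue = NULL, voltage = 0,
                                modulation = 1, n = 1) {
  stopifnot(inherits(profile, "subject_profile"))
  if (voltage < 0) stop("voltage must be non-negative", call. = FALSE)
  stopifnot(modulation >= 0, modulation <= 1)
  scale <- if (is.null(fatigue)) 1 else fatigue_scale(fatigue)
  f <- modulation * dose_response(profile, voltage, scale) /
    profile$response_gain
  hr <- profile$healthy_ref
  m_max <- profile$maxaa_mean - f * (profile$maxaa_mean - hr$maxaa_mean)
  v_max <- profile$maxaa_var * (1 - profile$variance_shrink * f)
  m_min <- profile$minaa_mean - f * (profile$minaa_mean - hr$minaa_mean)
  m_gcd <- profile$gcd_mean - f * (profile$gcd_mean - hr$gcd_mean)
  data.frame(
    maxaa = stats::rnorm(n, m_max, sqrt(v_max)),
    minaa = stats::rnorm(n, m_min, sqrt(profile$minaa_var)),
    gcd = pmax(0.4, stats::rnorm(n, m_gcd, sqrt(profile$gcd_var))))
}

#' Per-site muscle fatigue state
#'
#' Stimulation exposure accumulates per electrode site as a leaky integrator
#' with recovery constant `tau`; the muscle's response scale decays
#' exponentially with the maximum per-site load,
#' `scale = exp(-k * max(load))`, so splitting a fixed exposure over several
#' sites always fatigues less than concentrating it on one. The default `k`
#' is calibrated so 900 s of continuous single-site stimulation costs about
#' a quarter of the response.
#'
#' @param n_sites number of stimulation sites (channels).
#' @param tau recovery time constant in seconds.
#' @param k response decay per unit load.
#' @return a list of class `"fatigue_state"`.
#' @export
fatigue_state <- function(n_sites = 1, tau = 300, k = 0.00100918) {
  stopifnot(n_sites >= 1, tau > 0, k >= 0)
  structure(list(load = numeric(n_sites), tau = tau, k = k),
            class = "fatigue_state")
}

#' @rdname fatigue_state
#' @param state a `"fatigue_state"`.
#' @export
fatigue_scale <- function(state) {
  stopifnot(inherits(state, "fatigue_state"))
  exp(-state$k * max(state$load, 0))
}

#' Advance the fatigue state over an interval
#'
#' Over `elapsed` seconds each site receives `exposure` seconds of
#' stimulation on-time (a constant rate `exposure/elapsed` is assumed); the
#' per-site load follows `load' = rate - load / tau` exactly over the
#' interval, so loads accumulate under stimulation and recover first-order
#' when idle.
#'
#' @param state a [fatigue_state()].
#' @param exposure per-site on-time in seconds (vector, `>= 0`, each
#'   `<= elapsed`).
#' @param elapsed interval length in seconds (`>= 0`).
#' @return the updated `"fatigue_state"`.
#' @export
update_fatigue <- function(state, exposure, elapsed) {
  stopifnot(inherits(state, "fatigue_state"), elapsed >= 0)
  exposure <- rep_len(as.numeric(exposure), length(state$load))
  if (any(exposure < 0)) stop("exposures must be >= 0", call. = FALSE)
  if (any(exposure > elapsed + 1e-9))
    stop("per-site exposure cannot exceed the elapsed interval",
         call. = FALSE)
  if (elapsed == 0) return(state)
  rate <- exposure / elapsed
  decay <- exp(-elapsed / state$tau)
  state$load <- rate * state$tau + (state$load - rate * state$tau) * decay
  state
}

#' Draw per-cycle bilateral feature rows directly from a profile
#'
#' Samples the same per-cycle laws used by [generate_gait()] (left = healthy
#' reference, right = profile) without synthesizing waveforms, and derives
#' the maximum dorsiflexion angular velocity from the raised-cosine cycle
#' geometry: `pi * (maxaa - minaa) / (2 * 0.45 * gcd)`. Convenient for
#' machine-learning experiments at scale.
#'
#' @param profile a [make_profile()] result.
#' @param n number of cycles.
#' @param seed optional integer seed.
#' @return a data frame with the 8 bilateral feature columns of
#'   [build_features()].
#' @export
sample_cycle_features <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  hr <- profile$healthy_ref
  maxvel <- function(d) pi * (d$maxaa - d$minaa) / (2 * 0.45 * d$gcd)
  l <- draw_cycles(n, hr$maxaa_mean, hr$maxaa_var, hr$minaa_mean,
                   hr$minaa_var, hr$gcd_mean, hr$gcd_var)
  r <- draw_cycles(n, profile$maxaa_mean, profile$maxaa_var,
                   profile$minaa_mean, profile$minaa_var,
                   profile$gcd_mean, profile$gcd_var)
  data.frame(
    l_maxaa = l$maxaa, l_minaa = l$minaa, l_maxvel = maxvel(l),
    l_gcd = l$gcd,
    r_maxaa = r$maxaa, r_minaa = r$minaa, r_maxvel = maxvel(r),
    r_gcd = r$gcd)
}

#' Stimulation crosstalk artifact on an sEMG trace
#'
#' Additive stimulation artifact picked up by recording electrodes at
#' `distance` centimetres from the stimulation site, decaying exponentially
#' with distance. Off by default in the generator; exposed to study electrode
#' separation.
#'
#' @param x an sEMG [trace()] in volts.
#' @param stim_events [event_list()] of stimulation on-intervals.
#' @param distance electrode separation in cm.
#' @param amp0 artifact amplitude at zero distance, volts.
#' @param decay exponential decay length, cm.
#' @return the trace with the artifact added.
#' @export
crosstalk_artifact <- function(x, stim_events, distance, amp0 = 0.5,
                               decay = 2.5) {
  stop_if_not_trace(x)
  stopifnot(inherits(stim_events, "event_list"), distance >= 0)
  amp <- amp0 * exp(-distance / decay)
  tt <- trace_times(x)
  art <- numeric(length(tt))
  for (i in seq_len(nrow(stim_events))) {
    on <- tt >= stim_events$onset[i] & tt <= stim_events$offset[i]
    art[on] <- amp * sin(2 * pi * 33 * tt[on])
  }
  x$values <- x$values + art
  x
}

#' Write a gait recording to a directory of CSV files
#'
#' One trace CSV per signal plus an `events.csv` of the ground-truth steps.
#'
#' @param rec a [generate_gait()] / [generate_semg()] recording.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "gait_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(rec))
    if (inherits(rec[[nm]], "trace"))
      write_trace_csv(rec[[nm]], file.path(dir, paste0(nm, ".csv")))
  write_events_csv(rec$steps, file.path(dir, "events.csv"))
  invisible(dir)
}
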