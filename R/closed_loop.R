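#' Closed-loop controller settings
#'
#' The controller records the healthy-side tibialis anterior envelope while it
#' exceeds `t1` (0.15 V), stores it as a normalized intensity template,
#' triggers stimulation when the affected-side rectus femoris envelope
#' crosses `t2` (= `t1`), scales the template by an adaptive gain, and
#' adjusts that gain from IMU ankle-angle feedback: when the recent mean
#' MaxAA sits above `maxaa_target` (assistance insufficient) the gain grows
#' multiplicatively, inside the `deadband` it is held, and it is always
#' clamped to `gain_bounds`.
#'
#' @param t1 healthy-side record threshold, volts.
#' @param t2 affected-side trigger threshold, volts.
#' @param template_len stored template length in samples.
#' @param gain_init,gain_eta,gain_bounds initial gain, learning rate, and
#'   `c(min, max)` clamp.
#' @param maxaa_target feedback target in degrees (healthy reference mean).
#' @param deadband half-width in degrees of the hold band around the target.
#' @param maxaa_window number of recent cycles averaged for feedback.
#' @param stim_window stimulation burst duration in seconds (the switch
#'   countdown).
#' @param stim a [stim_config()]; the controller defaults to the deployed
#'   dual-channel configuration, which alternates pulses between two sites on
#'   the same muscle to mitigate fatigue.
#' @return a list of class `"controller_config"`.
#' @export
controller_config <- function(t1 = 0.15, t2 = 0.15, template_len = 100,
                              gain_init = 0.5, gain_eta = 0.02,
                              gain_bounds = c(0.05, 2),
                              maxaa_target = 100.72, deadband = 2,
                              maxaa_window = 10, stim_window = 0.8,
                              stim = stim_config(n_channels = 2)) {
  stopifnot(t1 > 0, t2 > 0, template_len >= 2,
            length(gain_bounds) == 2, gain_bounds[1] <= gain_bounds[2],
            maxaa_window >= 1, stim_window > 0, deadband >= 0,
            inherits(stim, "stim_config"))
  structure(list(t1 = t1, t2 = t2, template_len = as.integer(template_len),
                 gain_init = gain_init, gain_eta = gain_eta,
                 gain_bounds = gain_bounds, maxaa_target = maxaa_target,
                 deadband = deadband, maxaa_window = as.integer(maxaa_window),
                 stim_window = stim_window, stim = stim),
            class = "controller_config")
}

#' Capture the intensity template from a healthy-side envelope
#'
#' Extracts the first maximal contiguous segment of the envelope above `t1`,
#' resamples it to `template_len` points by linear interpolation and
#' peak-normalizes it to 1. Returns `NULL` when no sample exceeds `t1`
#' (nothing recorded this gait). The storage is conceptually released after
#' each use: every cycle captures afresh.
#'
#' @param ta_envelope a [trace()] from [emg_envelope()].
#' @param cfg a [controller_config()].
#' @return numeric vector of length `template_len` with maximum exactly 1,
#'   or `NULL`.
#' @export
capture_template <- function(ta_envelope, cfg = controller_config()) {
  stop_if_not_trace(ta_envelope)
  v <- ta_envelope$values
  above <- v > cfg$t1
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  first <- which(r$values)[1]
  seg <- v[starts[first]:ends[first]]
  if (length(seg) == 1) seg <- rep(seg, 2)
  tpl <- stats::approx(seq_along(seg), seg, n = cfg$template_len)$y
  tpl / max(tpl)
}

#' Template-modulated intensity over one stimulation window
#'
#' `counts(t) = clamp(count_min + gain * template(t) * (count_max -
#' count_min), 0, count_max)`, spread over the stimulation window. An empty
#' template falls back to a constant `count_min` drive (logged).
#'
#' @param template numeric template from [capture_template()], or `NULL`.
#' @param gain current controller gain (`>= 0`).
#' @param cfg a [controller_config()].
#' @return a [trace()] of intensity counts spanning `cfg$stim_window`
#'   seconds.
#' @export
modulate_intensity <- function(template, gain, cfg = controller_config()) {
  stopifnot(inherits(cfg, "controller_config"), gain >= 0)
  sc <- cfg$stim
  if (is.null(template)) {
    log_line("empty template: falling back to constant count_min drive")
    template <- rep(1, cfg$template_len)
    counts <- rep(sc$count_min, cfg$template_len)
  } else {
    counts <- clamp(sc$count_min + gain * template *
                      (sc$count_max - sc$count_min), 0, sc$count_max)
  }
  trace(counts, length(counts) / cfg$stim_window, "intensity", "counts")
}

#' One feedback update of the controller gain
#'
#' `error = mean(recent_maxaa) - maxaa_target`. Inside the deadband the gain
#' is held; otherwise `gain' = clamp(gain * (1 + gain_eta * error),
#' gain_bounds)`. MaxAA above target (too little dorsiflexion assistance)
#' increases the gain.
#'
#' @param gain current gain.
#' @param recent_maxaa numeric vector of the last `maxaa_window` cycle
#'   maxima, degrees; at least one value.
#' @param cfg a [controller_config()].
#' @return the updated gain.
#' @export
update_gain <- function(gain, recent_maxaa, cfg = controller_config()) {
  stopifnot(length(recent_maxaa) >= 1)
  err <- mean(recent_maxaa) - cfg$maxaa_target
  if (abs(err) <= cfg$deadband) return(gain)
  clamp(gain * (1 + cfg$gain_eta * err), cfg$gain_bounds[1],
        cfg$gain_bounds[2])
}

#' Run the closed loop against the virtual patient
#'
#' Per gait cycle: the healthy-side TA envelope is captured as a template;
#' when the affected-side RF envelope crosses `t2` (threshold switch with the
#' countdown hold) a template-modulated biphasic burst is delivered and the
#' affected cycle's (MaxAA, MinAA, GCD) is drawn from the plant at the
#' delivered peak voltage; fatigue and (in `"closed"` mode) the adaptive gain
#' are updated. Modes: `"closed"` — full loop; `"constant"` — fixed flat
#' 240 V drive when triggered, no gain adaptation; `"none"` — no
#' stimulation. Deterministic given `seed`.
#'
#' @param profile a [make_profile()] result (usually foot drop).
#' @param cfg a [controller_config()].
#' @param n_steps number of gait cycles.
#' @param seed integer RNG seed.
#' @param mode `"closed"`, `"constant"` or `"none"`.
#' @param sampling_rate recording sampling rate, Hz.
#' @return an object of class `"cifes_sim"`: a per-step `log` data frame
#'   (`step`, `maxaa`, `minaa`, `gcd`, `triggered`, `delivered_peak`,
#'   `gain`, `fatigue_scale`), plus profile, config, mode and seed.
#' @export
run_closed_loop <- function(profile, cfg = controller_config(),
                            n_steps = 300, seed = 1,
                            mode = c("closed", "constant", "none"),
                            sampling_rate = 1000) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(cfg, "controller_config"), n_steps >= 1)
  mode <- match.arg(mode)
  set.seed(seed)
  rec <- generate_semg(profile, generate_gait(profile, n_steps,
                                              sampling_rate))
  env_ta <- emg_envelope(rec$ta_healthy)
  env_rf <- emg_envelope(rec$rf_affected)
  sw <- threshold_switch(env_rf, switch_config(
    threshold = cfg$t2, direction = "above",
    countdown = cfg$stim_window, refractory = 0.3))
  cyc_l <- rec$cycles[rec$cycles$side == "left", ]
  cyc_r <- rec$cycles[rec$cycles$side == "right", ]
  fat <- fatigue_state(cfg$stim$n_channels)
  gain <- cfg$gain_init
  maxaa_hist <- numeric(0)
  log_df <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    # template from the healthy side's cycle k (contralateral record phase)
    tpl <- capture_template(
      window_trace(env_ta, cyc_l$cycle_start[k], cyc_l$cycle_end[k]), cfg)
    triggered <- any(sw$activations$onset >= cyc_r$cycle_start[k] &
                       sw$activations$onset < cyc_r$cycle_end[k])
    if (mode == "none") triggered <- FALSE
    if (triggered) {
      if (mode == "constant") {
        intensity <- trace(rep(cfg$stim$count_max, cfg$template_len),
                           cfg$template_len / cfg$stim_window, "intensity",
                           "counts")
        modulation <- 0
      } else {
        intensity <- modulate_intensity(tpl, gain, cfg)
        modulation <- 1
      }
      pk_count <- max(intensity$values)
      delivered <- if (pk_count > 0)
        min(count_to_voltage(pk_count, cfg$stim), cfg$stim$v_cap) else 0
    } else {
      delivered <- 0
      modulation <- 1
    }
    draw <- plant_step_response(profile, fat, delivered, modulation)
    exposure <- if (triggered)
      rep(cfg$stim_window / cfg$stim$n_channels, cfg$stim$n_channels)
    else rep(0, cfg$stim$n_channels)
    fat <- update_fatigue(fat, pmin(exposure, draw$gcd), draw$gcd)
    maxaa_hist <- c(maxaa_hist, draw$maxaa)
    log_df[[k]] <- data.frame(
      step = k, maxaa = draw$maxaa, minaa = draw$minaa, gcd = draw$gcd,
      triggered = triggered, delivered_peak = delivered, gain = gain,
      fatigue_scale = fatigue_scale(fat))
    if (mode == "closed")
      gain <- update_gain(gain, utils::tail(maxaa_hist, cfg$maxaa_window),
                          cfg)
  }
  structure(list(log = do.call(rbind, log_df), profile = profile,
                 config = cfg, mode = mode, seed = seed,
                 n_steps = as.integer(n_steps)),
            class = "cifes_sim")
}

#' @export
print.cifes_sim <- function(x, ...) {
  cat(sprintf("<cifes_sim> %s mode, %d steps, seed %d\n", x$mode, x$n_steps,
              x$seed))
  print(summary(x))
  invisible(x)
}

#' Final-window summary of a closed-loop simulation
#'
#' @param object a `"cifes_sim"`.
#' @param window number of final steps summarized (default 100, clipped to
#'   the run length).
#' @param ... unused.
#' @return a list with the final-window MaxAA mean and unbiased variance,
#'   trigger rate, mean delivered peak and final fatigue scale.
#' @export
summary.cifes_sim <- function(object, window = 100, ...) {
  lg <- object$log
  w <- utils::tail(lg, min(window, nrow(lg)))
  out <- list(mode = object$mode, steps = nrow(lg), window = nrow(w),
              maxaa_mean = mean(w$maxaa), maxaa_var = stats::var(w$maxaa),
              trigger_rate = mean(lg$triggered),
              mean_delivered_peak = mean(w$delivered_peak[w$triggered]),
              final_gain = lg$gain[nrow(lg)],
              final_fatigue_scale = lg$fatigue_scale[nrow(lg)])
  class(out) <- "summary.cifes_sim"
  out
}

#' @export
print.summary.cifes_sim <- function(x, ...) {
  cat(sprintf("  final %d steps: MaxAA mean %.2f deg, variance %.2f deg^2\n",
              x$window, x$maxaa_mean, x$maxaa_var))
  cat(sprintf("  trigger rate %.1f%%, mean delivered peak %.1f V, gain %.3f, fatigue scale %.3f\n",
              100 * x$trigger_rate,
              if (is.nan(x$mean_delivered_peak)) 0 else
                x$mean_delivered_peak,
              x$final_gain, x$final_fatigue_scale))
  invisible(x)
}

#' @export
plot.cifes_sim <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$step, lg$maxaa, type = "l", xlab = "step",
                 ylab = "MaxAA (deg)", ...)
  graphics::abline(h = x$config$maxaa_target, lty = 2)
  graphics::plot(lg$step, lg$delivered_peak, type = "s", xlab = "step",
                 ylab = "delivered peak (V)")
  graphics::plot(lg$step, lg$gain, type = "l", xlab = "step", ylab = "gain")
  invisible(x)
}

#' Write a simulation log to CSV
#' @param x a `"cifes_sim"`.
#' @param path output path.
#' @export
write_sim_csv <- function(x, path) {
  stopifnot(inherits(x, "cifes_sim"))
  utils::write.csv(x$log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
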