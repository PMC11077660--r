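#' Stimulus-train settings
#'
#' Operating point of the stimulator: biphasic pulses at `pulse_freq` with an
#' anodic phase of `anodic_width` followed by a cathodic phase `width_ratio`
#' times wider (the 1:2 shape), intensity set by a pulse-count calibration
#' mapping `count_min..count_max` counts linearly onto
#' `v_at_count_min..v_at_count_max` volts, delivery capped at `v_cap`, and an
#' optional high-frequency intensity carrier (`carrier_freq`, `carrier_duty`)
#' chopping each phase.
#'
#' By default the cathodic amplitude is the anodic amplitude divided by
#' `width_ratio`, so the two phases carry equal and opposite charge
#' (charge-balanced stimulation); `equal_amplitude = TRUE` reproduces a
#' non-balanced symmetric rendering instead.
#'
#' @param pulse_freq pulse repetition rate, Hz.
#' @param anodic_width anodic phase width, seconds.
#' @param width_ratio cathodic-to-anodic width ratio.
#' @param carrier_freq,carrier_duty intensity-carrier frequency (Hz) and duty
#'   cycle (fraction in (0,1)).
#' @param count_min,count_max,v_at_count_min,v_at_count_max calibration-map
#'   anchors (counts and volts).
#' @param v_cap delivery voltage cap, volts.
#' @param n_channels number of output channels (pulses are dealt round-robin).
#' @param carrier logical; render the carrier inside each phase.
#' @param equal_amplitude logical; use -V instead of -V/ratio cathodically.
#' @return a list of class `"stim_config"`.
#' @export
stim_config <- function(pulse_freq = 33, anodic_width = 200e-6,
                        width_ratio = 2, carrier_freq = 16.67e3,
                        carrier_duty = 0.833, count_min = 20, count_max = 140,
                        v_at_count_min = 138, v_at_count_max = 255,
                        v_cap = 240, n_channels = 1, carrier = FALSE,
                        equal_amplitude = FALSE) {
  stopifnot(pulse_freq > 0, anodic_width > 0, width_ratio > 0,
            carrier_duty > 0, carrier_duty < 1,
            count_min < count_max, v_at_count_min <= v_at_count_max,
            n_channels >= 1)
  if (anodic_width * (1 + width_ratio) >= 1 / pulse_freq)
    stop("biphasic pulse does not fit within one pulse period", call. = FALSE)
  if (v_cap > v_at_count_max)
    stop("v_cap must not exceed v_at_count_max", call. = FALSE)
  structure(list(pulse_freq = pulse_freq, anodic_width = anodic_width,
                 width_ratio = width_ratio, carrier_freq = carrier_freq,
                 carrier_duty = carrier_duty, count_min = count_min,
                 count_max = count_max, v_at_count_min = v_at_count_min,
                 v_at_count_max = v_at_count_max, v_cap = v_cap,
                 n_channels = as.integer(n_channels), carrier = carrier,
                 equal_amplitude = equal_amplitude),
            class = "stim_config")
}

#' Intensity calibration: pulse counts to voltage
#'
#' Monotone piecewise-linear map anchored at
#' `(count_min, v_at_count_min)` and `(count_max, v_at_count_max)` —
#' with the defaults, 20 counts deliver 138 V and 140 counts 255 V.
#' Outside the anchors the map clamps to the anchor voltages. This is the raw
#' calibration, before the `v_cap` delivery cap.
#'
#' @param count numeric vector of intensity counts (`>= 0`).
#' @param cfg a [stim_config()].
#' @return voltages in V.
#' @export
count_to_voltage <- function(count, cfg = stim_config()) {
  stopifnot(inherits(cfg, "stim_config"))
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  c0 <- clamp(count, cfg$count_min, cfg$count_max)
  cfg$v_at_count_min + (c0 - cfg$count_min) *
    (cfg$v_at_count_max - cfg$v_at_count_min) /
    (cfg$count_max - cfg$count_min)
}

#' Render a biphasic pulse train from an intensity trace
#'
#' Pulses are emitted at `cfg$pulse_freq`; at each pulse onset the intensity
#' trace is sampled and held, converted through [count_to_voltage()], and
#' capped at `cfg$v_cap`. A count of zero (or below) suppresses the pulse
#' entirely, so delivered amplitudes are either 0 or within the calibrated
#' 138-240 V band. Each pulse is the anodic phase at `+V` for `anodic_width`
#' followed by the cathodic phase at `-V/width_ratio` (charge balanced) for
#' `width_ratio * anodic_width`. With `cfg$carrier = TRUE` both phases are
#' chopped by the intensity carrier.
#'
#' @param cfg a [stim_config()].
#' @param intensity a [trace()] of non-negative counts.
#' @param duration train duration in seconds.
#' @param sampling_rate rendering rate in Hz; must resolve the anodic phase,
#'   and be at least `10 * carrier_freq` when the carrier is rendered.
#' @return an object of class `"stim_train"`: per-channel [trace()]s, the
#'   pulse schedule, and `delivered_peak` in volts.
#' @export
render_pulse_train <- function(cfg = stim_config(), intensity, duration,
                               sampling_rate = 20e3) {
  stopifnot(inherits(cfg, "stim_config"), duration > 0)
  stop_if_not_trace(intensity)
  if (any(intensity$values < 0))
    stop("intensity counts must be non-negative", call. = FALSE)
  if (cfg$carrier && sampling_rate < 10 * cfg$carrier_freq)
    stop(sprintf(
      "sampling rate %g Hz cannot render the %g Hz carrier (need >= %g Hz)",
      sampling_rate, cfg$carrier_freq, 10 * cfg$carrier_freq), call. = FALSE)
  if (sampling_rate * cfg$anodic_width < 1)
    stop("sampling rate too low to resolve the anodic phase", call. = FALSE)

  total_w <- cfg$anodic_width * (1 + cfg$width_ratio)
  t_p <- seq(0, duration - total_w, by = 1 / cfg$pulse_freq)
  idx <- clamp(1L + as.integer(floor((t_p - intensity$start_time) *
                                       intensity$sampling_rate)),
               1L, max(1L, length(intensity$values)))
  counts <- if (length(intensity$values)) intensity$values[idx] else
    rep(0, length(t_p))
  volts <- ifelse(counts > 0,
                  pmin(count_to_voltage(pmax(counts, 0), cfg), cfg$v_cap), 0)
  schedule <- data.frame(
    time = t_p, count = counts, voltage = volts,
    channel = ((seq_along(t_p) - 1L) %% cfg$n_channels) + 1L)
  train <- structure(list(schedule = schedule, config = cfg,
                          duration = duration,
                          sampling_rate = sampling_rate,
                          delivered_peak = if (length(volts)) max(volts) else 0,
                          channels = NULL),
                     class = "stim_train")
  train$channels <- render_channels(train)
  train
}

# Rasterize the pulse schedule of a stim_train into per-channel traces.
render_channels <- function(train) {
  cfg <- train$config
  fs <- train$sampling_rate
  n <- as.integer(round(train$duration * fs))
  grid_t <- (seq_len(n) - 1) / fs
  lapply(seq_len(cfg$n_channels), function(ch) {
    v <- numeric(n)
    sub <- train$schedule[train$schedule$channel == ch &
                            train$schedule$voltage > 0, , drop = FALSE]
    na <- as.integer(round(cfg$anodic_width * fs))
    nc <- as.integer(round(cfg$width_ratio * cfg$anodic_width * fs))
    for (r in seq_len(nrow(sub))) {
      t0 <- sub$time[r]
      V <- sub$voltage[r]
      # integer phase extents so charge balance is exact on the grid
      i0 <- 1L + as.integer(ceiling(t0 * fs - 1e-9))
      ia <- i0:min(n, i0 + na - 1L)
      ic <- if (i0 + na <= n) (i0 + na):min(n, i0 + na + nc - 1L)
        else integer(0)
      vc <- if (cfg$equal_amplitude) -V else -V / cfg$width_ratio
      if (cfg$carrier) {
        gate <- function(i) ((grid_t[i] - t0) %% (1 / cfg$carrier_freq)) <
          cfg$carrier_duty / cfg$carrier_freq
        v[ia] <- V * gate(ia)
        v[ic] <- vc * gate(ic)
      } else {
        v[ia] <- V
        v[ic] <- vc
      }
    }
    trace(v, fs, sprintf("stim.ch%d", ch), "V")
  })
}

#' Deal the pulses of a train across output channels
#'
#' Round-robin reassignment of the pulse schedule over `n_channels`: channel
#' pulse-time sets are disjoint, their union is the original pulse set, and
#' each channel runs at `pulse_freq / n_channels`. Alternating sites this way
#' is the fatigue-mitigation strategy of multi-channel FES.
#'
#' @param train a `"stim_train"`.
#' @param n_channels number of channels (`>= 1`).
#' @return a new `"stim_train"` with `n_channels` channel traces.
#' @export
split_channels <- function(train, n_channels) {
  stopifnot(inherits(train, "stim_train"), n_channels >= 1)
  cfg <- train$config
  cfg$n_channels <- as.integer(n_channels)
  out <- train
  out$config <- cfg
  out$schedule$channel <- ((seq_len(nrow(out$schedule)) - 1L) %%
                             cfg$n_channels) + 1L
  out$channels <- render_channels(out)
  out
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf(
    "<stim_train> %d pulses over %.3g s, %d channel(s), delivered peak %.1f V\n",
    nrow(x$schedule), x$duration, x$config$n_channels, x$delivered_peak))
  invisible(x)
}
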