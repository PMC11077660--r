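#' Envelope-extraction settings for the sEMG conditioning chain
#'
#' The conditioning chain mirrors a hardware front end: a gain stage, full-wave
#' rectification, a 2nd-order causal Butterworth low-pass, a trailing
#' integration window normalized by its length (a windowed mean), and a final
#' moving average. An optional saturation clamp models the 0-3.3 V ADC input
#' range.
#'
#' @param lowpass_cutoff low-pass cutoff in Hz.
#' @param integrate_window integration window in seconds.
#' @param moving_avg_window moving-average window in seconds.
#' @param gain dimensionless amplification folded into one scalar.
#' @param clamp saturation level in volts applied to the output; `NA` disables.
#' @return a list of class `"envelope_config"`.
#' @export
envelope_config <- function(lowpass_cutoff = 10, integrate_window = 0.05,
                            moving_avg_window = 0.10, gain = 1, clamp = 3.3) {
  stopifnot(lowpass_cutoff > 0, integrate_window > 0, moving_avg_window > 0,
            gain > 0)
  structure(list(lowpass_cutoff = lowpass_cutoff,
                 integrate_window = integrate_window,
                 moving_avg_window = moving_avg_window,
                 gain = gain, clamp = clamp),
            class = "envelope_config")
}

#' Causal moving average of a trace
#'
#' Trailing (causal) sliding mean over `window` seconds; the first samples use
#' the available partial window, so a constant trace maps to itself and a unit
#' step ramps linearly to 1 over exactly one window.
#'
#' @param x a [trace()].
#' @param window window length in seconds; must cover at least one sample
#'   period.
#' @return a [trace()] of the same length and sampling rate.
#' @export
moving_average <- function(x, window) {
  stop_if_not_trace(x)
  if (!is.numeric(window) || window <= 0)
    stop("window must be positive", call. = FALSE)
  n <- as.integer(round(window * x$sampling_rate))
  if (n < 1)
    stop("window must cover at least one sample period", call. = FALSE)
  v <- x$values
  if (!length(v) || n == 1) return(x)
  cs <- cumsum(v)
  out <- numeric(length(v))
  head_n <- seq_len(min(n, length(v)))
  out[head_n] <- cs[head_n] / head_n
  if (length(v) > n) {
    i <- (n + 1):length(v)
    out[i] <- (cs[i] - cs[i - n]) / n
  }
  trace(out, x$sampling_rate, x$label, x$units, x$start_time)
}

#' Nonlinear envelope of a raw sEMG trace
#'
#' Applies, in order: gain, full-wave rectification, a 2nd-order causal
#' Butterworth low-pass at `cfg$lowpass_cutoff`, a trailing windowed mean over
#' `cfg$integrate_window`, a moving average over `cfg$moving_avg_window`, and
#' the ADC saturation clamp. A multi-peaked physiological burst becomes one
#' smooth non-negative hump; a zero-mean sine of amplitude `A` settles at
#' `gain * 2 A / pi`, the mean of the rectified sine.
#'
#' @param raw a [trace()] of raw sEMG in volts.
#' @param cfg an [envelope_config()].
#' @return a [trace()] in volts, same length and sampling rate as `raw`.
#' @export
emg_envelope <- function(raw, cfg = envelope_config()) {
  stop_if_not_trace(raw)
  stopifnot(inherits(cfg, "envelope_config"))
  if (raw$sampling_rate < 2 * cfg$lowpass_cutoff)
    stop(sprintf(
      "sampling rate %g Hz violates the Nyquist precondition for a %g Hz cutoff",
      raw$sampling_rate, cfg$lowpass_cutoff), call. = FALSE)
  if (!length(raw$values))
    return(trace(numeric(0), raw$sampling_rate, paste0(raw$label, ".env"),
                 "V", raw$start_time))
  x <- abs(cfg$gain * raw$values)
  b <- signal::butter(2, cfg$lowpass_cutoff / (raw$sampling_rate / 2))
  x <- as.numeric(signal::filter(b, x))
  out <- trace(x, raw$sampling_rate, paste0(raw$label, ".env"), "V",
               raw$start_time)
  out <- moving_average(out, cfg$integrate_window)
  out <- moving_average(out, cfg$moving_avg_window)
  # causal IIR stage can undershoot very slightly; the envelope is non-negative
  out$values <- pmax(out$values, 0)
  if (is.finite(cfg$clamp)) out$values <- pmin(out$values, cfg$clamp)
  out
}
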