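#' Threshold-switch settings
#'
#' One configuration type serves the three activation switches studied for
#' FES gating: the sEMG envelope switch (`threshold` 0.15-0.2 V, direction
#' `"above"`), the shank tilt switch (threshold -25 deg, direction `"below"`),
#' and the foot-pressure switch (0.25 V, `"above"`). After a trigger the
#' switch stays on for at least `countdown` seconds (the programmed hold), and
#' a new onset is refused within `refractory` seconds of the previous onset.
#'
#' @param threshold threshold in the signal's units.
#' @param direction `"above"` or `"below"`.
#' @param countdown minimum on-duration after a trigger, seconds.
#' @param refractory minimum spacing between onsets, seconds.
#' @return a list of class `"switch_config"`.
#' @export
switch_config <- function(threshold = 0.15, direction = c("above", "below"),
                          countdown = 0.8, refractory = 0.3) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), countdown >= 0, refractory >= 0)
  structure(list(threshold = threshold, direction = direction,
                 countdown = countdown, refractory = refractory),
            class = "switch_config")
}

#' Threshold-triggered activation switch with countdown hold
#'
#' The switch turns on at the first sample strictly beyond the threshold in
#' the configured direction, provided at least one preceding sample lay on
#' the other side (a crossing, not an initial condition). It stays on for
#' `max(countdown, time the signal remains beyond threshold)` and will not
#' re-trigger within `refractory` seconds of the previous onset.
#'
#' @param x a non-empty [trace()].
#' @param cfg a [switch_config()].
#' @return a list with `state`, a 0/1 [trace()] aligned with `x`, and
#'   `activations`, an [event_list()] with one event per on-interval.
#' @export
threshold_switch <- function(x, cfg = switch_config()) {
  stop_if_not_trace(x)
  stopifnot(inherits(cfg, "switch_config"))
  if (!length(x$values)) stop("trace is empty", call. = FALSE)
  beyond <- if (cfg$direction == "above") x$values > cfg$threshold
            else x$values < cfg$threshold
  tt <- trace_times(x)
  n <- length(beyond)
  state <- integer(n)
  onsets <- offsets <- numeric(0)
  on <- FALSE
  onset_t <- -Inf
  last_onset <- -Inf
  last_beyond_t <- -Inf
  for (i in seq_len(n)) {
    if (!on) {
      if (beyond[i] && i > 1 && !beyond[i - 1] &&
          (tt[i] - last_onset) >= cfg$refractory) {
        on <- TRUE
        onset_t <- tt[i]
        last_onset <- tt[i]
        last_beyond_t <- tt[i]
      }
    } else {
      if (beyond[i]) last_beyond_t <- tt[i]
      if (!beyond[i] && tt[i] >= onset_t + cfg$countdown &&
          tt[i] > last_beyond_t) {
        on <- FALSE
        onsets <- c(onsets, onset_t)
        offsets <- c(offsets, tt[i])
      }
    }
    state[i] <- as.integer(on)
  }
  if (on) {
    onsets <- c(onsets, onset_t)
    offsets <- c(offsets, tt[n])
  }
  list(state = trace(state, x$sampling_rate, paste0(x$label, ".switch"),
                     "on/off", x$start_time),
       activations = event_list(onsets, offsets,
                                rep("activation", length(onsets))))
}

#' Switch accuracy against ground-truth step onsets
#'
#' Greedy one-to-one matching, in time order, of activation onsets to true
#' swing onsets within `tolerance` seconds. The score
#' `matched / max(n_true, n_activations)` penalizes misses and false triggers
#' symmetrically; an ideal switch scores 1.
#'
#' @param activations [event_list()] of switch activations.
#' @param truth_steps [event_list()] of ground-truth swing onsets.
#' @param tolerance matching window in seconds (`>= 0`).
#' @return a fraction in `[0, 1]`; 1 when both lists are empty.
#' @export
switch_accuracy <- function(activations, truth_steps, tolerance = 0.3) {
  stopifnot(inherits(activations, "event_list"),
            inherits(truth_steps, "event_list"), tolerance >= 0)
  a <- sort(activations$onset)
  b <- sort(truth_steps$onset)
  if (!length(a) && !length(b)) return(1)
  matched <- 0L
  i <- j <- 1L
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tolerance) {
      matched <- matched + 1L
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  matched / max(length(a), length(b))
}
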