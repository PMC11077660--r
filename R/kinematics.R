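#' Ankle joint angle from the two IMU attitude traces
#'
#' Two inertial sensors bracket the ankle (one on the shank, one on the foot);
#' in quiet stance both read 0 and the joint is at its prestored 90 degrees.
#' The joint angle is reconstructed sample-for-sample as
#' `imu_up + imu_down + 90`.
#'
#' @param imu_up,imu_down [trace()]s in degrees with equal length and
#'   sampling rate.
#' @return a [trace()] of ankle angle in degrees.
#' @export
ankle_angle <- function(imu_up, imu_down) {
  stop_if_not_trace(imu_up); stop_if_not_trace(imu_down)
  if (length(imu_up$values) != length(imu_down$values))
    stop("imu_up and imu_down must have equal length", call. = FALSE)
  if (imu_up$sampling_rate != imu_down$sampling_rate)
    stop("imu_up and imu_down must share a sampling rate", call. = FALSE)
  trace(imu_up$values + imu_down$values + 90, imu_up$sampling_rate,
        "ankle_angle", "deg", imu_up$start_time)
}

#' Angular velocity of an angle trace
#'
#' Central finite difference scaled by the sampling rate; one-sided
#' differences at the endpoints.
#'
#' @param angle a [trace()] in degrees with at least 2 samples.
#' @return a [trace()] in deg/s.
#' @export
angular_velocity <- function(angle) {
  stop_if_not_trace(angle)
  v <- angle$values
  n <- length(v)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  fs <- angle$sampling_rate
  out <- numeric(n)
  out[1] <- (v[2] - v[1]) * fs
  out[n] <- (v[n] - v[n - 1]) * fs
  if (n > 2) out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
  trace(out, fs, paste0(angle$label, ".vel"), "deg/s", angle$start_time)
}

# Local maxima with topographic prominence (Findpeaks-style semantics).
# Returns indices of strict local maxima whose prominence reaches `prominence`,
# thinned so that retained peaks are at least `min_sep` samples apart
# (keeping the higher peak).
find_peaks <- function(v, prominence = 0, min_sep = 1L) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- v[i]
    left <- if (i > 1) {
      higher <- which(v[1:(i - 1)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(v[lo:(i - 1)])
    } else h
    right <- if (i < n) {
      higher <- which(v[(i + 1):n] > h)
      hi <- if (length(higher)) i + min(higher) - 1L else n
      min(v[(i + 1):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (length(keep) > 1 && min_sep > 1) {
    ord <- keep[order(v[keep], decreasing = TRUE)]
    taken <- integer(0)
    for (i in ord)
      if (!length(taken) || all(abs(taken - i) >= min_sep))
        taken <- c(taken, i)
    keep <- sort(taken)
  }
  keep
}

#' Segment an ankle-angle trace into gait cycles
#'
#' Peaks and troughs are located Findpeaks-style with a prominence criterion
#' (and a minimum peak separation to suppress noise-induced double peaks).
#' Each adjacent pair of peaks delimits one cycle: `maxaa` is the left peak
#' value, `minaa` the deepest trough within the cycle, `gcd` the inter-peak
#' sample count times the sample period, and `max_ang_vel` the maximum
#' angular velocity within the dorsiflexion interval (trough to next peak).
#'
#' @param angle a non-empty [trace()] in degrees.
#' @param prominence peak prominence in degrees.
#' @param min_separation minimum peak spacing in seconds.
#' @param side `"left"` or `"right"`, recorded per cycle.
#' @return a data frame of class `"gait_features"` with columns
#'   `cycle_index`, `side`, `maxaa`, `minaa`, `max_ang_vel`, `gcd`,
#'   `peak_time`, `trough_time`; zero rows when fewer than 2 peaks are found.
#' @export
segment_gait <- function(angle, prominence = 3, min_separation = 0.5,
                         side = "right") {
  stop_if_not_trace(angle)
  if (!length(angle$values)) stop("trace is empty", call. = FALSE)
  fs <- angle$sampling_rate
  empty <- structure(
    data.frame(cycle_index = integer(0), side = character(0),
               maxaa = numeric(0), minaa = numeric(0),
               max_ang_vel = numeric(0), gcd = numeric(0),
               peak_time = numeric(0), trough_time = numeric(0)),
    class = c("gait_features", "data.frame"))
  if (length(angle$values) < 3) return(empty)
  pk <- find_peaks(angle$values, prominence,
                   max(1L, as.integer(round(min_separation * fs))))
  if (length(pk) < 2) {
    log_line("segment_gait: %d peak(s) found, no complete cycle", length(pk))
    return(empty)
  }
  vel <- angular_velocity(angle)$values
  n_cyc <- length(pk) - 1L
  res <- lapply(seq_len(n_cyc), function(k) {
    i0 <- pk[k]; i1 <- pk[k + 1]
    if (i1 - i0 < 2) return(NULL)
    inner <- (i0 + 1):(i1 - 1)
    ti <- inner[which.min(angle$values[inner])]
    data.frame(cycle_index = k, side = side,
               maxaa = angle$values[i0],
               minaa = angle$values[ti],
               max_ang_vel = max(vel[ti:i1]),
               gcd = (i1 - i0) / fs,
               peak_time = angle$start_time + (i0 - 1) / fs,
               trough_time = angle$start_time + (ti - 1) / fs)
  })
  structure(do.call(rbind, res), class = c("gait_features", "data.frame"))
}

#' Histogram and moment summary of a feature distribution
#'
#' Histogram at a fixed bin width aligned to multiples of `bin_width`
#' (5 degrees by default, the interval used for gait-angle distribution
#' plots), together with the sample mean and unbiased sample variance. The
#' moments are computed from the raw values; bins are reporting only.
#'
#' @param values numeric vector with at least 2 values.
#' @param bin_width bin width in the values' units.
#' @return a list of class `"dist_summary"`: `bin_edges`, `counts`, `mean`,
#'   `variance`, `n`, `bin_width`.
#' @export
distribution_summary <- function(values, bin_width = 5) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("need at least 2 values for a variance", call. = FALSE)
  stopifnot(bin_width > 0)
  edges <- seq(floor(min(values) / bin_width) * bin_width,
               ceiling(max(values) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2) edges <- c(edges, edges + bin_width)
  counts <- graphics::hist(values, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  structure(list(bin_edges = edges, counts = counts,
                 mean = mean(values), variance = stats::var(values),
                 n = length(values), bin_width = bin_width),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf(
    "<dist_summary> n = %d, mean = %.3f, variance = %.3f (%g-unit bins, %d bins)\n",
    x$n, x$mean, x$variance, x$bin_width, length(x$counts)))
  invisible(x)
}
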