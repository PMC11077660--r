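#' Channel geometry for the modified Beer-Lambert conversion
#'
#' Source-detector distance, differential pathlength factors and the 2x2
#' molar extinction matrix (rows = wavelengths, columns = HbO, HbR, in
#' 1/(mM*cm)). The bundled defaults are standard literature coefficients for
#' 760/850 nm continuous-wave NIRS with adult-head pathlength factors; all
#' are overridable.
#'
#' @param distance source-detector distance in cm.
#' @param wavelengths two distinct wavelengths in nm (labels only).
#' @param dpf differential pathlength factor per wavelength.
#' @param extinction 2x2 matrix of extinction coefficients, 1/(mM*cm).
#' @return a list of class `"channel_geometry"`.
#' @export
channel_geometry <- function(distance = 3, wavelengths = c(760, 850),
                             dpf = c(6, 6),
                             extinction = rbind(c(0.586, 1.548),
                                                c(1.058, 0.691))) {
  stopifnot(distance > 0, length(wavelengths) == 2,
            wavelengths[1] != wavelengths[2], length(dpf) == 2,
            all(dpf > 0), all(dim(extinction) == c(2, 2)))
  cond <- kappa(extinction)
  if (!is.finite(cond) || abs(det(extinction)) < 1e-12)
    stop("extinction matrix is singular", call. = FALSE)
  log_line("channel geometry: extinction condition number %.2f", cond)
  dimnames(extinction) <- list(paste0(wavelengths, "nm"), c("HbO", "HbR"))
  structure(list(distance = distance, wavelengths = wavelengths,
                 dpf = dpf, extinction = extinction),
            class = "channel_geometry")
}

#' Optical-density pair for one channel
#'
#' @param od_lambda1,od_lambda2 [trace()]s of optical-density change at the
#'   two wavelengths; equal length and sampling rate.
#' @param wavelengths the two wavelengths in nm.
#' @return a list of class `"od_pair"`.
#' @export
od_pair <- function(od_lambda1, od_lambda2, wavelengths = c(760, 850)) {
  stop_if_not_trace(od_lambda1); stop_if_not_trace(od_lambda2)
  if (length(od_lambda1$values) != length(od_lambda2$values) ||
      od_lambda1$sampling_rate != od_lambda2$sampling_rate)
    stop("the two optical-density traces must share length and sampling rate",
         call. = FALSE)
  stopifnot(wavelengths[1] != wavelengths[2])
  structure(list(od_lambda1 = od_lambda1, od_lambda2 = od_lambda2,
                 wavelengths = wavelengths), class = "od_pair")
}

#' Spline motion-artifact correction
#'
#' Motion artifacts are detected where the moving standard deviation (window
#' `detect_window`) exceeds `detect_threshold` times the trace's median
#' moving SD; detected samples are dilated by half a window and segments
#' closer than `merge_gap` are merged, so a baseline-shift artifact is
#' treated as one segment. Within each segment a smoothing spline is
#' subtracted and the segment re-leveled onto the line joining its
#' neighbors. Samples outside detected segments are returned unchanged.
#'
#' @param od a non-empty [trace()].
#' @param detect_window moving-SD window in seconds.
#' @param detect_threshold detection threshold in multiples of the median
#'   moving SD.
#' @param merge_gap segments closer than this (seconds) are merged.
#' @param spar smoothing parameter passed to [stats::smooth.spline()]; low
#'   values let the spline track the artifact shape closely.
#' @param max_passes detection/correction passes; the routine stops as soon
#'   as a pass detects nothing, so the operation is idempotent.
#' @return the corrected [trace()].
#' @export
motion_correct_spline <- function(od, detect_window = 1,
                                  detect_threshold = 3, merge_gap = 2,
                                  spar = 0.3, max_passes = 5) {
  stop_if_not_trace(od)
  out <- od
  for (pass in seq_len(max_passes)) {
    corrected <- motion_correct_once(out, detect_window, detect_threshold,
                                     merge_gap, spar)
    if (identical(corrected$values, out$values)) break
    out <- corrected
  }
  out
}

motion_correct_once <- function(od, detect_window, detect_threshold,
                                merge_gap, spar) {
  v <- od$values
  n <- length(v)
  if (!n) stop("trace is empty", call. = FALSE)
  fs <- od$sampling_rate
  w <- max(3L, as.integer(round(detect_window * fs)))
  if (n <= w) return(od)
  # centred moving SD via cumulative sums
  cs <- cumsum(c(0, v)); cs2 <- cumsum(c(0, v^2))
  half <- w %/% 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo
  mu <- (cs[hi + 1L] - cs[lo + 1L]) / cnt
  msd <- sqrt(pmax(0, (cs2[hi + 1L] - cs2[lo + 1L]) / cnt - mu^2))
  ref <- stats::median(msd)
  if (ref <= 0) return(od)
  flagged <- msd > detect_threshold * ref
  if (!any(flagged)) return(od)
  # dilate by half a window, then merge across short gaps
  idx <- which(flagged)
  marks <- logical(n)
  for (i in idx) marks[max(1, i - half):min(n, i + half)] <- TRUE
  r <- rle(marks)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gap_n <- as.integer(round(merge_gap * fs))
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg) > 1) {
    keep <- list(seg[1, ])
    for (i in 2:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg$start[i] - last$end <= gap_n)
        keep[[length(keep)]]$end <- seg$end[i]
      else keep[[length(keep) + 1]] <- seg[i, ]
    }
    seg <- do.call(rbind, keep)
  }
  out <- v
  for (i in seq_len(nrow(seg))) {
    a <- seg$start[i]; b <- seg$end[i]
    s <- a:b
    fit <- stats::smooth.spline(s, v[s], spar = spar)
    resid <- v[s] - stats::predict(fit, s)$y
    # the spline cannot follow a sharp discontinuity, so the residual keeps
    # spikes at artifact edges; normalize its spread to the trace's
    # reference noise level before re-leveling
    rs <- stats::sd(resid)
    if (is.finite(rs) && rs > ref) resid <- resid * (ref / rs)
    left <- if (a > 1) v[a - 1] else v[b + 1]
    right <- if (b < n) v[b + 1] else v[a - 1]
    level <- left + (right - left) * (s - a) / max(1, b - a)
    out[s] <- resid + level
  }
  trace(out, fs, od$label, od$units, od$start_time)
}

#' Band-pass filter for hemodynamic signals
#'
#' 3rd-order zero-phase Butterworth band-pass (applied forward and backward,
#' [signal::filtfilt()]); the default 0.01-0.2 Hz band removes the DC level,
#' slow drift, and cardiac/respiratory physiological noise while passing the
#' task-locked hemodynamic response.
#'
#' @param od a [trace()].
#' @param low,high band edges in Hz; `sampling_rate > 2 * high` required.
#' @return the filtered [trace()].
#' @export
fnirs_bandpass <- function(od, low = 0.01, high = 0.2) {
  stop_if_not_trace(od)
  stopifnot(low > 0, high > low)
  if (od$sampling_rate <= 2 * high)
    stop(sprintf("sampling rate %g Hz violates Nyquist for a %g Hz band edge",
                 od$sampling_rate, high), call. = FALSE)
  b <- signal::butter(3, c(low, high) / (od$sampling_rate / 2),
                      type = "pass")
  # demean first: the DC level is rejected exactly and the very long
  # high-pass edge transient is not excited by the baseline
  x <- od$values - mean(od$values)
  trace(as.numeric(signal::filtfilt(b, x)), od$sampling_rate,
        od$label, od$units, od$start_time)
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Solves, per sample, the 2x2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' for `(dHbO, dHbR)`, and reports `HbT = HbO + HbR`. Extinction
#' coefficients in 1/(mM*cm) and distance in cm yield concentration changes
#' in mmol/L, reported here in umol/L.
#'
#' @param od an [od_pair()].
#' @param geom a [channel_geometry()].
#' @return a list of class `"hemo_trace"` with `hbo`, `hbr`, `hbt`
#'   [trace()]s in umol/L.
#' @export
mbll <- function(od, geom = channel_geometry()) {
  stopifnot(inherits(od, "od_pair"), inherits(geom, "channel_geometry"))
  A <- geom$extinction * geom$distance * geom$dpf  # row-wise DPF scaling
  if (abs(det(A)) < 1e-12)
    stop("extinction matrix is singular", call. = FALSE)
  rhs <- rbind(od$od_lambda1$values, od$od_lambda2$values)
  conc <- solve(A, rhs) * 1000  # mM -> umol/L
  fs <- od$od_lambda1$sampling_rate
  t0 <- od$od_lambda1$start_time
  structure(list(
    hbo = trace(conc[1, ], fs, "HbO", "umol/L", t0),
    hbr = trace(conc[2, ], fs, "HbR", "umol/L", t0),
    hbt = trace(conc[1, ] + conc[2, ], fs, "HbT", "umol/L", t0)),
    class = "hemo_trace")
}

#' Forward modified Beer-Lambert model
#'
#' Maps known hemoglobin concentration changes (umol/L) to the
#' optical-density pair they would produce — the inverse of [mbll()], used
#' to synthesize test data and to validate the conversion by round trip.
#'
#' @param hbo,hbr [trace()]s in umol/L.
#' @param geom a [channel_geometry()].
#' @return an [od_pair()].
#' @export
mbll_forward <- function(hbo, hbr, geom = channel_geometry()) {
  stop_if_not_trace(hbo); stop_if_not_trace(hbr)
  A <- geom$extinction * geom$distance * geom$dpf
  od <- A %*% rbind(hbo$values, hbr$values) / 1000
  fs <- hbo$sampling_rate
  od_pair(trace(od[1, ], fs, "od1", "OD", hbo$start_time),
          trace(od[2, ], fs, "od2", "OD", hbo$start_time),
          geom$wavelengths)
}

#' Onset-aligned block average
#'
#' Averages `window`-second windows aligned at the task onsets, after
#' subtracting each window's value at its onset (baseline zero at t = 0).
#'
#' @param hemo a [trace()].
#' @param onsets an [event_list()] of task onsets.
#' @param window window length in seconds; every `onset + window` must lie
#'   within the trace.
#' @return a [trace()] of length `window * sampling_rate`, starting at 0.
#' @export
block_average <- function(hemo, onsets, window) {
  stop_if_not_trace(hemo)
  stopifnot(inherits(onsets, "event_list"), window > 0)
  if (!nrow(onsets)) stop("no onsets given", call. = FALSE)
  fs <- hemo$sampling_rate
  wn <- as.integer(round(window * fs))
  n <- length(hemo$values)
  i0s <- 1L + as.integer(round((onsets$onset - hemo$start_time) * fs))
  bad <- i0s < 1L | i0s + wn - 1L > n
  if (any(bad))
    stop("onset(s) out of range: ",
         paste(format(onsets$onset[bad]), collapse = ", "), call. = FALSE)
  acc <- numeric(wn)
  for (i0 in i0s) {
    seg <- hemo$values[i0:(i0 + wn - 1L)]
    acc <- acc + (seg - seg[1])
  }
  trace(acc / nrow(onsets), fs, paste0(hemo$label, ".block"), hemo$units,
        0)
}

#' Variance of a hemodynamic trace over the task window
#'
#' Unbiased variance of the first `task_window` seconds — the summary used
#' to compare cortical-activation variability between assisted and
#' unassisted walking.
#'
#' @param hemo a [trace()] spanning at least `task_window` seconds.
#' @param task_window window in seconds (default 45).
#' @return the variance, in the trace's units squared.
#' @export
task_variance <- function(hemo, task_window = 45) {
  stop_if_not_trace(hemo)
  wn <- as.integer(round(task_window * hemo$sampling_rate))
  if (length(hemo$values) < wn)
    stop(sprintf("trace spans %.3g s, shorter than the %g s task window",
                 trace_duration(hemo), task_window), call. = FALSE)
  stats::var(hemo$values[seq_len(wn)])
}

#' Synthesize a hemodynamic test channel
#'
#' Builds known ground-truth HbO/HbR concentration changes — a canonical
#' gamma-shaped task response repeated over equally spaced onsets, plus
#' cardiac and respiratory sinusoids and optional spike/shift artifacts —
#' and pushes them through the forward Beer-Lambert model. Returns both the
#' optical densities and the ground truth, for pipeline validation.
#'
#' @param n_blocks number of task repetitions.
#' @param block_period spacing of onsets in seconds.
#' @param amp_hbo peak HbO response in umol/L (HbR is -amp/3).
#' @param fs sampling rate, Hz.
#' @param cardiac_amp,resp_amp sinusoid amplitudes in umol/L.
#' @param artifact logical; inject motion artifacts into the optical
#'   densities.
#' @param geom a [channel_geometry()].
#' @param seed optional integer seed.
#' @return list with `od` (an [od_pair()]), `truth` (HbO/HbR traces),
#'   `onsets` (an [event_list()]), and `response` (one noiseless response
#'   window as a trace).
#' @export
simulate_hemodynamics <- function(n_blocks = 25, block_period = 40,
                                  amp_hbo = 1, fs = 10, cardiac_amp = 0.3,
                                  resp_amp = 0.2, artifact = FALSE,
                                  geom = channel_geometry(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- n_blocks * block_period + 30
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  onset_t <- 10 + block_period * (seq_len(n_blocks) - 1)
  # slow gamma-like response: peak ~1 at t = 8 s, width ~12 s
  hrf <- function(t) ifelse(t > 0, (t / 8)^3 * exp(3 - 3 * t / 8), 0)
  resp <- numeric(length(tt))
  for (o in onset_t) resp <- resp + hrf(tt - o)
  hbo <- amp_hbo * resp + cardiac_amp * sin(2 * pi * 1.0 * tt) +
    resp_amp * sin(2 * pi * 0.3 * tt)
  hbr <- -amp_hbo / 3 * resp + 0.5 * cardiac_amp * sin(2 * pi * 1.0 * tt +
                                                         1)
  hbo_tr <- trace(hbo, fs, "HbO.truth", "umol/L")
  hbr_tr <- trace(hbr, fs, "HbR.truth", "umol/L")
  od <- mbll_forward(hbo_tr, hbr_tr, geom)
  if (artifact) {
    n_art <- max(1L, n_blocks %/% 5L)
    at <- sort(sample(seq(20, dur - 20), n_art))
    for (a in at) {
      sel <- tt >= a & tt < a + 2
      od$od_lambda1$values[sel] <- od$od_lambda1$values[sel] + 0.05
      od$od_lambda2$values[sel] <- od$od_lambda2$values[sel] - 0.04
    }
  }
  wn <- as.integer(round(30 * fs))
  list(od = od, truth = list(hbo = hbo_tr, hbr = hbr_tr),
       onsets = event_list(onset_t, onset_t, rep("task", n_blocks)),
       response = trace(amp_hbo * hrf(seq(0, 30 - 1 / fs, by = 1 / fs)),
                        fs, "response", "umol/L"))
}
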