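# Shared internal helpers.

# Timestamped log line on standard error. Silenced with
# options(cifes.quiet = TRUE); tests keep it quiet via the testthat helper.
log_line <- function(fmt, ...) {
  if (isTRUE(getOption("cifes.quiet"))) return(invisible(NULL))
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), msg))
  invisible(NULL)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_trace <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "trace"))
    stop(arg, " must be a trace object", call. = FALSE)
  invisible(x)
}

# Zero-mean Gaussian noise band-limited to [low, high] Hz (4th-order
# Butterworth, forward filtering), rescaled back to unit variance.
band_noise <- function(n, fs, low = 20, high = 450) {
  if (n == 0) return(numeric(0))
  hi <- min(high, 0.95 * fs / 2)
  b <- signal::butter(4, c(low, hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(b, stats::rnorm(n + 200)))[-(1:200)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}
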