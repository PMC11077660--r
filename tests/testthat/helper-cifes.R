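options(cifes.quiet = TRUE)

# sine test signal as a trace
sine_trace <- function(freq, amp = 1, fs = 1000, dur = 2, offset = 0,
                       units = "V") {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  trace(offset + amp * sin(2 * pi * freq * tt), fs, "sine", units)
}

# steady-state level of a trace: mean of the final fraction
steady_level <- function(x, frac = 0.25) {
  n <- length(x$values)
  mean(x$values[floor(n * (1 - frac)):n])
}
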