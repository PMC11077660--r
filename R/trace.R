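#' Uniformly sampled labeled time series
#'
#' `trace()` is the universal signal carrier of the package: raw and enveloped
#' surface EMG in volts, ankle/IMU angles in degrees, stimulus waveforms in
#' volts, optical densities and hemoglobin concentration changes. A trace is a
#' plain list with a label, a start time, a strictly positive sampling rate,
#' a numeric value vector, and a unit string; sample `i` (1-based) sits at
#' `start_time + (i - 1) / sampling_rate` seconds.
#'
#' @param values numeric vector of samples (all finite).
#' @param sampling_rate sampling rate in Hz, strictly positive.
#' @param label short text label.
#' @param units unit string, e.g. `"V"`, `"deg"`, `"deg/s"`, `"OD"`, `"umol/L"`.
#' @param start_time time of the first sample in seconds.
#' @return an object of class `"trace"`.
#' @examples
#' tr <- trace(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), 1000, "demo", "V")
#' tr
#' @export
trace <- function(values, sampling_rate, label = "signal", units = "",
                  start_time = 0) {
  values <- as.numeric(values)
  if (length(values) && any(!is.finite(values)))
    stop("trace values must all be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single strictly positive number",
         call. = FALSE)
  structure(
    list(label = as.character(label)[1], start_time = as.numeric(start_time)[1],
         sampling_rate = sampling_rate, values = values,
         units = as.character(units)[1]),
    class = "trace")
}

#' @export
length.trace <- function(x) length(x$values)

#' Sample times of a trace
#' @param x a [trace()].
#' @return numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  if (!length(x$values)) return(numeric(0))
  x$start_time + (seq_along(x$values) - 1) / x$sampling_rate
}

#' Duration spanned by a trace in seconds
#' @param x a [trace()].
#' @export
trace_duration <- function(x) length(x$values) / x$sampling_rate

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s: %d samples @ %g Hz [%s], t0 = %g s\n",
              x$label, length(x$values), x$sampling_rate, x$units,
              x$start_time))
  if (length(x$values))
    cat(sprintf("  range [%.4g, %.4g], duration %.3f s\n",
                min(x$values), max(x$values), trace_duration(x)))
  invisible(x)
}

#' @export
plot.trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (s)",
                 ylab = sprintf("%s (%s)", x$label, x$units), ...)
  invisible(x)
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time = trace_times(x), value = x$values)
}

# Extract the samples with start_time + [from, to) as a sub-trace.
# Used internally for per-cycle segmentation; clamps to the trace extent.
window_trace <- function(x, from, to) {
  stopifnot(inherits(x, "trace"))
  i0 <- max(1L, 1L + as.integer(ceiling((from - x$start_time) *
                                          x$sampling_rate - 1e-9)))
  i1 <- min(length(x$values),
            as.integer(floor((to - x$start_time) * x$sampling_rate + 1e-9)))
  vals <- if (i1 >= i0) x$values[i0:i1] else numeric(0)
  trace(vals, x$sampling_rate, x$label, x$units,
        start_time = x$start_time + (i0 - 1) / x$sampling_rate)
}

#' Ordered list of tagged events
#'
#' Events carry ground-truth gait steps, switch activations and task blocks.
#' Each event is an `(onset, offset, tag)` triple with `onset <= offset`;
#' the list is kept sorted by onset.
#'
#' @param onset,offset numeric vectors of times in seconds.
#' @param tag character vector of tags (recycled).
#' @return a data frame of class `"event_list"`.
#' @export
event_list <- function(onset = numeric(0), offset = onset,
                       tag = character(length(onset))) {
  onset <- as.numeric(onset); offset <- as.numeric(offset)
  if (length(onset) != length(offset))
    stop("onset and offset must have equal length", call. = FALSE)
  if (any(offset < onset))
    stop("every event must have onset <= offset", call. = FALSE)
  tag <- rep_len(as.character(tag), length(onset))
  ord <- order(onset)
  structure(data.frame(onset = onset[ord], offset = offset[ord],
                       tag = tag[ord], stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

#' Read a trace from its CSV representation
#'
#' The on-disk dialect is UTF-8 comma-separated text: leading `# key=value`
#' comment lines carrying the metadata (`label`, `sampling_rate`, `units`,
#' and optionally `start_time`), then a single `value` column of samples.
#' The format round-trips with [write_trace_csv()] at full double precision.
#'
#' @param path path to a trace CSV file.
#' @return a [trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_i <- grep("^#", lines)
  meta_i <- meta_i[meta_i == seq_along(meta_i)]  # leading block only
  meta <- list()
  for (ln in lines[meta_i]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0)
      stop("malformed metadata line in ", path, ": ", ln, call. = FALSE)
    meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1,
                                                           nchar(kv)))
  }
  for (field in c("label", "sampling_rate", "units"))
    if (is.null(meta[[field]]))
      stop("trace CSV header of ", path, " lacks required field '", field,
           "'", call. = FALSE)
  fs <- suppressWarnings(as.numeric(meta$sampling_rate))
  if (is.na(fs))
    stop("field 'sampling_rate' is not numeric in ", path, call. = FALSE)
  t0 <- if (is.null(meta$start_time)) 0 else
    suppressWarnings(as.numeric(meta$start_time))
  if (is.na(t0))
    stop("field 'start_time' is not numeric in ", path, call. = FALSE)
  body <- lines[-seq_len(length(meta_i))]
  body <- body[nzchar(trimws(body))]
  if (!length(body) || trimws(body[1]) != "value")
    stop("trace CSV ", path, " lacks the 'value' column header",
         call. = FALSE)
  raw <- body[-1]
  vals <- suppressWarnings(as.numeric(raw))
  if (length(vals) && anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric sample '%s' at data row %d of %s",
                 raw[bad], bad, path), call. = FALSE)
  }
  trace(vals, fs, meta$label, meta$units, start_time = t0)
}

#' Write a trace to CSV
#'
#' @param x a [trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_trace_csv()] for the dialect.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", x$label),
               sprintf("# start_time=%s", formatC(x$start_time, format = "g",
                                                  digits = 17)),
               sprintf("# sampling_rate=%s",
                       formatC(x$sampling_rate, format = "g", digits = 17)),
               sprintf("# units=%s", x$units),
               "value"), con)
  if (length(x$values))
    writeLines(formatC(x$values, format = "g", digits = 17), con)
  invisible(path)
}

#' Read / write an event list as CSV
#'
#' Plain `onset,offset,tag` CSV with a header row.
#' @param path file path.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset", "offset", "tag")
  if (!all(need %in% names(df)))
    stop("event CSV ", path, " must have columns onset, offset, tag",
         call. = FALSE)
  event_list(df$onset, df$offset, df$tag)
}

#' @rdname read_events_csv
#' @param x an [event_list()].
#' @export
write_events_csv <- function(x, path) {
  stopifnot(inherits(x, "event_list"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
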