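#' Package-wide run configuration
#'
#' A run configuration is a nested named list: a top-level `seed` plus one
#' section per module. [default_config()] returns every documented default;
#' [load_config()] layers a YAML file and programmatic overrides on top,
#' rejecting unknown keys so typos fail loudly.
#'
#' @return a nested named list of class `"cifes_config"`.
#' @export
default_config <- function() {
  structure(list(
    seed = 0L,
    virtual_patient = list(
      sampling_rate = 1000,       # Hz, shared by all generated traces
      fatigue_tau   = 300,        # s, first-order fatigue recovery constant
      fatigue_k     = 0.00100918, # 1/load, response decay per unit load
      crosstalk     = FALSE,      # stimulation artifact into sEMG electrodes
      crosstalk_amp = 0.5,        # V at zero distance
      crosstalk_decay = 2.5       # cm, exponential decay length
    ),
    emg_chain = list(
      lowpass_cutoff    = 10,     # Hz
      integrate_window  = 0.05,   # s
      moving_avg_window = 0.10,   # s
      gain              = 1,
      clamp             = 3.3     # V, ADC saturation; NA disables
    ),
    gait_switch = list(
      threshold  = 0.15,          # V (sEMG envelope)
      direction  = "above",
      countdown  = 0.8,           # s
      refractory = 0.3,           # s
      tolerance  = 0.3            # s, accuracy matching window
    ),
    stim_waveform = list(
      pulse_freq       = 33,      # Hz
      anodic_width     = 200e-6,  # s
      width_ratio      = 2,       # cathodic:anodic width
      carrier_freq     = 16.67e3, # Hz
      carrier_duty     = 0.833,
      count_min        = 20,
      count_max        = 140,
      v_at_count_min   = 138,     # V
      v_at_count_max   = 255,     # V
      v_cap            = 240,     # V
      n_channels       = 1,
      carrier          = FALSE,   # render the intensity carrier
      equal_amplitude  = FALSE    # charge-imbalanced +-V rendering
    ),
    closed_loop = list(
      t1          = 0.15,         # V, healthy-side record threshold
      t2          = 0.15,         # V, affected-side trigger threshold
      template_len = 100,
      gain_init   = 0.5,
      gain_eta    = 0.02,
      gain_bounds = c(0.05, 2),
      maxaa_target = 100.72,      # deg, healthy reference mean
      deadband    = 2,            # deg, hold gain inside +-deadband
      maxaa_window = 10,          # cycles averaged for feedback
      stim_window = 0.8           # s, stimulation burst = switch countdown
    ),
    kinematics = list(
      prominence     = 3,         # deg
      min_separation = 0.5,       # s between retained peaks
      bin_width      = 5          # deg, histogram interval
    ),
    rehab_ml = list(
      folds = 10,
      cost  = 1
    ),
    fnirs = list(
      low  = 0.01,                # Hz
      high = 0.2,                 # Hz
      detect_window    = 1,       # s, moving-SD window
      detect_threshold = 3,       # multiples of median moving SD
      merge_gap        = 2,       # s, join artifact segments closer than this
      spline_spar      = 0.6,
      task_window      = 45,      # s
      distance         = 3,       # cm source-detector
      wavelengths      = c(760, 850),
      dpf              = c(6, 6)
    )
  ), class = "cifes_config")
}

# Recursive merge of `new` into `base`; unknown keys are configuration errors.
merge_config <- function(base, new, path = character(0)) {
  for (key in names(new)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key '%s'; valid keys here: %s",
                   full, paste(names(base), collapse = ", ")),
           call. = FALSE)
    if (is.list(base[[key]]) && !is.list(new[[key]]))
      stop(sprintf("configuration key '%s' must be a section", full),
           call. = FALSE)
    if (is.list(base[[key]]))
      base[[key]] <- merge_config(base[[key]], new[[key]], c(path, key))
    else
      base[[key]] <- new[[key]]
  }
  base
}

# Expand list(a.b = 1) into list(a = list(b = 1)).
expand_dotted <- function(overrides) {
  out <- list()
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- overrides[[key]]
    for (p in rev(parts)) node <- stats::setNames(list(node), p)
    out <- utils::modifyList(out, node)
  }
  out
}

#' Load a run configuration
#'
#' Reads a YAML configuration file (any subset of the keys in
#' [default_config()]), fills remaining defaults, then applies programmatic
#' `overrides` (which win over file values). Unknown keys at any level raise
#' a configuration error listing the valid keys. The effective configuration
#' is echoed to the log.
#'
#' @param path path to a YAML file, or `NULL` for defaults only.
#' @param overrides named list; names may be dotted paths such as
#'   `"gait_switch.threshold"`.
#' @return a `"cifes_config"` list.
#' @examples
#' cfg <- load_config(overrides = list("closed_loop.gain_eta" = 0.01))
#' cfg$closed_loop$gain_eta
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    from_file <- yaml::read_yaml(path)
    if (is.null(from_file)) from_file <- list()
    cfg <- merge_config(cfg, from_file)
  }
  if (length(overrides))
    cfg <- merge_config(cfg, expand_dotted(overrides))
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed) || cfg$seed < 0)
    stop("seed must be a non-negative integer", call. = FALSE)
  class(cfg) <- "cifes_config"
  log_line("configuration: %s",
           jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))
  cfg
}

#' @export
print.cifes_config <- function(x, ...) {
  cat("<cifes_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
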