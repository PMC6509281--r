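#' Analysis configuration with pipeline defaults
#'
#' Every numeric parameter used by the pipeline stages, collected in one
#' serializable list. Defaults are the values used throughout the package:
#' working rate 1 kHz, delta evidence bands \[0,1\] and \[1,2\] Hz with
#' preferred phase 180 deg, beta/low-gamma band \[10,51\] Hz with 5-ms running
#' RMS and 50-ms smoothing, up/down thresholds at mu +/- 2 sigma of the
#' extreme mixture components, 100-ms minimum state duration and 50-ms
#' minimum inter-state gap, juxtasomal threshold 6 x SD above a 300-Hz
#' high-pass, PTSD band \[300,3000\] Hz with 3-ms peak lifetime, 8.5 x SD
#' differential threshold and 1-ms refractory period, 12.5-ms IFR kernel with
#' 100-ms pre/post windows and 100 surrogates, and derivative thresholds
#' mu - 4 sigma (evoked) / mu - 2 sigma (spontaneous).
#'
#' @param ... Named overrides of any default (nested lists are replaced
#'   field-by-field).
#' @return A nested list of class `analysis_config`.
#' @examples
#' cfg <- analysis_config(sta = list(n_surrogates = 50))
#' cfg$sta$n_surrogates
#' @export
analysis_config <- function(...) {
  cfg <- list(
    working_rate = 1000,
    lowpass_hz = 500,
    sync = list(trial_len = 5, low_band = c(0.1, 4), high_band = c(4, 100),
                threshold = 4),
    delta = list(bands = list(c(0, 1), c(1, 2)), preferred_phase_deg = 180,
                 method = "analytic", sharpness = 8, crossing_offset = 0.2),
    phase_band = c(0.1, 4),
    betagamma = list(band = c(10, 51), rms_frame = 0.005, smooth_frame = 0.05,
                     norm_percentile = 0.95),
    gmm = list(n_restarts = 10, max_iter = 500, tol = 1e-8, seed = 1,
               exclude_percentile = 0.95),
    segment = list(min_dur = 0.1, min_gap = 0.05),
    juxta = list(highpass_hz = 300, threshold_mult = 6,
                 sd_estimator = "robust_mad"),
    ptsd = list(band = c(300, 3000), peak_lifetime = 0.003,
                threshold_mult = 8.5, refractory = 0.001,
                sd_estimator = "robust_mad"),
    filter = list(order = 4, ripple_db = 0.1, stop_db = 40),
    phaselock = list(n_bins = 18, rayleigh_alpha = 0.01,
                     up_range_deg = c(95, 255), down_range_deg = c(295, 75)),
    sta = list(kernel_sd = 0.0125, window = 0.1, curve_window = 0.5,
               n_surrogates = 100, seed = 1),
    opto = list(artifact_window = 0.06, artifact_smooth = 0.014,
                rms_frame = 0.01, k_evoked = 4, k_spont = 2,
                spont_pre_gap = 0.05, spont_post_gap = 0.55,
                surrogate_period = 0.5, trial_len = 5,
                down_threshold = "median"),
    whisker = list(window = 0.1)
  )
  overrides <- list(...)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("analysis_config: overrides must be named")
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("analysis_config: unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    cfg <- merge_into(cfg, overrides)
  }
  structure(cfg, class = "analysis_config")
}

#' Write / read an analysis configuration as JSON
#'
#' Round-trips exactly: `read_config(write_config(cfg, path))` equals `cfg`.
#'
#' @param cfg An `analysis_config`.
#' @param path File path for the JSON document.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  # lists of band pairs come back as lists of vectors; scalars as scalars
  do.call(analysis_config, raw)
}
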