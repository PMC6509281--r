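#' Uniformly sampled voltage trace
#'
#' Container for LFP, juxtasomal or multi-unit (MUA) voltage signals. Sample
#' `i` (1-based) covers the half-open time bin
#' `[t0 + (i-1)/rate, t0 + i/rate)`; its nominal time is `t0 + (i-1)/rate`.
#'
#' @param samples Numeric vector of voltage samples (volts or normalized
#'   units). Must be finite and non-empty.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param channel Free-text channel label (e.g. "LFP", "juxta", "MUA").
#' @return An object of class `time_series`.
#' @examples
#' ts <- time_series(sin(2 * pi * seq(0, 1, by = 1e-3)), rate = 1000)
#' ts_duration(ts)
#' @export
time_series <- function(samples, rate, t0 = 0, channel = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("time_series: need at least one sample")
  if (!all(is.finite(samples))) stop("time_series: all samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("time_series: rate must be a single positive number")
  structure(
    list(samples = samples, rate = as.numeric(rate), t0 = as.numeric(t0),
         channel = as.character(channel)),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d samples @ %g Hz, t0 = %g s (%.3f s)\n",
              if (nzchar(x$channel)) x$channel else "unlabeled",
              length(x$samples), x$rate, x$t0, ts_duration(x)))
  invisible(x)
}

#' Sample times and duration of a time series
#'
#' @param ts A `time_series`.
#' @return `ts_times()`: numeric vector of the nominal sample times (s);
#'   `ts_duration()`: total covered duration `length/rate` (s).
#' @export
ts_times <- function(ts) ts$t0 + (seq_along(ts$samples) - 1) / ts$rate

#' @rdname ts_times
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$rate

#' Spike train with source label
#'
#' @param times Spike times in seconds, strictly increasing, in
#'   `[0, duration)`.
#' @param source One of `"PV"`, `"VPM"`, `"OTHER"`.
#' @param duration Recording duration in seconds.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, source = c("PV", "VPM", "OTHER"), duration) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike_train: times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration))
    stop("spike_train: times must lie in [0, duration)")
  structure(list(times = times, source = source, duration = as.numeric(duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over %.1f s (%.2f spikes/s)\n",
              x$source, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

STATE_LEVELS <- c("UP", "DOWN", "INDET")

#' State segmentation of a recording
#'
#' An ordered set of non-overlapping half-open intervals `[start, end)`
#' labeled `UP`, `DOWN` or `INDET` (indeterminate) that jointly tile the
#' recording.
#'
#' @param start,end Interval bounds in seconds (`start < end`).
#' @param label Character vector of labels (`UP`/`DOWN`/`INDET`).
#' @param rate Working sampling rate (Hz) at which the segmentation was
#'   computed.
#' @return An object of class `state_segmentation`: a data.frame with columns
#'   `start`, `end`, `label` plus a `rate` attribute.
#' @export
state_segmentation <- function(start, end, label, rate = 1000) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$label %in% STATE_LEVELS))
      stop("state_segmentation: labels must be UP, DOWN or INDET")
    if (any(df$start >= df$end))
      stop("state_segmentation: every interval needs start < end")
    o <- order(df$start)
    df <- df[o, , drop = FALSE]
    if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)] - 1e-12))
      stop("state_segmentation: intervals overlap")
    rownames(df) <- NULL
  }
  attr(df, "rate") <- rate
  class(df) <- c("state_segmentation", "data.frame")
  df
}

#' @export
print.state_segmentation <- function(x, ...) {
  tab <- table(factor(x$label, STATE_LEVELS))
  cat(sprintf("<state_segmentation> %d intervals over [%.3f, %.3f) s (UP %d, DOWN %d, INDET %d)\n",
              nrow(x), if (nrow(x)) min(x$start) else NA,
              if (nrow(x)) max(x$end) else NA,
              tab["UP"], tab["DOWN"], tab["INDET"]))
  invisible(x)
}

#' Total time covered by each state label
#'
#' @param seg A `state_segmentation`.
#' @return Named numeric vector of seconds per label (UP, DOWN, INDET).
#' @export
segmentation_time_by_label <- function(seg) {
  dur <- seg$end - seg$start
  vapply(STATE_LEVELS, function(l) sum(dur[seg$label == l]), numeric(1))
}

#' Look up the state label at given times
#'
#' @param seg A `state_segmentation`.
#' @param t Times in seconds.
#' @return Character vector of labels (`NA` outside the segmentation).
#' @export
state_at <- function(seg, t) {
  idx <- findInterval(t, seg$start)
  lab <- rep(NA_character_, length(t))
  ok <- idx >= 1
  ok[ok] <- t[ok] < seg$end[idx[ok]]
  lab[ok] <- seg$label[idx[ok]]
  lab
}

#' Index of the interval containing each time
#'
#' @inheritParams state_at
#' @return Integer vector of row indices into `seg` (`NA` if uncovered).
#' @export
interval_at <- function(seg, t) {
  idx <- findInterval(t, seg$start)
  idx[idx < 1] <- NA_integer_
  inside <- !is.na(idx) & t < seg$end[pmax(idx, 1L)]
  idx[!inside] <- NA_integer_
  idx
}

#' Optogenetic stimulation protocol
#'
#' @param onsets Illumination onset times (s), sorted.
#' @param duration Illumination epoch duration (s); 0.5 s by default,
#'   matching a 500-ms stimulus.
#' @param wavelength_nm Light wavelength metadata (594 nm default).
#' @return An object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(onsets, duration = 0.5, wavelength_nm = 594) {
  onsets <- sort(as.numeric(onsets))
  if (length(onsets) > 1 && any(diff(onsets) < duration))
    stop("stimulation_protocol: illumination epochs overlap")
  structure(list(onsets = onsets, duration = as.numeric(duration),
                 wavelength_nm = wavelength_nm),
            class = "stimulation_protocol")
}
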