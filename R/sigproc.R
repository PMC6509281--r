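#' Zero-phase elliptic filtering
#'
#' Designs an elliptic (Cauer) IIR filter and applies it forward-backward
#' (`signal::filtfilt`), so the output is zero-phase and spike/transition
#' timing is preserved. Defaults: order 4, 0.1 dB passband ripple, 40 dB
#' stopband attenuation.
#'
#' @param ts A [time_series()].
#' @param kind `"low"`, `"high"` or `"band"`.
#' @param edges Cutoff (Hz) for low/high, or `c(lo, hi)` for band.
#' @param order,ripple_db,stop_db Filter design parameters.
#' @return Filtered [time_series()] of the same length.
#' @export
elliptic_filter <- function(ts, kind = c("low", "high", "band"), edges,
                            order = 4, ripple_db = 0.1, stop_db = 40) {
  kind <- match.arg(kind)
  stopifnot(inherits(ts, "time_series"))
  nyq <- ts$rate / 2
  if (any(edges >= nyq))
    stop(sprintf("elliptic_filter: edge %g Hz >= Nyquist %g Hz",
                 max(edges), nyq))
  if (any(edges <= 0)) stop("elliptic_filter: edges must be positive")
  type <- switch(kind, low = "low", high = "high", band = "pass")
  if (kind == "band" && length(edges) != 2)
    stop("elliptic_filter: band filtering needs c(lo, hi)")
  flt <- signal::ellip(order, ripple_db, stop_db, edges / nyq, type = type)
  out <- signal::filtfilt(flt, ts$samples)
  time_series(out, ts$rate, ts$t0, ts$channel)
}

#' Frequency-domain band filtering with raised-cosine edges
#'
#' Zero-phase band filter implemented by masking the FFT, used for narrow
#' low-frequency bands (delta) where IIR designs are numerically unstable at
#' typical working rates. Gain is 1 inside `[lo, hi]`, rolling off to 0 over
#' a half-cosine transition on each edge. `lo = 0` gives a pure low-pass.
#'
#' @param ts A [time_series()].
#' @param band `c(lo, hi)` in Hz.
#' @param transition Transition width (Hz); default a quarter of the band
#'   width, capped at 0.5 Hz.
#' @return Filtered [time_series()].
#' @export
fft_bandpass <- function(ts, band, transition = NULL) {
  stopifnot(inherits(ts, "time_series"), length(band) == 2, band[1] < band[2])
  n <- length(ts$samples)
  if (is.null(transition)) transition <- min(0.5, 0.25 * diff(band))
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * ts$rate / n
  af <- abs(f)
  g <- numeric(n)
  g[af >= max(band[1], 0) & af <= band[2]] <- 1
  if (band[1] > 0) {
    lo_t <- af >= band[1] - transition & af < band[1]
    g[lo_t] <- 0.5 * (1 + cos(pi * (band[1] - af[lo_t]) / transition))
  }
  hi_t <- af > band[2] & af <= band[2] + transition
  g[hi_t] <- 0.5 * (1 + cos(pi * (af[hi_t] - band[2]) / transition))
  out <- Re(stats::fft(stats::fft(ts$samples) * g, inverse = TRUE)) / n
  time_series(out, ts$rate, ts$t0, ts$channel)
}

#' Integer-factor downsampling with anti-alias filtering
#'
#' Low-pass filters at 0.45 x target rate (elliptic, zero-phase) and keeps
#' every k-th sample. The target rate must divide the source rate.
#'
#' @param ts A [time_series()].
#' @param target_rate Target sampling rate (Hz).
#' @return Decimated [time_series()]; `t0` preserved.
#' @export
downsample <- function(ts, target_rate) {
  stopifnot(inherits(ts, "time_series"))
  ratio <- ts$rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("downsample: %g Hz is not an integer divisor of %g Hz",
                 target_rate, ts$rate))
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(ts)
  filt <- elliptic_filter(ts, "low", 0.45 * target_rate)
  time_series(filt$samples[seq(1, length(filt$samples), by = ratio)],
              target_rate, ts$t0, ts$channel)
}

#' Welch power spectral density
#'
#' Hann-windowed segments with 50% overlap; one-sided periodogram average.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate (Hz).
#' @param seg_len Segment length in seconds (default 2 s, resolving 0.5 Hz).
#' @return List with `freq` (Hz) and `power` (arbitrary density units).
#' @export
welch_psd <- function(x, rate, seg_len = 2) {
  nseg <- round(seg_len * rate)
  if (length(x) < nseg) stop("welch_psd: signal shorter than one segment")
  step <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(length(acc))]
  }
  acc <- acc / (length(starts) * sum(w^2) * rate)
  acc[-1] <- 2 * acc[-1]
  list(freq = (seq_along(acc) - 1) * rate / nseg, power = acc)
}

#' Synchronization index per 5-s trial
#'
#' Ratio of LFP power in the low-frequency band (0.1, 4\] Hz over the
#' high-frequency band (4, 100\] Hz, computed per consecutive trial with a
#' Welch estimator. Trials with index > 4 are flagged as synchronized slow
#' oscillation epochs suitable for up/down-state analysis.
#'
#' @param ts LFP [time_series()].
#' @param trial_len Trial length in seconds (default 5).
#' @param low_band,high_band Band edges in Hz.
#' @param threshold Selection threshold on the index (default 4).
#' @return data.frame with `trial`, `start_s`, `index`, `synchronized`.
#' @export
synchronization_index <- function(ts, trial_len = 5,
                                  low_band = c(0.1, 4),
                                  high_band = c(4, 100),
                                  threshold = 4) {
  stopifnot(inherits(ts, "time_series"))
  npt <- round(trial_len * ts$rate)
  n_trials <- length(ts$samples) %/% npt
  if (n_trials < 1) {
    warning("synchronization_index: recording shorter than one trial; skipped")
    return(data.frame(trial = integer(), start_s = numeric(),
                      index = numeric(), synchronized = logical()))
  }
  res <- lapply(seq_len(n_trials), function(i) {
    seg <- ts$samples[((i - 1) * npt + 1):(i * npt)]
    psd <- welch_psd(seg, ts$rate, seg_len = min(2, trial_len / 2))
    f <- psd$freq
    lo <- sum(psd$power[f > low_band[1] & f <= low_band[2]])
    hi <- sum(psd$power[f > high_band[1] & f <= high_band[2]])
    data.frame(trial = i, start_s = ts$t0 + (i - 1) * trial_len,
               index = lo / hi)
  })
  out <- do.call(rbind, res)
  out$synchronized <- out$index > threshold
  out
}

#' Instantaneous phase of a band-filtered trace
#'
#' Band-filters the signal (frequency-domain filter, see [fft_bandpass()])
#' and takes the angle of its analytic signal. Phase 0 falls at
#' depth-positive peaks of the filtered trace; with the depth-recording
#' convention used throughout (down states depth-positive), up states
#' cluster near 180 degrees.
#'
#' @param ts A [time_series()] (at least a few cycles long; edge effects are
#'   not trimmed).
#' @param band `c(lo, hi)` in Hz; default the slow-oscillation band
#'   \[0.1, 4\] Hz.
#' @return A `phase_trace`: list with `phase` (radians in \[-pi, pi)),
#'   `rate`, `t0`, `band`.
#' @export
analytic_signal <- function(ts, band) {
  xf <- fft_bandpass(ts, band)$samples
  n <- length(xf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(xf) * h, inverse = TRUE) / n
}

hilbert_phase <- function(ts, band = c(0.1, 4)) {
  stopifnot(inherits(ts, "time_series"))
  if (all(ts$samples == 0)) stop("hilbert_phase: all-zero trace")
  ph <- Arg(analytic_signal(ts, band))
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi
  structure(list(phase = ph, rate = ts$rate, t0 = ts$t0, band = band),
            class = "phase_trace")
}

#' @export
print.phase_trace <- function(x, ...) {
  cat(sprintf("<phase_trace> %d samples @ %g Hz, band [%g, %g] Hz\n",
              length(x$phase), x$rate, x$band[1], x$band[2]))
  invisible(x)
}

#' Phase of a trace at given times
#'
#' @param pt A `phase_trace`.
#' @param t Times (s).
#' @return Phases in radians at the nearest sample.
#' @export
phase_at <- function(pt, t) {
  idx <- pmin(pmax(round((t - pt$t0) * pt$rate) + 1, 1), length(pt$phase))
  pt$phase[idx]
}

# centered moving sum with truncated edges; k must be odd
moving_sum_trunc <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half - 1L, 0L)
  list(sum = cs[hi + 1L] - cs[lo + 1L], count = hi - lo)
}

frame_to_odd_samples <- function(frame, rate) {
  k <- 2L * as.integer(round(frame * rate / 2)) + 1L
  max(k, 1L)
}

#' Centered running RMS
#'
#' Root mean square of the signal in a centered sliding frame; frames are
#' truncated at the trace edges.
#'
#' @param ts A [time_series()].
#' @param frame Frame length in seconds (default 5 ms).
#' @return [time_series()] of running RMS values.
#' @export
running_rms <- function(ts, frame = 0.005) {
  stopifnot(inherits(ts, "time_series"))
  k <- frame_to_odd_samples(frame, ts$rate)
  if (k < 2 && round(frame * ts$rate) >= 2) k <- 3L
  ms <- moving_sum_trunc(ts$samples^2, k)
  time_series(sqrt(ms$sum / ms$count), ts$rate, ts$t0, ts$channel)
}

#' Centered moving average (boxcar)
#'
#' @param ts A [time_series()].
#' @param frame Frame length in seconds.
#' @return Smoothed [time_series()]; constants are preserved and edges use
#'   truncated frames.
#' @export
moving_average <- function(ts, frame) {
  stopifnot(inherits(ts, "time_series"))
  k <- frame_to_odd_samples(frame, ts$rate)
  ms <- moving_sum_trunc(ts$samples, k)
  time_series(ms$sum / ms$count, ts$rate, ts$t0, ts$channel)
}

#' Gaussian-kernel instantaneous firing rate (IFR)
#'
#' Convolves a spike train with a unit-area Gaussian kernel evaluated on the
#' sample grid. The integral of the returned trace equals the spike count up
#' to edge truncation (kernel support +/- 6 SD).
#'
#' @param spikes A [spike_train()].
#' @param kernel_sd Kernel standard deviation in seconds (e.g. 0.0125 for a
#'   12.5-ms kernel, roughly 20-Hz low-pass smoothing).
#' @param rate Output sampling rate (Hz).
#' @param duration Trace duration (s); defaults to the train's duration.
#' @return A `rate_trace` (also a [time_series()]) in spikes/s, with
#'   attributes `kernel_sd` and `source`.
#' @export
kernel_ifr <- function(spikes, kernel_sd, rate, duration = NULL) {
  stopifnot(inherits(spikes, "spike_train"), kernel_sd > 0)
  if (is.null(duration)) duration <- spikes$duration
  n <- as.integer(round(duration * rate))
  counts <- numeric(n)
  if (length(spikes$times)) {
    idx <- pmin(pmax(as.integer(floor(spikes$times * rate)) + 1L, 1L), n)
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  half <- as.integer(ceiling(6 * kernel_sd * rate))
  kk <- stats::dnorm(seq(-half, half) / rate, sd = kernel_sd)
  kk <- kk * rate / sum(kk)  # discrete unit area: sum(kk)/rate == 1
  padded <- c(numeric(half), counts, numeric(half))
  conv <- stats::convolve(padded, rev(kk), type = "open")
  out <- conv[(2 * half + 1):(2 * half + n)]
  out[out < 0] <- 0  # FFT round-off
  ts <- time_series(out, rate, 0, paste0("IFR:", spikes$source))
  attr(ts, "kernel_sd") <- kernel_sd
  attr(ts, "source") <- spikes$source
  class(ts) <- c("rate_trace", class(ts))
  ts
}

# robust (or plain) noise SD estimate used by spike detectors
noise_sd <- function(x, estimator = c("robust_mad", "raw_sd")) {
  estimator <- match.arg(estimator)
  if (estimator == "robust_mad") stats::median(abs(x)) / 0.6745 else stats::sd(x)
}
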