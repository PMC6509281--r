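#' Correct the light artifact around stimulation onsets
#'
#' Illumination onset produces a brief (~4 ms) polarization of the LFP. The
#' correction subtracts, inside a 60-ms window centered on each onset, the
#' across-trial mean of the artifact-only trials (trials without a
#' transition-like derivative crossing within 30 ms of the onset) and then
#' smooths that window with a 14-ms moving average. Samples outside the
#' window are untouched.
#'
#' @param lfp Session LFP [time_series()].
#' @param onsets Illumination onset times (s).
#' @param window Correction window (s, default 0.06, centered).
#' @param smooth Moving-average frame (s, default 0.014).
#' @param k Derivative-threshold multiplier used to classify a trial as
#'   containing a fast evoked transition near the onset (default 4).
#' @return List with `lfp` (corrected trace) and `artifact_trials` (indices
#'   of the trials used for the template). With fewer than 2 artifact-only
#'   trials the correction is skipped with a warning and the input returned.
#' @export
correct_light_artifact <- function(lfp, onsets, window = 0.06,
                                   smooth = 0.014, k = 4) {
  stopifnot(inherits(lfp, "time_series"))
  rate <- lfp$rate
  half <- as.integer(round(window / 2 * rate))
  n <- length(lfp$samples)
  ctr <- as.integer(round((onsets - lfp$t0) * rate)) + 1L
  ok <- ctr - half >= 1L & ctr + half <= n
  ctr <- ctr[ok]
  sm <- moving_average(lfp, smooth)$samples
  d <- c(0, diff(sm)) * rate
  # artifact-only trials: no fast negative derivative crossing near the
  # onset, judged beyond the artifact's own smoothed span (the ~4-ms pulse
  # spreads over ~18 ms after the moving-average smoothing)
  art_skip <- as.integer(round(0.02 * rate))
  is_artifact_only <- vapply(ctr, function(c0) {
    seg <- d[(c0 + art_skip):(c0 + half)]
    base <- d[max(1L, c0 - as.integer(rate)):(c0 - half)]
    thr <- mean(base) - k * stats::sd(base)
    !any(seg < thr)
  }, logical(1))
  if (sum(is_artifact_only) < 2) {
    warning("correct_light_artifact: fewer than 2 artifact-only trials; correction skipped")
    return(list(lfp = lfp, artifact_trials = integer(0)))
  }
  sel <- ctr[is_artifact_only]
  segs <- vapply(sel, function(c0) lfp$samples[(c0 - half):(c0 + half)],
                 numeric(2L * half + 1L))
  template <- rowMeans(segs)
  template <- template - mean(template[1:max(1L, half %/% 3)])  # baseline
  x <- lfp$samples
  ks <- frame_to_odd_samples(smooth, rate)
  for (c0 in ctr) {
    idx <- (c0 - half):(c0 + half)
    x[idx] <- x[idx] - template
    ms <- moving_sum_trunc(x[idx], ks)
    x[idx] <- ms$sum / ms$count
  }
  list(lfp = time_series(x, rate, lfp$t0, lfp$channel),
       artifact_trials = which(is_artifact_only))
}

# FWHM of the first peak of a density estimate
first_peak_fwhm_threshold <- function(x) {
  d <- stats::density(x, n = 512)
  ex <- local_extrema(d$y)
  pk <- if (length(ex$max)) min(ex$max) else which.max(d$y)
  hm <- d$y[pk] / 2
  right <- which(d$y[pk:length(d$y)] <= hm)
  if (!length(right)) return(stats::median(x))
  d$x[pk + right[1] - 1L]
}

#' Putative down-state mask from the beta/gamma evidence
#'
#' Simplified down-state gating for the latency analysis: time samples
#' whose beta/low-gamma evidence lies below a threshold are putative down
#' states. Threshold options: the overall median of the evidence (default),
#' the full width at half maximum of the first peak of its distribution, or
#' mu + sigma of the lower component of a two-Gaussian mixture fit. The
#' same threshold computed under control conditions can be reused on a
#' later (e.g. post-muscimol) recording by passing it via `threshold`.
#'
#' @param s_betagamma Numeric evidence vector (see [betagamma_evidence()];
#'   the latency pipeline computes it with a 10-ms RMS frame).
#' @param rate Working rate (Hz).
#' @param method `"median"`, `"fwhm"` or `"gmm2"`.
#' @param threshold Explicit threshold overriding `method`.
#' @param t0 Trace start time (s).
#' @param min_dur Minimum putative-down interval duration (s, default 0.1,
#'   the pipeline's minimum state duration); shorter below-threshold dips
#'   are discarded.
#' @return List with `mask` (logical per sample), `intervals` (data.frame
#'   `start`, `end` of putative down periods), `threshold`.
#' @export
putative_down_mask <- function(s_betagamma, rate = 1000,
                               method = c("median", "fwhm", "gmm2"),
                               threshold = NULL, t0 = 0, min_dur = 0.1) {
  method <- match.arg(method)
  if (stats::sd(s_betagamma) < 1e-12)
    stop("putative_down_mask: constant evidence signal")
  if (is.null(threshold)) {
    threshold <- switch(method,
      median = stats::median(s_betagamma),
      fwhm = first_peak_fwhm_threshold(s_betagamma),
      gmm2 = {
        q <- stats::quantile(s_betagamma, c(0.25, 0.75), names = FALSE)
        fit <- em_weighted(s_betagamma[seq(1, length(s_betagamma),
                                           length.out = min(20000, length(s_betagamma)))],
                           w = rep(1, min(20000, length(s_betagamma))),
                           mu = q, sigma = rep(stats::sd(s_betagamma) / 2, 2),
                           lambda = c(0.5, 0.5), max_iter = 300, tol = 1e-8)
        o <- order(fit$mu)
        fit$mu[o][1] + fit$sigma[o][1]
      })
  }
  mask <- s_betagamma < threshold
  r <- rle(mask)
  short <- r$values & r$lengths < round(min_dur * rate)
  r$values[short] <- FALSE
  mask <- inverse.rle(r)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  iv <- data.frame(start = t0 + starts[r$values] / rate,
                   end = t0 + ends[r$values] / rate)
  list(mask = mask, intervals = iv, threshold = threshold)
}

# derivative-threshold crossing for one onset: threshold statistics come
# from the putative down interval containing the onset; the crossing is
# searched forward from the onset (the transition itself typically sits at
# or just past the smoothed-power interval end) up to `horizon` seconds
latency_in_interval <- function(d, rate, t0, iv_start, iv_end, onset, k,
                                horizon = 2, sustain = 0.01) {
  lo <- max(as.integer(floor((iv_start - t0) * rate)) + 1L, 1L)
  hi <- min(as.integer(floor((iv_end - t0) * rate)), length(d))
  if (hi - lo < 2) return(list(latency = NA_real_, censored = NA, excluded = TRUE))
  seg <- d[lo:hi]
  mu <- mean(seg); sg <- stats::sd(seg)
  thr <- mu - k * sg
  on_i <- max(as.integer(round((onset - t0) * rate)) + 1L, lo)
  end_i <- min(on_i + as.integer(round(horizon * rate)), length(d))
  below <- d[on_i:end_i] < thr
  # a genuine down-to-up deflection holds the derivative below threshold
  # for tens of ms; require the crossing to be sustained to reject brief
  # noise excursions
  need <- max(1L, as.integer(round(sustain * rate)))
  r <- rle(below)
  qual <- which(r$values & r$lengths >= need)
  if (!length(qual))
    return(list(latency = NA_real_, censored = TRUE, excluded = FALSE))
  first <- if (qual[1] == 1) 1L else sum(r$lengths[seq_len(qual[1] - 1L)]) + 1L
  list(latency = (first - 1L) / rate, censored = FALSE, excluded = FALSE)
}

#' Latency of optogenetically evoked down-to-up transitions
#'
#' For each illumination onset falling inside a putative down state: the
#' mean and SD of the discrete LFP temporal derivative are computed over
#' that down interval, and the evoked transition is the first sample at or
#' after the onset where the derivative drops below `T = mu - k*sigma`
#' (down-to-up transitions are depth-negative deflections in this recording
#' convention; `k = 4` by default). The latency is the time from onset to
#' that crossing; trials without a crossing before the interval end are
#' censored.
#'
#' @param lfp (Artifact-corrected) LFP [time_series()].
#' @param onsets Illumination onset times (s).
#' @param mask Result of [putative_down_mask()].
#' @param k Threshold multiplier (default 4).
#' @param deriv_smooth Moving-average frame (s) applied to the LFP before
#'   differentiation (default 14 ms): the down-to-up deflection unfolds
#'   over tens of milliseconds, while the raw sample-to-sample derivative
#'   at 1 kHz is dominated by beta/gamma-band noise.
#' @param horizon Maximum time (s) after the onset searched for a crossing;
#'   trials without a crossing inside it are censored.
#' @return data.frame per onset: `onset`, `in_down`, `latency` (s; `NA` if
#'   censored or excluded), `censored`, `excluded`.
#' @export
evoked_latency <- function(lfp, onsets, mask, k = 4, deriv_smooth = 0.014,
                           horizon = 2, sustain = 0.01) {
  stopifnot(inherits(lfp, "time_series"))
  rate <- lfp$rate
  sm <- if (deriv_smooth > 0) moving_average(lfp, deriv_smooth)$samples
        else lfp$samples
  d <- c(diff(sm), 0) * rate
  iv <- mask$intervals
  out <- lapply(onsets, function(on) {
    j <- which(iv$start <= on & on < iv$end)
    if (!length(j))
      return(data.frame(onset = on, in_down = FALSE, latency = NA_real_,
                        censored = NA, excluded = TRUE))
    r <- latency_in_interval(d, rate, lfp$t0, iv$start[j[1]], iv$end[j[1]],
                             on, k, horizon, sustain)
    data.frame(onset = on, in_down = TRUE, latency = r$latency,
               censored = isTRUE(r$censored), excluded = r$excluded)
  })
  do.call(rbind, out)
}

#' Latencies of spontaneous down-to-up transitions at surrogate onsets
#'
#' Places periodically distributed surrogate onsets inside spontaneous
#' activity (at least `pre_gap` before each illumination onset and
#' `post_gap` after each offset), keeps those falling inside putative down
#' states, and measures the latency to the next derivative-threshold
#' crossing with a lower multiplier (`k = 2`) to account for the slower
#' slopes of spontaneous transitions.
#'
#' @param lfp LFP [time_series()].
#' @param mask Result of [putative_down_mask()].
#' @param protocol A [stimulation_protocol()] defining the illuminated
#'   epochs to exclude (may have zero onsets).
#' @param period Surrogate onset period (s, default 0.5).
#' @param k Threshold multiplier (default 2).
#' @param pre_gap,post_gap Spontaneous-exclusion margins (s; 0.05 before
#'   onsets, 0.55 after offsets).
#' @param phase Grid phase offset in \[0, period) (s).
#' @return data.frame as in [evoked_latency()].
#' @export
spontaneous_latencies <- function(lfp, mask, protocol, period = 0.5, k = 2,
                                  pre_gap = 0.05, post_gap = 0.55,
                                  phase = 0, deriv_smooth = 0.014,
                                  sustain = 0.01) {
  dur <- ts_duration(lfp)
  grid <- seq(lfp$t0 + phase, lfp$t0 + dur, by = period)
  if (length(protocol$onsets)) {
    excl <- vapply(grid, function(g)
      any(g >= protocol$onsets - pre_gap &
            g <= protocol$onsets + protocol$duration + post_gap), logical(1))
    grid <- grid[!excl]
  }
  if (!length(grid)) stop("spontaneous_latencies: no valid surrogate onsets")
  evoked_latency(lfp, grid, mask, k = k, deriv_smooth = deriv_smooth,
                 sustain = sustain)
}

#' Ratio of evoked to spontaneous transition latency
#'
#' Ratio of the mean uncensored evoked latency over the mean uncensored
#' spontaneous latency; censored or excluded trials are dropped and
#' counted.
#'
#' @param evoked,spontaneous data.frames from [evoked_latency()] /
#'   [spontaneous_latencies()].
#' @return List with `ratio`, `mean_evoked`, `mean_spontaneous`,
#'   `n_evoked`, `n_spontaneous`, `n_censored_evoked`,
#'   `n_censored_spontaneous`.
#' @export
latency_ratio <- function(evoked, spontaneous) {
  ev <- evoked$latency[!is.na(evoked$latency)]
  sp <- spontaneous$latency[!is.na(spontaneous$latency)]
  if (!length(ev) || !length(sp))
    stop("latency_ratio: need at least one uncensored latency in each set")
  list(ratio = mean(ev) / mean(sp),
       mean_evoked = mean(ev), mean_spontaneous = mean(sp),
       n_evoked = length(ev), n_spontaneous = length(sp),
       n_censored_evoked = sum(evoked$censored %in% TRUE),
       n_censored_spontaneous = sum(spontaneous$censored %in% TRUE))
}

#' Full evoked-latency pipeline for one optogenetic session
#'
#' Artifact correction, beta/gamma evidence with 10-ms RMS frames, putative
#' down-state gating, evoked latencies (k = 4) and spontaneous surrogate
#' latencies (k = 2), and their ratio.
#'
#' @param lfp Session LFP [time_series()].
#' @param protocol A [stimulation_protocol()].
#' @param cfg An [analysis_config()].
#' @param threshold Optional fixed down-state threshold (reuse the control
#'   threshold on a post-muscimol session).
#' @return List with `evoked`, `spontaneous` (per-trial data.frames),
#'   `ratio` (see [latency_ratio()]), `mask`, `threshold`.
#' @export
opto_latency_analysis <- function(lfp, protocol, cfg = analysis_config(),
                                  threshold = NULL) {
  corr <- correct_light_artifact(lfp, protocol$onsets,
                                 window = cfg$opto$artifact_window,
                                 smooth = cfg$opto$artifact_smooth,
                                 k = cfg$opto$k_evoked)
  sbg <- betagamma_evidence(corr$lfp, cfg$betagamma$band,
                            rms_frame = cfg$opto$rms_frame,
                            smooth_frame = cfg$betagamma$smooth_frame)
  mask <- putative_down_mask(sbg, rate = corr$lfp$rate,
                             method = cfg$opto$down_threshold,
                             threshold = threshold, t0 = corr$lfp$t0)
  # a light-evoked transition must fall inside the illumination epoch;
  # later crossings are censored rather than attributed to the light
  ev <- evoked_latency(corr$lfp, protocol$onsets, mask, k = cfg$opto$k_evoked,
                       horizon = protocol$duration)
  sp <- spontaneous_latencies(corr$lfp, mask, protocol,
                              period = cfg$opto$surrogate_period,
                              k = cfg$opto$k_spont,
                              pre_gap = cfg$opto$spont_pre_gap,
                              post_gap = cfg$opto$spont_post_gap)
  rat <- latency_ratio(ev, sp)
  list(evoked = ev, spontaneous = sp, ratio = rat, mask = mask,
       threshold = mask$threshold)
}
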