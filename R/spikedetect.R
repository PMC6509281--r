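#' Spike detection parameters
#'
#' @param juxta_highpass_hz High-pass edge for juxtasomal traces (300 Hz).
#' @param juxta_mult Hard-threshold multiplier (6 x estimated SD).
#' @param ptsd_band Band-pass for multi-unit traces (\[300, 3000\] Hz).
#' @param ptsd_lifetime Peak lifetime period (3 ms): maximum separation of
#'   the max/min pair forming one spike.
#' @param ptsd_mult Differential (peak-to-peak) threshold multiplier; the
#'   conventional range is 8-9 x noise SD, default 8.5.
#' @param refractory Refractory period (1 ms) used to discard overlapping
#'   detections.
#' @param sd_estimator `"robust_mad"` (median(|x|)/0.6745, robust to spike
#'   contamination; default) or `"raw_sd"`.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(juxta_highpass_hz = 300, juxta_mult = 6,
                             ptsd_band = c(300, 3000), ptsd_lifetime = 0.003,
                             ptsd_mult = 8.5, refractory = 0.001,
                             sd_estimator = c("robust_mad", "raw_sd")) {
  stopifnot(juxta_mult > 0, ptsd_mult > 0, ptsd_lifetime > 0)
  structure(list(juxta_highpass_hz = juxta_highpass_hz,
                 juxta_mult = juxta_mult, ptsd_band = ptsd_band,
                 ptsd_lifetime = ptsd_lifetime, ptsd_mult = ptsd_mult,
                 refractory = refractory,
                 sd_estimator = match.arg(sd_estimator)),
            class = "detection_params")
}

#' Hard-threshold spike detection for juxtasomal traces
#'
#' High-pass filters the trace (elliptic, 300 Hz cutoff, zero phase),
#' estimates the noise SD, and detects one spike per supra-threshold
#' excursion (threshold = 6 x SD), time-stamped at the positive peak of the
#' excursion.
#'
#' @param ts Juxtasomal [time_series()] (rate >= 2 kHz).
#' @param params A [detection_params()].
#' @return A [spike_train()] (source `"PV"`) with attributes `threshold`
#'   and `noise_sd`.
#' @export
detect_juxtasomal <- function(ts, params = detection_params()) {
  stopifnot(inherits(ts, "time_series"))
  if (ts$rate < 2000) stop("detect_juxtasomal: rate must be >= 2 kHz")
  if (all(ts$samples == 0))
    return(spike_train(numeric(0), "PV", ts_duration(ts)))
  x <- elliptic_filter(ts, "high", params$juxta_highpass_hz)$samples
  sdn <- noise_sd(x, params$sd_estimator)
  thr <- params$juxta_mult * sdn
  above <- x > thr
  if (!any(above)) {
    out <- spike_train(numeric(0), "PV", ts_duration(ts))
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    runs <- which(r$values)
    peaks <- vapply(runs, function(i) {
      seg <- starts[i]:ends[i]
      seg[which.max(x[seg])]
    }, integer(1))
    peaks <- sort(peaks)
    # merge excursions closer than the refractory period (waveform ringing
    # can split one spike into two supra-threshold excursions): keep larger
    if (length(peaks) > 1) {
      refr_n <- params$refractory * ts$rate
      keep <- rep(TRUE, length(peaks))
      last <- 1L
      for (i in 2:length(peaks)) {
        if (peaks[i] - peaks[last] < refr_n) {
          if (x[peaks[i]] > x[peaks[last]]) { keep[last] <- FALSE; last <- i }
          else keep[i] <- FALSE
        } else last <- i
      }
      peaks <- peaks[keep]
    }
    out <- spike_train(ts$t0 + (peaks - 1) / ts$rate, "PV",
                       ts$t0 + ts_duration(ts))
  }
  attr(out, "threshold") <- thr
  attr(out, "noise_sd") <- sdn
  out
}

# indices of local maxima / minima of x (interior strict extrema)
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse flat stretches so plateaus yield a single extremum
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  idx <- nz[which(diff(s[nz]) != 0)] + 1L
  kind <- s[idx - 1L]
  list(max = idx[kind > 0], min = idx[kind < 0])
}

#' Precise-timing spike detection (PTSD) for multi-unit traces
#'
#' Band-pass filters the trace (\[300, 3000\] Hz elliptic, zero phase) and
#' searches for pairs of neighboring relative maxima/minima (either
#' polarity order) whose temporal separation is at most the peak lifetime
#' period (3 ms) and whose peak-to-peak amplitude exceeds the differential
#' threshold (8.5 x noise SD by default). Each accepted pair is
#' time-stamped at its negative voltage peak; detections closer than the
#' 1-ms refractory period are resolved by keeping the larger peak-to-peak
#' event.
#'
#' @param ts Multi-unit [time_series()] (>= 10 kHz recommended).
#' @param params A [detection_params()].
#' @return A [spike_train()] (source `"VPM"`) with attributes `threshold`
#'   and `noise_sd`.
#' @export
detect_ptsd <- function(ts, params = detection_params()) {
  stopifnot(inherits(ts, "time_series"))
  x <- elliptic_filter(ts, "band", params$ptsd_band)$samples
  sdn <- noise_sd(x, params$sd_estimator)
  thr <- params$ptsd_mult * sdn
  ex <- local_extrema(x)
  pk <- sort(c(ex$max, ex$min))
  if (length(pk) < 2) {
    out <- spike_train(numeric(0), "VPM", ts_duration(ts))
    attr(out, "threshold") <- thr; attr(out, "noise_sd") <- sdn
    return(out)
  }
  life_n <- params$ptsd_lifetime * ts$rate
  i1 <- pk[-length(pk)]; i2 <- pk[-1]
  amp <- abs(x[i1] - x[i2])
  # negative-dominant pairs only: the trough must carry at least half the
  # peak-to-peak excursion (timestamps go to negative peaks of negative-
  # dominant extracellular spikes; rejects ringing-rebound pairs)
  trough <- pmin(x[i1], x[i2])
  ok <- amp > thr & (i2 - i1) <= life_n & (-trough) >= amp / 2
  if (!any(ok)) {
    out <- spike_train(numeric(0), "VPM", ts_duration(ts))
    attr(out, "threshold") <- thr; attr(out, "noise_sd") <- sdn
    return(out)
  }
  # each extremum belongs to at most one spike event: accept pairs greedily
  # by peak-to-peak amplitude, consuming both extrema (suppresses filter-
  # ringing rebound pairs that share an extremum with the true spike pair)
  p1 <- i1[ok]; p2 <- i2[ok]; pamp <- amp[ok]
  o <- order(-pamp)
  used <- new.env(hash = TRUE, size = 2L * length(p1))
  acc <- logical(length(p1))
  for (q in o) {
    k1 <- as.character(p1[q]); k2 <- as.character(p2[q])
    if (is.null(used[[k1]]) && is.null(used[[k2]])) {
      acc[q] <- TRUE
      used[[k1]] <- TRUE; used[[k2]] <- TRUE
    }
  }
  neg <- ifelse(x[p1[acc]] < x[p2[acc]], p1[acc], p2[acc])
  cand <- data.frame(idx = neg, amp = pamp[acc])
  cand <- cand[order(cand$idx), ]
  cand <- cand[!duplicated(cand$idx), ]
  # refractory resolution: among detections closer than 1 ms keep the larger
  refr_n <- params$refractory * ts$rate
  keep <- rep(TRUE, nrow(cand))
  last <- 1L
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      if (cand$idx[i] - cand$idx[last] < refr_n) {
        if (cand$amp[i] > cand$amp[last]) {
          keep[last] <- FALSE; last <- i
        } else keep[i] <- FALSE
      } else last <- i
    }
  }
  idx <- cand$idx[keep]
  out <- spike_train(ts$t0 + (idx - 1) / ts$rate, "VPM",
                     ts$t0 + ts_duration(ts))
  attr(out, "threshold") <- thr
  attr(out, "noise_sd") <- sdn
  out
}

#' Match detected to reference spike times
#'
#' Greedy nearest matching within a tolerance; each reference spike is
#' matched at most once. Used to score detector recall/precision against
#' ground truth.
#'
#' @param detected,reference Spike time vectors (s).
#' @param tol Matching tolerance (s, default 1 ms).
#' @return List with `recall`, `precision`, `n_matched`,
#'   `timing_error` (vector of signed errors, detected - reference, for the
#'   matches).
#' @export
match_spike_times <- function(detected, reference, tol = 0.001) {
  if (!length(reference))
    return(list(recall = NA_real_,
                precision = if (length(detected)) 0 else NA_real_,
                n_matched = 0L, timing_error = numeric(0)))
  used <- rep(FALSE, length(reference))
  err <- numeric(0)
  n_matched <- 0L
  for (d in detected) {
    j <- which(!used & abs(reference - d) <= tol)
    if (length(j)) {
      j <- j[which.min(abs(reference[j] - d))]
      used[j] <- TRUE
      err <- c(err, d - reference[j])
      n_matched <- n_matched + 1L
    }
  }
  list(recall = n_matched / length(reference),
       precision = if (length(detected)) n_matched / length(detected) else NA_real_,
       n_matched = n_matched, timing_error = err)
}
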