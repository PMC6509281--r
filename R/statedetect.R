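#' Delta-band phase evidence for the up state
#'
#' Phase-based up-state evidence from the configured low-frequency bands
#' (optimal bands for state detection at 1 kHz: \[0,1\] and \[1,2\] Hz).
#' Two combination methods are provided:
#' \describe{
#'   \item{`"analytic"` (default)}{The per-band analytic signals are
#'     summed -- for contiguous bands this is the analytic signal of the
#'     union band, whose harmonics pin the phase tightly to the actual
#'     waveform transitions (the phase at state boundaries is nearly
#'     identical across cycles, unlike narrowband phases which scatter by
#'     tens of degrees). The phase of the sum is mapped through a
#'     normalized logistic of `cos(phi - phi_up)` with the configured
#'     `sharpness`, giving evidence exactly 1 at the up-state phase and 0
#'     at the opposite phase with a steep but smooth crossing near +/- 90
#'     degrees. `crossing_offset` shifts the 0.5-crossing to
#'     `cos(phi - phi_up) = crossing_offset`, slightly shrinking the
#'     phase region scored as up state; the default 0.2 compensates the
#'     symmetric boundary dilation introduced by the centered smoothing of
#'     the power evidence (the beta/gamma transition burst bleeds ~25 ms
#'     into the neighboring down state on each side).}
#'   \item{`"cosine"`}{The per-band raised-cosine evidences
#'     `e_b(t) = (1 + cos(phi_b(t) - phi_up)) / 2` are averaged across
#'     bands; the simplest monotone phase evidence.}
#' }
#'
#' @param lfp_1k LFP [time_series()] already low-passed and at the working
#'   rate (1 kHz).
#' @param bands List of `c(lo, hi)` band edges in Hz.
#' @param preferred_phase_deg Up-state phase (180 degrees by default, the
#'   depth-negative trough; recycled per band for `"cosine"`).
#' @param method `"analytic"` or `"cosine"`.
#' @param sharpness Logistic steepness for `"analytic"` (default 8).
#' @param crossing_offset 0.5-crossing position in `cos` units for
#'   `"analytic"` (default 0.2).
#' @return Numeric vector in \[0,1\], one value per sample.
#' @export
delta_evidence <- function(lfp_1k, bands = list(c(0, 1), c(1, 2)),
                           preferred_phase_deg = 180,
                           method = c("analytic", "cosine"),
                           sharpness = 8, crossing_offset = 0.2) {
  if (!length(bands)) stop("delta_evidence: empty band list")
  method <- match.arg(method)
  pref <- rep_len(deg2rad(preferred_phase_deg), length(bands))
  clamp_band <- function(b) c(max(b[1], 0.05), b[2])  # keep DC out
  if (method == "analytic") {
    z <- Reduce(`+`, lapply(bands, function(b)
      analytic_signal(lfp_1k, clamp_band(b))))
    cc <- cos(Arg(z) - pref[1])
    sig <- function(v) 1 / (1 + exp(-sharpness * (v - crossing_offset)))
    (sig(cc) - sig(-1)) / (sig(1) - sig(-1))
  } else {
    es <- vapply(seq_along(bands), function(i) {
      ph <- hilbert_phase(lfp_1k, clamp_band(bands[[i]]))$phase
      (1 + cos(ph - pref[i])) / 2
    }, numeric(length(lfp_1k$samples)))
    rowMeans(es)
  }
}

#' Beta/low-gamma power evidence for the up state
#'
#' Band-filters the LFP in \[10, 51\] Hz (elliptic, zero-phase), takes the
#' running RMS in a short frame, smooths with a boxcar, and normalizes the
#' result to \[0, 1\] mapping the minimum to 0 and the 95th percentile to 1
#' (values above are clipped), so the evidence is invariant to amplitude
#' rescaling of the raw LFP.
#'
#' @param lfp_1k LFP [time_series()] at the working rate.
#' @param band Beta/low-gamma band (Hz).
#' @param rms_frame Running-RMS frame (s; 5 ms for state detection, 10 ms in
#'   the evoked-latency pipeline).
#' @param smooth_frame Boxcar smoothing frame (s).
#' @param norm_percentile Upper normalization quantile (default 0.95).
#' @return Numeric vector in \[0,1\].
#' @export
betagamma_evidence <- function(lfp_1k, band = c(10, 51), rms_frame = 0.005,
                               smooth_frame = 0.05, norm_percentile = 0.95) {
  if (stats::sd(lfp_1k$samples) < 1e-12)
    stop("betagamma_evidence: constant trace (zero dynamic range)")
  filt <- elliptic_filter(lfp_1k, "band", band)
  env <- moving_average(running_rms(filt, rms_frame), smooth_frame)$samples
  lo <- min(env)
  hi <- stats::quantile(env, norm_percentile, names = FALSE)
  if (hi - lo < 1e-9 * max(hi, 1e-12))
    stop("betagamma_evidence: constant trace (zero dynamic range)")
  pmin(pmax((env - lo) / (hi - lo), 0), 1)
}

#' Compute the combined state-evidence trace
#'
#' Runs [delta_evidence()] and [betagamma_evidence()] and averages them into
#' the combined decision variable used for segmentation.
#'
#' @param lfp LFP [time_series()]; if its rate exceeds `cfg$working_rate` it
#'   is low-passed at 500 Hz and downsampled first.
#' @param cfg An [analysis_config()].
#' @return Object of class `evidence_trace`: list with `s_delta`,
#'   `s_betagamma`, `s_comb` (all in \[0,1\], equal length,
#'   `s_comb = (s_delta + s_betagamma)/2`), `rate`, `t0`.
#' @export
evidence_trace <- function(lfp, cfg = analysis_config()) {
  stopifnot(inherits(lfp, "time_series"))
  if (lfp$rate > cfg$working_rate) {
    if (cfg$lowpass_hz < lfp$rate / 2)
      lfp <- elliptic_filter(lfp, "low", cfg$lowpass_hz,
                             order = cfg$filter$order,
                             ripple_db = cfg$filter$ripple_db,
                             stop_db = cfg$filter$stop_db)
    lfp <- downsample(lfp, cfg$working_rate)
  }
  sd_ <- delta_evidence(lfp, cfg$delta$bands, cfg$delta$preferred_phase_deg,
                        method = cfg$delta$method,
                        sharpness = cfg$delta$sharpness,
                        crossing_offset = cfg$delta$crossing_offset)
  sb <- betagamma_evidence(lfp, cfg$betagamma$band, cfg$betagamma$rms_frame,
                           cfg$betagamma$smooth_frame,
                           cfg$betagamma$norm_percentile)
  structure(list(s_delta = sd_, s_betagamma = sb,
                 s_comb = (sd_ + sb) / 2, rate = lfp$rate, t0 = lfp$t0),
            class = "evidence_trace")
}

#' @export
print.evidence_trace <- function(x, ...) {
  cat(sprintf("<evidence_trace> %d samples @ %g Hz (s_comb mean %.3f)\n",
              length(x$s_comb), x$rate, mean(x$s_comb)))
  invisible(x)
}

# weighted univariate EM for a K-component Gaussian mixture
em_weighted <- function(x, w, mu, sigma, lambda, max_iter, tol) {
  n <- sum(w)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_along(mu),
                   function(k) lambda[k] * stats::dnorm(x, mu[k], sigma[k]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    resp <- dens / tot
    nk <- colSums(w * resp)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(w * resp * x) / nk
    sigma <- sqrt(pmax(colSums(w * resp * (x - rep(mu, each = length(x)))^2) / nk,
                       1e-8))
    lambda <- nk / n
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, lambda = lambda, loglik = ll_old, n_iter = it)
}

#' Fit a three-Gaussian mixture to the combined evidence
#'
#' EM fit of a three-component univariate Gaussian mixture to the
#' distribution of the combined evidence (excluding the top 5th percentile).
#' Components are sorted by mean: lowest = down state, middle =
#' indeterminate, highest = up state. The state-assignment thresholds are
#' `theta_up = mu_UP - 2 sigma_UP` and `theta_down = mu_DOWN + 2
#' sigma_DOWN`; the fit is flagged degenerate when `theta_down >=
#' theta_up`.
#'
#' For speed the EM runs on a 512-bin histogram of the samples (weighted
#' EM), which is equivalent to sample EM up to binning resolution.
#' Initialization is quantile-based (means near the 10th/50th/90th
#' percentiles) with seeded jitter over `n_restarts` restarts; the restart
#' with the best log-likelihood wins.
#'
#' @param s_comb Numeric vector of combined evidence values (or an
#'   `evidence_trace`).
#' @param seed RNG seed for restart jitter.
#' @param n_restarts Number of EM restarts (default 10).
#' @param max_iter,tol EM stopping rule (500 iterations / 1e-8
#'   log-likelihood change).
#' @param exclude_percentile Upper quantile excluded from the fit (0.95).
#' @return Object of class `gmm_fit`: `means`, `sds`, `weights` (each named
#'   DOWN/INDET/UP), `theta_up`, `theta_down`, `loglik`, `n_iter`,
#'   `degenerate`.
#' @export
fit_three_gaussians <- function(s_comb, seed = 1, n_restarts = 10,
                                max_iter = 500, tol = 1e-8,
                                exclude_percentile = 0.95) {
  if (inherits(s_comb, "evidence_trace")) s_comb <- s_comb$s_comb
  x <- s_comb[s_comb <= stats::quantile(s_comb, exclude_percentile,
                                        names = FALSE)]
  if (stats::sd(x) < 1e-10)
    stop("fit_three_gaussians: degenerate input (all samples equal)")
  # weighted EM on a fine histogram of the retained samples
  nb <- 512L
  br <- seq(min(x), max(x), length.out = nb + 1L)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  keep <- h$counts > 0
  xs <- h$mids[keep]; ws <- h$counts[keep]
  q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  s0 <- stats::sd(x) / 3
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu0 <- q + if (r == 1) 0 else stats::rnorm(3, 0, s0 / 2)
    fit <- em_weighted(xs, ws, sort(mu0), rep(s0, 3), rep(1 / 3, 3),
                       max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  o <- order(best$mu)
  means <- best$mu[o]; sds <- best$sigma[o]; weights <- best$lambda[o]
  names(means) <- names(sds) <- names(weights) <- c("DOWN", "INDET", "UP")
  theta_up <- means["UP"] - 2 * sds["UP"]
  theta_down <- means["DOWN"] + 2 * sds["DOWN"]
  structure(list(means = means, sds = sds, weights = weights,
                 theta_up = unname(theta_up), theta_down = unname(theta_down),
                 loglik = best$loglik, n_iter = best$n_iter,
                 degenerate = unname(theta_down >= theta_up)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(paste0("<gmm_fit> means %.3f/%.3f/%.3f (DOWN/INDET/UP), ",
                     "theta_down = %.3f, theta_up = %.3f%s\n"),
              x$means[1], x$means[2], x$means[3], x$theta_down, x$theta_up,
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Segment the evidence trace into up/down/indeterminate states
#'
#' Samples with combined evidence strictly above `theta_up` are up state,
#' strictly below `theta_down` down state, all others (including exact
#' threshold ties) indeterminate. Two post-processing rules are then
#' applied once, in order: (1) indeterminate gaps shorter than `min_gap`
#' flanked by two states of the same label are merged into that label;
#' (2) up or down runs shorter than `min_dur` are relabeled indeterminate.
#'
#' @param s_comb Combined evidence (numeric vector or `evidence_trace`).
#' @param fit A `gmm_fit` (must not be degenerate).
#' @param rate Working rate (Hz); taken from the evidence trace if given.
#' @param min_dur Minimum up/down state duration (s; default 0.1).
#' @param min_gap Minimum inter-state interval (s; default 0.05).
#' @param t0 Start time (s).
#' @return A [state_segmentation()].
#' @export
segment_states <- function(s_comb, fit, rate = 1000, min_dur = 0.1,
                           min_gap = 0.05, t0 = 0) {
  if (inherits(s_comb, "evidence_trace")) {
    rate <- s_comb$rate; t0 <- s_comb$t0; s_comb <- s_comb$s_comb
  }
  stopifnot(inherits(fit, "gmm_fit"))
  if (fit$degenerate)
    stop("segment_states: degenerate mixture fit (theta_down >= theta_up)")
  lab <- ifelse(s_comb > fit$theta_up, "UP",
                ifelse(s_comb < fit$theta_down, "DOWN", "INDET"))
  r <- rle(lab)
  # rule 1: short INDET gap between two same-label states -> merged
  min_gap_n <- round(min_gap * rate)
  v <- r$values; l <- r$lengths
  if (length(v) > 2) {
    for (i in 2:(length(v) - 1)) {
      if (v[i] == "INDET" && l[i] < min_gap_n &&
          v[i - 1] == v[i + 1] && v[i - 1] != "INDET")
        v[i] <- v[i - 1]
    }
  }
  r2 <- rle(inverse.rle(list(values = v, lengths = l)))
  # rule 2: short UP/DOWN runs -> INDET
  min_dur_n <- round(min_dur * rate)
  short <- r2$values != "INDET" & r2$lengths < min_dur_n
  r2$values[short] <- "INDET"
  r3 <- rle(inverse.rle(r2))
  ends_n <- cumsum(r3$lengths)
  starts_n <- c(0, ends_n[-length(ends_n)])
  state_segmentation(t0 + starts_n / rate, t0 + ends_n / rate, r3$values,
                     rate = rate)
}

#' Detect up/down states from a raw LFP trace
#'
#' Convenience pipeline: evidence computation ([evidence_trace()]),
#' three-Gaussian fit ([fit_three_gaussians()]) and segmentation
#' ([segment_states()]).
#'
#' @param lfp LFP [time_series()].
#' @param cfg An [analysis_config()].
#' @return List with `segmentation`, `fit`, `evidence`.
#' @export
detect_states <- function(lfp, cfg = analysis_config()) {
  ev <- evidence_trace(lfp, cfg)
  fit <- fit_three_gaussians(ev, seed = cfg$gmm$seed,
                             n_restarts = cfg$gmm$n_restarts,
                             max_iter = cfg$gmm$max_iter, tol = cfg$gmm$tol,
                             exclude_percentile = cfg$gmm$exclude_percentile)
  seg <- segment_states(ev, fit, min_dur = cfg$segment$min_dur,
                        min_gap = cfg$segment$min_gap)
  list(segmentation = seg, fit = fit, evidence = ev)
}

#' Per-state duration and spiking summary metrics
#'
#' For the segmentation: per-label duration mean and CV and up-state
#' frequency (up states per second of recording). For each spike train: the
#' fraction of spikes in up/down/indeterminate periods, the active-state
#' ratios (states of a label containing at least one spike over all states
#' of that label) and the mean spike count per active state.
#'
#' @param seg A [state_segmentation()].
#' @param spikes A [spike_train()] or list of them.
#' @return List with `states` (data.frame per label: `n`, `mean_dur`,
#'   `cv_dur`), `up_state_freq`, and `trains`: per train a list with
#'   `fractions` (UP/DOWN/INDET, summing to 1), `active_ratio` (UP, DOWN)
#'   and `mean_spikes_per_active` (UP, DOWN). Ratios are `NA` when a label
#'   has no states.
#' @export
state_metrics <- function(seg, spikes) {
  if (inherits(spikes, "spike_train")) spikes <- list(spikes)
  dur <- seg$end - seg$start
  total_time <- max(seg$end) - min(seg$start)
  per_label <- do.call(rbind, lapply(STATE_LEVELS, function(l) {
    d <- dur[seg$label == l]
    data.frame(label = l, n = length(d),
               mean_dur = if (length(d)) mean(d) else NA_real_,
               cv_dur = if (length(d) > 1) stats::sd(d) / mean(d) else NA_real_)
  }))
  trains <- lapply(spikes, function(tr) {
    iv <- interval_at(seg, tr$times)
    lab <- factor(seg$label[iv], STATE_LEVELS)
    counts <- table(lab)
    n <- length(tr$times)
    fractions <- if (sum(counts)) as.numeric(counts) / sum(counts)
                 else rep(NA_real_, 3)
    names(fractions) <- STATE_LEVELS
    act <- vapply(c("UP", "DOWN"), function(l) {
      rows <- which(seg$label == l)
      if (!length(rows)) return(c(ratio = NA_real_, mean_count = NA_real_))
      cnt <- tabulate(match(iv, rows), nbins = length(rows))
      active <- cnt > 0
      c(ratio = mean(active),
        mean_count = if (any(active)) mean(cnt[active]) else NA_real_)
    }, numeric(2))
    list(source = tr$source, n_spikes = n, fractions = fractions,
         active_ratio = act["ratio", ],
         mean_spikes_per_active = act["mean_count", ])
  })
  list(states = per_label,
       up_state_freq = sum(seg$label == "UP") / total_time,
       trains = trains)
}

#' Spike rate before and after stimulus onsets
#'
#' Counts spikes in windows `[-w, 0)` and `[0, w)` around each onset and
#' converts to spikes/s; used e.g. to quantify whisker-evoked responses.
#'
#' @param spikes A [spike_train()].
#' @param onsets Stimulus onset times (s).
#' @param window Window length (s, default 0.1).
#' @return List with `per_onset` (data.frame `onset`, `pre_rate`,
#'   `post_rate`) and `summary` (mean pre/post rates and, when at least two
#'   onsets with non-identical differences exist, a paired Wilcoxon
#'   signed-rank p-value, two-sided).
#' @export
evoked_rate_change <- function(spikes, onsets, window = 0.1) {
  stopifnot(inherits(spikes, "spike_train"))
  pre <- vapply(onsets, function(o)
    sum(spikes$times >= o - window & spikes$times < o), numeric(1)) / window
  post <- vapply(onsets, function(o)
    sum(spikes$times >= o & spikes$times < o + window), numeric(1)) / window
  p <- NA_real_
  if (length(onsets) >= 2 && any(pre != post))
    p <- suppressWarnings(stats::wilcox.test(pre, post, paired = TRUE)$p.value)
  list(per_onset = data.frame(onset = onsets, pre_rate = pre, post_rate = post),
       summary = list(mean_pre = mean(pre), mean_post = mean(post),
                      wilcoxon_p = p))
}
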