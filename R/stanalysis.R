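#' Spike-triggered firing-rate curve
#'
#' Averages segments of an instantaneous-firing-rate trace aligned at
#' trigger times (e.g. VPM IFR triggered on PV spikes fired in down
#' states). Triggers closer than the window to either recording edge are
#' dropped (their count is reported).
#'
#' @param ifr A `rate_trace` (see [kernel_ifr()]).
#' @param triggers Trigger times (s).
#' @param window Half-window (s, default 0.5): the curve covers
#'   \[-window, +window\].
#' @return List with `lag` (s), `mean` and `sem` (spikes/s; SEM across
#'   triggers), `n_triggers`, `n_dropped`.
#' @export
spike_triggered_ifr <- function(ifr, triggers, window = 0.5) {
  stopifnot(inherits(ifr, "time_series"))
  rate <- ifr$rate
  n <- length(ifr$samples)
  half <- as.integer(round(window * rate))
  ctr <- as.integer(round(triggers * rate)) + 1L
  ok <- ctr - half >= 1L & ctr + half <= n
  n_dropped <- sum(!ok)
  ctr <- ctr[ok]
  if (!length(ctr)) stop("spike_triggered_ifr: no usable triggers")
  seg <- vapply(ctr, function(c0) ifr$samples[(c0 - half):(c0 + half)],
                numeric(2L * half + 1L))
  mu <- rowMeans(seg)
  sem <- if (length(ctr) > 1) apply(seg, 1, stats::sd) / sqrt(length(ctr))
         else rep(0, length(mu))
  list(lag = seq(-half, half) / rate, mean = mu, sem = sem,
       n_triggers = length(ctr), n_dropped = n_dropped)
}

#' Mean firing rate in pre/post windows around triggers
#'
#' Per trigger: mean of the IFR trace in `[-w, 0)` (pre) and `[0, w)`
#' (post).
#'
#' @inheritParams spike_triggered_ifr
#' @param window Window length (s, default 0.1).
#' @return data.frame with `trigger`, `pre`, `post` (spikes/s); triggers too
#'   close to the edges are dropped.
#' @export
prepost_rates <- function(ifr, triggers, window = 0.1) {
  rate <- ifr$rate
  n <- length(ifr$samples)
  w <- as.integer(round(window * rate))
  ctr <- as.integer(round(triggers * rate)) + 1L
  ok <- ctr - w >= 1L & ctr + w - 1L <= n
  ctr <- ctr[ok]
  pre <- vapply(ctr, function(c0) mean(ifr$samples[(c0 - w):(c0 - 1L)]),
                numeric(1))
  post <- vapply(ctr, function(c0) mean(ifr$samples[c0:(c0 + w - 1L)]),
                 numeric(1))
  data.frame(trigger = (ctr - 1L) / rate, pre = pre, post = post)
}

#' Constrained surrogate spike ensembles for the triggered-rate null
#'
#' Builds `n_surrogates` artificial PV spike sets that preserve, per
#' surrogate: the total number of real down-state PV spikes, the empirical
#' down-state phase-of-firing distribution (the real spike phases are
#' permuted, so every surrogate carries exactly the real phase multiset),
#' the maximum number of sampled down states (the number of PV-active down
#' states in the real data) and the maximum number of spikes per down
#' state. Surrogate spikes are placed only in PV-silent down states
#' (sampled duration-weighted -- random placement per unit time -- without
#' replacement within one surrogate, restricted to states longer than twice
#' the pre/post window so the windows fit): each spike's phase is mapped to
#' the in-state sample whose phase is circularly nearest (earliest sample
#' on ties).
#'
#' @param seg A [state_segmentation()].
#' @param pv_spikes PV [spike_train()].
#' @param phase_trace A `phase_trace` for the recording.
#' @param n_surrogates Number of surrogate sets (default 100).
#' @param window Pre/post analysis window the surrogates must accommodate
#'   (s).
#' @param seed RNG seed.
#' @return Object of class `surrogate_ensemble`: list with `sets` (list of
#'   numeric spike-time vectors), `n_real`, `max_per_state`,
#'   `n_states_real`, `real_down_spikes`.
#' @export
generate_surrogates <- function(seg, pv_spikes, phase_trace,
                                n_surrogates = 100, window = 0.1, seed = 1) {
  iv <- interval_at(seg, pv_spikes$times)
  down_rows <- which(seg$label == "DOWN")
  in_down <- !is.na(iv) & iv %in% down_rows
  real_t <- pv_spikes$times[in_down]
  if (!length(real_t))
    stop("generate_surrogates: no real down-state PV spikes")
  real_iv <- iv[in_down]
  n_real <- length(real_t)
  counts_per_state <- table(real_iv)
  max_per_state <- max(counts_per_state)
  n_states_real <- length(counts_per_state)
  active <- as.integer(names(counts_per_state))
  silent <- setdiff(down_rows, active)
  silent <- silent[seg$end[silent] - seg$start[silent] > 2 * window]
  if (!length(silent))
    stop("generate_surrogates: no PV-silent down states longer than 2x window")
  real_phases <- phase_at(phase_trace, real_t)
  # precompute in-state sample indices and phases per silent state
  rate <- phase_trace$rate
  state_samples <- lapply(silent, function(r) {
    lo <- as.integer(ceiling((seg$start[r] - phase_trace$t0) * rate)) + 1L
    hi <- as.integer(floor((seg$end[r] - phase_trace$t0) * rate))
    lo <- max(lo, 1L); hi <- min(hi, length(phase_trace$phase))
    idx <- lo:hi
    list(t = phase_trace$t0 + (idx - 1L) / rate, phase = phase_trace$phase[idx])
  })
  names(state_samples) <- as.character(silent)
  set.seed(seed)
  n_take <- min(n_states_real, length(silent))
  if (n_take * max_per_state < n_real)
    stop(sprintf(paste0("generate_surrogates: cannot place %d spikes in %d ",
                        "states with <= %d spikes each"),
                 n_real, n_take, max_per_state))
  dur_w <- seg$end[silent] - seg$start[silent]
  sets <- vector("list", n_surrogates)
  for (s in seq_len(n_surrogates)) {
    chosen <- sample(seq_along(silent), n_take, replace = FALSE, prob = dur_w)
    cap <- rep(max_per_state, n_take)
    assigned <- integer(n_real)
    for (k in seq_len(n_real)) {
      avail <- which(cap > 0)
      pick <- if (length(avail) == 1) avail else sample(avail, 1)
      assigned[k] <- chosen[pick]
      cap[pick] <- cap[pick] - 1L
    }
    phases <- if (n_real > 1) sample(real_phases) else real_phases
    tms <- numeric(n_real)
    for (k in seq_len(n_real)) {
      ss <- state_samples[[assigned[k]]]
      d <- Arg(exp(1i * (ss$phase - phases[k])))
      j <- which.min(abs(d))  # which.min takes the earliest on ties
      tms[k] <- ss$t[j]
    }
    sets[[s]] <- sort(tms)
  }
  structure(list(sets = sets, n_real = n_real, max_per_state = max_per_state,
                 n_states_real = n_states_real, real_down_spikes = real_t),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d sets of %d spikes (max %d per state, %d states)\n",
              length(x$sets), x$n_real, x$max_per_state, x$n_states_real))
  invisible(x)
}

#' z-score of real pre/post rates against the surrogate distribution
#'
#' @param real_pre,real_post Real mean rates in the pre/post windows
#'   (spikes/s).
#' @param surr_pre,surr_post Vectors of per-surrogate mean rates.
#' @return List with `z_pre`, `z_post`, one-tailed p-values
#'   (`p = 1 - Phi(z)`, testing for rate excess), and the 5th/95th
#'   percentiles of each surrogate distribution.
#' @export
surrogate_zscore <- function(real_pre, real_post, surr_pre, surr_post) {
  zs <- function(real, surr) {
    s <- stats::sd(surr)
    if (!is.finite(s) || s == 0)
      stop("surrogate_zscore: zero surrogate SD")
    (real - mean(surr)) / s
  }
  z_pre <- zs(real_pre, surr_pre)
  z_post <- zs(real_post, surr_post)
  list(z_pre = z_pre, z_post = z_post,
       p_pre = 1 - stats::pnorm(z_pre), p_post = 1 - stats::pnorm(z_post),
       pre_pct = stats::quantile(surr_pre, c(0.05, 0.95), names = FALSE),
       post_pct = stats::quantile(surr_post, c(0.05, 0.95), names = FALSE))
}

#' Paired pre/post firing-rate comparison at triggers
#'
#' Wilcoxon signed-rank test on per-trigger pre vs post mean rates.
#'
#' @inheritParams prepost_rates
#' @param alternative Passed to [stats::wilcox.test()] (`"greater"` tests
#'   pre > post).
#' @return List with the per-trigger data.frame, `mean_pre`, `mean_post`
#'   and `p` (`NA` when all differences are zero or triggers < 5).
#' @export
pre_post_comparison <- function(ifr, triggers, window = 0.1,
                                alternative = "greater") {
  pp <- prepost_rates(ifr, triggers, window)
  p <- NA_real_
  if (nrow(pp) >= 5 && any(pp$pre != pp$post))
    p <- suppressWarnings(
      stats::wilcox.test(pp$pre, pp$post, paired = TRUE,
                         alternative = alternative)$p.value)
  list(per_trigger = pp, mean_pre = mean(pp$pre), mean_post = mean(pp$post),
       p = p)
}

#' Rate variation normalized to the surrogate baseline
#'
#' Expresses pre- and post-trigger rates as percentage deviations from the
#' overall mean surrogate-triggered rate, `100 * (rate - baseline) /
#' baseline`.
#'
#' @param pre,post Rates (spikes/s).
#' @param surrogate_mean Overall mean surrogate-triggered rate (> 0).
#' @return Named vector `c(pre_pct, post_pct)`.
#' @export
normalized_variation <- function(pre, post, surrogate_mean) {
  if (!is.finite(surrogate_mean) || surrogate_mean <= 0)
    stop("normalized_variation: surrogate mean must be > 0")
  c(pre_pct = 100 * (pre - surrogate_mean) / surrogate_mean,
    post_pct = 100 * (post - surrogate_mean) / surrogate_mean)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, find
#' the largest k with `p_(k) <= k * alpha / m` and reject hypotheses
#' 1..k. Adjusted p-values are the usual monotone BH values.
#'
#' @param pvals P-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `rejected` (logical, original order) and `adjusted`
#'   (BH-adjusted p-values).
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("fdr_bh: p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  thresh <- seq_len(m) * alpha / m
  k <- which(ps <= thresh)
  rejected <- rep(FALSE, m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj
  list(rejected = rejected, adjusted = adjusted)
}

#' Upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; exact and numerically stable for
#' very small tails. Used as the combination test for counting how many of
#' n independent per-cell tests came out significant at level p0.
#'
#' @param n Number of trials.
#' @param k Observed count (0 <= k <= n).
#' @param p0 Success probability under the null.
#' @return `P(X >= k)`.
#' @examples
#' binomial_tail(18, 11, 0.05)  # 1.12e-10
#' @export
binomial_tail <- function(n, k, p0) {
  if (k > n || k < 0) stop("binomial_tail: need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("binomial_tail: p0 must be in (0, 1)")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Full spike-triggered analysis of one recording
#'
#' Orchestrates the triggered-rate causality analysis for one session:
#' computes the target-train IFR ([kernel_ifr()]), restricts triggers to
#' the chosen state, builds the constrained surrogate ensemble
#' ([generate_surrogates()]), and reports real and surrogate pre/post
#' rates, z-scores with one-tailed p-values, the paired Wilcoxon pre-vs-post
#' comparison, normalized variations and the triggered-rate curves.
#'
#' @param seg A [state_segmentation()].
#' @param trigger_spikes Trigger train (PV) [spike_train()].
#' @param target_spikes Target train (VPM) [spike_train()].
#' @param phase_trace A `phase_trace` for the recording.
#' @param state Restrict triggers to this state (default `"DOWN"`).
#' @param kernel_sd IFR kernel SD (s, default 0.0125).
#' @param window Pre/post window (s, default 0.1).
#' @param curve_window Half-window of the reported curves (s).
#' @param n_surrogates Surrogate count (default 100).
#' @param seed RNG seed for the surrogates.
#' @return Object of class `sta_result`; see fields in the implementation:
#'   `real` (pre/post means, curve), `surrogate` (per-surrogate pre/post
#'   means, overall mean, curve of the surrogate-mean), `z` (z-scores and
#'   one-tailed p), `wilcoxon` (paired pre-vs-post), `normalized`
#'   (percentage variations), `n_triggers`.
#' @export
sta_analysis <- function(seg, trigger_spikes, target_spikes, phase_trace,
                         state = "DOWN", kernel_sd = 0.0125, window = 0.1,
                         curve_window = 0.5, n_surrogates = 100, seed = 1) {
  rate <- phase_trace$rate
  dur <- max(seg$end)
  ifr <- kernel_ifr(target_spikes, kernel_sd, rate, dur)
  lab <- state_at(seg, trigger_spikes$times)
  trig <- trigger_spikes$times[!is.na(lab) & lab == state]
  if (!length(trig)) stop("sta_analysis: no triggers in the requested state")
  curve <- spike_triggered_ifr(ifr, trig, curve_window)
  pp <- prepost_rates(ifr, trig, window)
  real_pre <- mean(pp$pre); real_post <- mean(pp$post)
  ens <- generate_surrogates(seg, trigger_spikes, phase_trace,
                             n_surrogates = n_surrogates, window = window,
                             seed = seed)
  surr <- vapply(ens$sets, function(tms) {
    s <- prepost_rates(ifr, tms, window)
    c(pre = mean(s$pre), post = mean(s$post))
  }, numeric(2))
  z <- surrogate_zscore(real_pre, real_post, surr["pre", ], surr["post", ])
  surr_overall <- mean(surr)
  wil <- pre_post_comparison(ifr, trig, window, alternative = "greater")
  nv <- if (surr_overall > 0)
    normalized_variation(real_pre, real_post, surr_overall)
  else c(pre_pct = NA_real_, post_pct = NA_real_)
  structure(list(
    state = state, n_triggers = length(trig),
    real = list(pre = real_pre, post = real_post, curve = curve),
    surrogate = list(pre = surr["pre", ], post = surr["post", ],
                     overall_mean = surr_overall, ensemble = ens),
    z = z, wilcoxon = wil, normalized = nv
  ), class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf(paste0("<sta_result> %d triggers in %s state: pre %.2f / post %.2f spikes/s, ",
                     "z_pre = %.2f (p = %.3g), z_post = %.2f (p = %.3g)\n"),
              x$n_triggers, x$state, x$real$pre, x$real$post,
              x$z$z_pre, x$z$p_pre, x$z$z_post, x$z$p_post))
  invisible(x)
}
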