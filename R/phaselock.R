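deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) {
  d <- r * 180 / pi
  d %% 360
}

#' Rescale phases by the empirical cumulative distribution of a phase trace
#'
#' Asymmetric slow-wave shapes make the raw distribution of instantaneous
#' phase across time non-uniform, which would bias any phase-locking
#' statistic. This maps phases through the empirical CDF `F` of all time
#' samples of the trace, `phi' = 2*pi*F(phi) - pi`, so the all-sample phase
#' distribution becomes uniform; spike phases are passed through the same
#' map.
#'
#' @param phase_trace A `phase_trace` (see [hilbert_phase()]).
#' @param phases Phases to rescale (radians); defaults to the trace's own
#'   samples.
#' @return Rescaled phases in radians, in \[-pi, pi).
#' @export
rescale_phases <- function(phase_trace, phases = phase_trace$phase) {
  ref <- phase_trace$phase
  if (!length(ref)) stop("rescale_phases: empty phase trace")
  s <- sort(ref)
  n <- length(s)
  fv <- (seq_len(n) - 0.5) / n
  f <- stats::approx(s, fv, xout = phases, rule = 2, ties = "ordered")$y
  out <- 2 * pi * f - pi
  out[out >= pi] <- pi - 1e-12
  out
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Tests departure from uniformity of a sample of angles using the standard
#' approximation to the Rayleigh statistic. Significant (small) p indicates
#' phase locking; the conventional significance level in this pipeline is
#' 0.01.
#'
#' @param angles Angles in radians.
#' @return List with `r_bar` (mean resultant length), `z` (n * r_bar^2),
#'   `p`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("rayleigh_test: need at least 2 angles")
  rbar <- Mod(mean(exp(1i * angles)))
  rl <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - rl^2)) - (1 + 2 * n))
  list(r_bar = rbar, z = n * rbar^2, p = min(p, 1), n = n)
}

#' Preferred phase and locking strength
#'
#' Locking strength is one minus the circular variance, i.e. the mean
#' resultant length of the unit vectors; the preferred phase is the circular
#' mean, reported in degrees in \[0, 360).
#'
#' @param angles Angles in radians.
#' @return List with `preferred_phase_deg` and `locking_strength`.
#' @export
locking_stats <- function(angles) {
  if (!length(angles)) stop("locking_stats: no angles")
  m <- mean(exp(1i * angles))
  list(preferred_phase_deg = rad2deg(Arg(m)), locking_strength = Mod(m))
}

# A1(kappa) = I1(kappa)/I0(kappa), computed with scaled Bessel functions
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises fit
#'
#' The mean direction is the circular mean; the concentration `kappa` solves
#' `A1(kappa) = r_bar` (with `A1 = I1/I0`) by Newton iteration, capped at
#' 1e3. A zero resultant yields `kappa = 0` with undefined (`NA`) mean.
#'
#' @param angles Angles in radians (n >= 10 recommended for stable fits).
#' @return List with `mu_deg`, `kappa`, `r_bar`, `n`.
#' @export
fit_von_mises <- function(angles) {
  n <- length(angles)
  m <- mean(exp(1i * angles))
  rbar <- Mod(m)
  if (rbar < 1e-12)
    return(list(mu_deg = NA_real_, kappa = 0, r_bar = rbar, n = n))
  # Banerjee et al. starting value, then Newton on A1(k) - rbar
  k <- rbar * (2 - rbar^2) / max(1 - rbar^2, 1e-9)
  k <- min(max(k, 1e-6), 1e3)
  for (i in 1:50) {
    a <- vm_a1(k)
    da <- 1 - a^2 - a / k
    step <- (a - rbar) / da
    k_new <- min(max(k - step, 1e-8), 1e3)
    if (abs(k_new - k) < 1e-10) { k <- k_new; break }
    k <- k_new
  }
  list(mu_deg = rad2deg(Arg(m)), kappa = k, r_bar = rbar, n = n)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to uniform angles.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in radians in \[-pi, pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) {
    th <- stats::runif(n, -pi, pi)
    return(th)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(length(th), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  th <- out + mu
  ((th + pi) %% (2 * pi)) - pi
}

#' Full phase-locking summary for one spike train
#'
#' Rescales spike phases by the all-sample phase CDF (see
#' [rescale_phases()]), then computes the Rayleigh test, preferred phase,
#' locking strength, a normalized phase histogram and a von Mises fit.
#'
#' @param phase_trace A `phase_trace` for the recording.
#' @param spikes A [spike_train()].
#' @param n_bins Histogram bins over \[0, 360) degrees (default 18 bins of
#'   20 degrees).
#' @return An object of class `phase_locking`: list with
#'   `preferred_phase_deg`, `locking_strength`, `rayleigh_p`, `n_spikes`,
#'   `histogram` (data.frame `bin_lo_deg`, `bin_hi_deg`, `density` summing
#'   to 1), `von_mises` (`mu_deg`, `kappa`), and the rescaled spike phases.
#' @export
phase_locking <- function(phase_trace, spikes, n_bins = 18) {
  stopifnot(inherits(spikes, "spike_train"))
  if (!length(spikes$times)) stop("phase_locking: empty spike train")
  raw <- phase_at(phase_trace, spikes$times)
  ph <- rescale_phases(phase_trace, raw)
  rt <- rayleigh_test(ph)
  ls <- locking_stats(ph)
  vm <- fit_von_mises(ph)
  deg <- rad2deg(ph)
  edges <- seq(0, 360, length.out = n_bins + 1)
  counts <- graphics::hist(deg, breaks = edges, plot = FALSE)$counts
  structure(list(
    preferred_phase_deg = ls$preferred_phase_deg,
    locking_strength = ls$locking_strength,
    rayleigh_p = rt$p,
    n_spikes = length(ph),
    histogram = data.frame(bin_lo_deg = edges[-length(edges)],
                           bin_hi_deg = edges[-1],
                           density = counts / sum(counts)),
    von_mises = list(mu_deg = vm$mu_deg, kappa = min(vm$kappa, 1e3)),
    spike_phases = ph
  ), class = "phase_locking")
}

#' @export
print.phase_locking <- function(x, ...) {
  cat(sprintf(paste0("<phase_locking> n = %d spikes: preferred phase %.1f deg, ",
                     "strength %.3f, Rayleigh p = %.3g, von Mises (mu = %.1f deg, kappa = %.2f)\n"),
              x$n_spikes, x$preferred_phase_deg, x$locking_strength,
              x$rayleigh_p, x$von_mises$mu_deg, x$von_mises$kappa))
  invisible(x)
}

# is angle (deg, [0,360)) inside a possibly wrapping [a, b] range?
in_circular_range <- function(deg, range_deg) {
  a <- range_deg[1] %% 360; b <- range_deg[2] %% 360
  if (a <= b) deg >= a & deg <= b else deg >= a | deg <= b
}

#' State-restricted phase and relative-time distributions
#'
#' Restricts spikes to those fired inside intervals of one state whose phase
#' lies in the state's characteristic phase range (5th-95th percentile
#' ranges: \[95, 255\] degrees for up states, \[295, 75\] degrees -- wrapping
#' through 0 -- for down states), rescales the within-range phases by the
#' within-range CDF of all same-state time samples, and also expresses each
#' spike as a relative time inside its interval (0 = state start, 1 = state
#' end).
#'
#' @param seg A [state_segmentation()].
#' @param phase_trace A `phase_trace` aligned with `seg`.
#' @param spikes A [spike_train()].
#' @param state `"UP"` or `"DOWN"`.
#' @param range_deg Phase range in degrees; defaults per state.
#' @param n_bins Histogram bins.
#' @return Object of class `state_restricted_distribution`: `state`,
#'   `range_deg`, `n_spikes`, `phase_hist` and `time_hist` (normalized),
#'   `rescaled_phase` in \[0,1\], `relative_time` in \[0,1\],
#'   `median_relative_time`. Empty result is flagged with `empty = TRUE`.
#' @export
state_restricted_distribution <- function(seg, phase_trace, spikes, state,
                                          range_deg = NULL, n_bins = 10) {
  state <- match.arg(state, c("UP", "DOWN"))
  if (is.null(range_deg))
    range_deg <- if (state == "UP") c(95, 255) else c(295, 75)
  iv <- interval_at(seg, spikes$times)
  in_state <- !is.na(iv) & seg$label[pmax(iv, 1L)] == state
  sp_t <- spikes$times[in_state]
  sp_iv <- iv[in_state]
  sp_deg <- rad2deg(phase_at(phase_trace, sp_t))
  keep <- in_circular_range(sp_deg, range_deg)
  sp_t <- sp_t[keep]; sp_iv <- sp_iv[keep]; sp_deg <- sp_deg[keep]
  # same-state trace samples inside the range (INDET and other states excluded)
  t_all <- phase_trace$t0 + (seq_along(phase_trace$phase) - 1) / phase_trace$rate
  samp_state <- state_at(seg, t_all)
  tr_deg <- rad2deg(phase_trace$phase)
  tr_in <- !is.na(samp_state) & samp_state == state &
    in_circular_range(tr_deg, range_deg)
  if (!length(sp_t) || !sum(tr_in)) {
    return(structure(list(state = state, range_deg = range_deg,
                          n_spikes = 0L, empty = TRUE),
                     class = "state_restricted_distribution"))
  }
  span <- (range_deg[2] - range_deg[1]) %% 360
  if (span == 0) span <- 360
  shift <- function(d) (d - range_deg[1]) %% 360
  ref <- sort(shift(tr_deg[tr_in]))
  fv <- (seq_along(ref) - 0.5) / length(ref)
  resc <- stats::approx(ref, fv, xout = shift(sp_deg), rule = 2,
                        ties = "ordered")$y
  rel_t <- (sp_t - seg$start[sp_iv]) / (seg$end[sp_iv] - seg$start[sp_iv])
  edges <- seq(0, 1, length.out = n_bins + 1)
  hcount <- function(v) {
    h <- graphics::hist(pmin(pmax(v, 0), 1), breaks = edges, plot = FALSE)$counts
    h / sum(h)
  }
  structure(list(
    state = state, range_deg = range_deg, n_spikes = length(sp_t),
    empty = FALSE,
    phase_hist = data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                            density = hcount(resc)),
    time_hist = data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                           density = hcount(rel_t)),
    rescaled_phase = resc, relative_time = rel_t,
    median_relative_time = stats::median(rel_t)
  ), class = "state_restricted_distribution")
}
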