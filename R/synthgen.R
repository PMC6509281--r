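#' Parameters of the synthetic slow-oscillation generator
#'
#' Defaults emulate the statistical structure of urethane-anesthetized
#' thalamo-cortical recordings: up/down alternation with gamma-distributed
#' durations (mean 0.4 s up / 0.6 s down, shape 4, giving cycle frequencies
#' inside 0.2-1 Hz), a depth-positive-down / depth-negative-up delta
#' waveform, beta/low-gamma \[10,51\] Hz noise three times stronger in up
#' states, a 1/f background, PV interneuron firing strongly locked near 188
#' degrees at about 3.4 spikes/s overall with occasional down-state spikes,
#' VPM multi-unit firing more weakly locked at about 10 spikes/s and active
#' in roughly half of down states, an optional causal VPM-to-PV coupling at
#' a configurable lag, and optogenetically evoked down-to-up transitions
#' with mean latency 0.11 s (control) or 0.25 s with slowed rhythm and
#' suppressed down-state PV firing ("muscimol" mode).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(...) {
  p <- list(
    up_mean = 0.4, up_shape = 4, down_mean = 0.6, down_shape = 4,
    delta_amplitude = 1, delta_asymmetry = 0, ramp = 0.05,
    bg_sd_up = 0.15, bg_ratio = 3, pink_sd = 0.03,
    pv_rate_up = 8, pv_rate_down = 0.3,
    vpm_rate_up = 23, vpm_rate_down = 1.2,
    pv_kappa = 1.4, pv_pref_deg = 188,
    vpm_kappa = 0.6, vpm_pref_deg = 191,
    coupling_lag = 0.02, coupling_sd = 0.005, coupling_gain = 0,
    opto_latency_mean = 0.11, opto_latency_sd = 0.02,
    muscimol_latency_mean = 0.25, muscimol_latency_sd = 0.05,
    muscimol_pv_suppression = 0.2, muscimol_down_factor = 1.6,
    artifact_amp = 0.6, artifact_dur = 0.004,
    spike_noise_sd = 1, juxta_amp_mult = 10, mua_amp_mult = 12,
    seed = 1
  )
  upd <- list(...)
  unknown <- setdiff(names(upd), names(p))
  if (length(unknown))
    stop("synth_params: unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(upd)] <- upd
  with(p, {
    if (any(c(pv_rate_up, pv_rate_down, vpm_rate_up, vpm_rate_down) < 0))
      stop("synth_params: rates must be >= 0")
    if (any(c(up_mean, down_mean) <= 0))
      stop("synth_params: state duration means must be > 0")
    if (coupling_gain < 0) stop("synth_params: coupling_gain must be >= 0")
  })
  structure(p, class = "synth_params")
}

#' Generate an alternating up/down state sequence
#'
#' Semi-Markov alternation starting in a down state: durations are i.i.d.
#' gamma (configured mean and shape per state), truncated below at 100 ms.
#' `shape = Inf` gives deterministic durations.
#'
#' @param params A [synth_params()].
#' @param total_duration Recording length (s).
#' @param seed RNG seed.
#' @return A [state_segmentation()] tiling `[0, total_duration)` with
#'   alternating `DOWN`/`UP` intervals.
#' @export
generate_states <- function(params, total_duration, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  if (total_duration <= 0) stop("generate_states: total_duration must be > 0")
  set.seed(seed)
  draw <- function(mean, shape, n) {
    if (is.infinite(shape)) rep(mean, n)
    else pmax(stats::rgamma(n, shape = shape, rate = shape / mean), 0.1)
  }
  # draw in blocks until the tiling covers the requested duration
  n_guess <- ceiling(total_duration / (params$up_mean + params$down_mean)) + 10
  starts <- numeric(0); ends <- numeric(0); labs <- character(0)
  t <- 0; lab <- "DOWN"
  while (t < total_duration) {
    n <- max(n_guess, 16)
    d_down <- draw(params$down_mean, params$down_shape, n)
    d_up <- draw(params$up_mean, params$up_shape, n)
    for (i in seq_len(n)) {
      d <- if (lab == "DOWN") d_down[i] else d_up[i]
      starts <- c(starts, t); ends <- c(ends, t + d); labs <- c(labs, lab)
      t <- t + d
      lab <- if (lab == "DOWN") "UP" else "DOWN"
      if (t >= total_duration) break
    }
  }
  ends[length(ends)] <- total_duration
  keep <- ends - starts > 1e-9
  state_segmentation(starts[keep], ends[keep], labs[keep])
}

# raised-cosine (Hann) smoothing kernel of given width in samples
hann_kernel <- function(k) {
  if (k < 2) return(1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  w / sum(w)
}

#' Generate a synthetic LFP from a state sequence
#'
#' Depth-positive baseline in down states and depth-negative in up states
#' (raised-cosine ramps at transitions), band-limited \[10,51\] Hz noise
#' whose SD is `bg_ratio` times larger in up states, and a 1/f background.
#'
#' @param states A [state_segmentation()] tiling the recording.
#' @param params A [synth_params()].
#' @param rate Sampling rate (Hz, >= 300 so the beta/gamma band is
#'   representable).
#' @param seed RNG seed.
#' @return LFP [time_series()].
#' @export
generate_lfp <- function(states, params, rate = 1000, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  if (rate < 300)
    stop("generate_lfp: rate must be >= 300 Hz to represent the [10,51] Hz band")
  set.seed(seed)
  dur <- max(states$end)
  n <- as.integer(round(dur * rate))
  tt <- (seq_len(n) - 1) / rate
  lab <- state_at(states, tt)
  up <- !is.na(lab) & lab == "UP"
  a <- params$delta_amplitude
  level <- ifelse(up, -a, a)
  ramp_on <- params$ramp * (1 + params$delta_asymmetry)
  k <- max(1L, as.integer(round(ramp_on * rate)))
  base <- as.numeric(stats::filter(c(rep(level[1], k), level, rep(level[n], k)),
                                   hann_kernel(k), sides = 2))
  base <- base[(k + 1):(k + n)]
  base[is.na(base)] <- level[is.na(base)]
  out <- base
  if (params$bg_sd_up > 0) {
    wn <- time_series(stats::rnorm(n), rate)
    bl <- fft_bandpass(wn, c(10, 51))$samples
    bl <- bl / stats::sd(bl)
    env <- ifelse(up, params$bg_sd_up, params$bg_sd_up / params$bg_ratio)
    out <- out + bl * env
  }
  if (params$pink_sd > 0) {
    wn <- stats::rnorm(n)
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
    amp <- 1 / sqrt(pmax(abs(f), 0.1))
    pk <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / n
    pk <- pk / stats::sd(pk) * params$pink_sd
    out <- out + pk
  }
  time_series(out, rate, 0, "LFP")
}

# von Mises modulation gain with unit mean under uniform phase
vm_gain <- function(phi, kappa, pref_rad) {
  if (kappa < 1e-12) return(rep(1, length(phi)))
  exp(kappa * (cos(phi - pref_rad) - 1)) / besselI(kappa, 0, expon.scaled = TRUE)
}

# thin a piecewise-constant intensity sampled on a grid
thin_poisson <- function(lambda, rate, duration) {
  lmax <- max(lambda)
  if (lmax <= 0) return(numeric(0))
  if (lmax > 1e4)
    stop("spike intensity exceeds 1e4 spikes/s; reduce coupling gain or rates")
  n_cand <- stats::rpois(1, lmax * duration)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration))
  idx <- pmin(pmax(as.integer(floor(cand * rate)) + 1L, 1L), length(lambda))
  keep <- stats::runif(n_cand) < lambda[idx] / lmax
  cand[keep]
}

#' Generate phase-locked PV and VPM spike trains
#'
#' Inhomogeneous point processes by thinning: the intensity is the state
#' base rate times a unit-mean von Mises phase gain (per-train kappa and
#' preferred phase). With `coupling_gain > 0`, every VPM spike fired in a
#' down state adds a transient Gaussian bump (configured lag and SD;
#' integral `coupling_gain` expected extra PV spikes) to the PV intensity,
#' emulating a causal thalamus-to-PV drive.
#'
#' @param states A [state_segmentation()].
#' @param lfp_phase A `phase_trace` aligned with `states` (typically
#'   [hilbert_phase()] of the generated LFP).
#' @param params A [synth_params()].
#' @param seed RNG seed.
#' @return List with elements `pv` and `vpm`, both [spike_train()]s.
#' @export
generate_spikes <- function(states, lfp_phase, params, seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(seed)
  rate <- lfp_phase$rate
  dur <- max(states$end)
  n <- length(lfp_phase$phase)
  tt <- lfp_phase$t0 + (seq_len(n) - 1) / rate
  lab <- state_at(states, tt)
  base <- function(rup, rdown)
    ifelse(!is.na(lab) & lab == "UP", rup,
           ifelse(!is.na(lab) & lab == "DOWN", rdown, 0))
  # per-state normalization: the mean gain over each state's samples is 1,
  # so the configured state base rates are the realized state rates
  state_norm_gain <- function(kappa, pref_deg) {
    g <- vm_gain(lfp_phase$phase, kappa, deg2rad(pref_deg))
    for (l in c("UP", "DOWN")) {
      in_l <- !is.na(lab) & lab == l
      if (any(in_l)) g[in_l] <- g[in_l] / mean(g[in_l])
    }
    g
  }
  lam_vpm <- base(params$vpm_rate_up, params$vpm_rate_down) *
    state_norm_gain(params$vpm_kappa, params$vpm_pref_deg)
  vpm_t <- thin_poisson(lam_vpm, rate, dur)
  lam_pv <- base(params$pv_rate_up, params$pv_rate_down) *
    state_norm_gain(params$pv_kappa, params$pv_pref_deg)
  if (params$coupling_gain > 0 && length(vpm_t)) {
    in_down <- !is.na(state_at(states, vpm_t)) &
      state_at(states, vpm_t) == "DOWN"
    src <- vpm_t[in_down]
    if (length(src)) {
      half <- as.integer(ceiling(5 * params$coupling_sd * rate))
      bump <- stats::dnorm(seq(-half, half) / rate, sd = params$coupling_sd) *
        params$coupling_gain
      for (s in src) {
        c0 <- as.integer(round((s + params$coupling_lag) * rate)) + 1L
        lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
        if (lo <= hi)
          lam_pv[lo:hi] <- lam_pv[lo:hi] +
            bump[(lo - c0 + half + 1L):(hi - c0 + half + 1L)]
      }
    }
  }
  pv_t <- thin_poisson(lam_pv, rate, dur)
  list(pv = spike_train(unique(pv_t), "PV", dur),
       vpm = spike_train(unique(vpm_t), "VPM", dur))
}

# stereotyped biphasic spike waveform sampled at `rate`; principal peak at 0
spike_waveform <- function(rate, positive_dominant = TRUE) {
  t <- seq(-0.0012, 0.0018, by = 1 / rate)
  w <- exp(-t^2 / (2 * 0.00025^2)) - 0.5 * exp(-(t - 0.0008)^2 / (2 * 0.00035^2))
  if (!positive_dominant) w <- -w
  list(w = w, peak_offset = which.min(abs(t)) - 1L)
}

#' Synthesize juxtasomal and multi-unit voltage traces from spike trains
#'
#' Inserts stereotyped biphasic waveforms (positive-dominant for the
#' juxtasomal trace, negative-dominant for the MUA trace; peak-to-trough
#' under 3 ms, principal peak at the spike time) on Gaussian noise.
#' Amplitudes are configured as multiples of the noise SD
#' (`juxta_amp_mult`, `mua_amp_mult`).
#'
#' @param spikes List with `pv` and `vpm` [spike_train()]s (as returned by
#'   [generate_spikes()]).
#' @param params A [synth_params()].
#' @param rate Sampling rate (Hz; 10 kHz default, matching typical
#'   extracellular digitization).
#' @param seed RNG seed.
#' @return List with `juxta` and `mua` [time_series()].
#' @export
generate_voltage_traces <- function(spikes, params, rate = 10000,
                                    seed = params$seed) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(seed)
  build <- function(train, positive, amp_mult) {
    wl <- 0.003
    if (length(train$times) / train$duration * wl > 0.5)
      stop("generate_voltage_traces: spike rate x waveform length > 0.5 (overlap regime)")
    n <- as.integer(round(train$duration * rate))
    x <- stats::rnorm(n, sd = params$spike_noise_sd)
    wf <- spike_waveform(rate, positive)
    amp <- amp_mult * params$spike_noise_sd
    for (s in train$times) {
      c0 <- as.integer(round(s * rate)) + 1L
      lo <- c0 - wf$peak_offset
      hi <- lo + length(wf$w) - 1L
      if (lo >= 1 && hi <= n) x[lo:hi] <- x[lo:hi] + amp * wf$w
    }
    time_series(x, rate, 0, if (positive) "juxta" else "MUA")
  }
  list(juxta = build(spikes$pv, TRUE, params$juxta_amp_mult),
       mua = build(spikes$vpm, FALSE, params$mua_amp_mult))
}

#' Generate an optogenetic stimulation session
#'
#' Builds a session of 5-s trials with one illumination onset per trial
#' placed at a random position. When an onset falls inside a true down
#' state, a down-to-up transition is inserted at onset + latency, with the
#' latency drawn from the configured distribution (control mode: mean 0.11
#' s; muscimol mode: mean 0.25 s, slowed spontaneous cycle and suppressed
#' down-state PV rate). A stereotyped ~4-ms half-cosine light artifact is
#' added at every onset.
#'
#' @param params A [synth_params()].
#' @param n_trials Number of 5-s trials (>= 1).
#' @param seed RNG seed.
#' @param mode `"control"` or `"muscimol"`.
#' @param rate LFP sampling rate (Hz).
#' @return List with `lfp` ([time_series()]), `protocol`
#'   ([stimulation_protocol()]), and `truth`: the generated
#'   [state_segmentation()] (after evoked-transition insertion) plus a
#'   per-trial data.frame (`trial`, `onset`, `in_down`, `latency`; latency
#'   `NA` when the onset missed a down state or the spontaneous transition
#'   came first).
#' @export
generate_opto_session <- function(params, n_trials, seed = params$seed,
                                  mode = c("control", "muscimol"),
                                  rate = 1000) {
  stopifnot(inherits(params, "synth_params"))
  mode <- match.arg(mode)
  if (n_trials < 1) stop("generate_opto_session: n_trials must be >= 1")
  trial_len <- 5
  p <- params
  if (mode == "muscimol") {
    p$down_mean <- params$down_mean * params$muscimol_down_factor
    p$pv_rate_down <- params$pv_rate_down * params$muscimol_pv_suppression
  }
  total <- n_trials * trial_len
  states <- generate_states(p, total, seed)
  set.seed(seed + 1L)
  onsets <- (seq_len(n_trials) - 1) * trial_len +
    stats::runif(n_trials, 1.0, trial_len - 1.5)
  lat_mean <- if (mode == "control") p$opto_latency_mean else p$muscimol_latency_mean
  lat_sd <- if (mode == "control") p$opto_latency_sd else p$muscimol_latency_sd
  truth <- data.frame(trial = seq_len(n_trials), onset = onsets,
                      in_down = FALSE, latency = NA_real_)
  st <- as.data.frame(states)[, c("start", "end", "label")]
  for (i in seq_len(n_trials)) {
    on <- onsets[i]
    j <- which(st$start <= on & on < st$end)
    if (!length(j) || st$label[j] != "DOWN") next
    truth$in_down[i] <- TRUE
    lat <- max(stats::rnorm(1, lat_mean, lat_sd), 0.02)
    # the labeled boundary marks the LFP ramp midpoint; place it half a
    # ramp after onset + latency so the deflection STARTS at the
    # programmed latency (the quantity the derivative threshold detects)
    tt <- on + lat + p$ramp / 2
    if (tt < st$end[j] - 0.05) {
      # evoked transition: the rest of this down state becomes up state
      nxt <- j + 1
      if (nxt <= nrow(st) && st$label[nxt] == "UP") {
        st$start[nxt] <- tt
        st$end[j] <- tt
      } else {
        st <- rbind(st[seq_len(j - 1), ],
                    data.frame(start = st$start[j], end = tt, label = "DOWN"),
                    data.frame(start = tt, end = st$end[j], label = "UP"),
                    if (j < nrow(st)) st[(j + 1):nrow(st), ])
      }
      truth$latency[i] <- lat
    }
  }
  states2 <- state_segmentation(st$start, st$end, st$label)
  lfp <- generate_lfp(states2, p, rate = rate, seed = seed + 2L)
  # additive light artifact: half-cosine pulse at each onset
  ka <- as.integer(round(p$artifact_dur * rate))
  pulse <- p$artifact_amp * sin(pi * seq_len(ka) / (ka + 1))
  for (on in onsets) {
    c0 <- as.integer(round(on * rate)) + 1L
    hi <- min(length(lfp$samples), c0 + ka - 1L)
    if (c0 <= hi) lfp$samples[c0:hi] <- lfp$samples[c0:hi] + pulse[seq_len(hi - c0 + 1L)]
  }
  list(lfp = lfp,
       protocol = stimulation_protocol(onsets, duration = 0.5),
       truth = list(states = states2, trials = truth, mode = mode))
}

#' Generate a complete synthetic recording session
#'
#' Convenience wrapper tying the generator stages together: states, LFP,
#' slow-oscillation phase, PV/VPM spike trains and (optionally) raw voltage
#' traces.
#'
#' @param params A [synth_params()].
#' @param duration Session length (s).
#' @param seed RNG seed.
#' @param rate LFP working rate (Hz).
#' @param voltage_traces If `TRUE`, also synthesize juxtasomal/MUA voltage
#'   traces at 10 kHz.
#' @return List with `states`, `lfp`, `phase`, `spikes` (list `pv`, `vpm`)
#'   and optionally `voltage` (list `juxta`, `mua`).
#' @export
generate_session <- function(params = synth_params(), duration = 120,
                             seed = params$seed, rate = 1000,
                             voltage_traces = FALSE) {
  states <- generate_states(params, duration, seed)
  lfp <- generate_lfp(states, params, rate = rate, seed = seed + 1L)
  phase <- hilbert_phase(lfp, c(0.1, 4))
  spikes <- generate_spikes(states, phase, params, seed = seed + 2L)
  out <- list(states = states, lfp = lfp, phase = phase, spikes = spikes)
  if (voltage_traces)
    out$voltage <- generate_voltage_traces(spikes, params, seed = seed + 3L)
  out
}
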