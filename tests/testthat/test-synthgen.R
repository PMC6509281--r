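test_that("state generation alternates, tiles, and is seed-deterministic", {
  p <- synth_params()
  s1 <- generate_states(p, 60, seed = 4)
  s2 <- generate_states(p, 60, seed = 4)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  s3 <- generate_states(p, 60, seed = 5)
  expect_false(isTRUE(all.equal(s1$start, s3$start)))
  # tiling: starts meet previous ends exactly, covering [0, 60)
  expect_equal(s1$start[1], 0)
  expect_equal(s1$end[nrow(s1)], 60)
  expect_equal(s1$start[-1], s1$end[-nrow(s1)])
  # strict alternation
  expect_true(all(s1$label[-1] != s1$label[-nrow(s1)]))
  expect_true(all(s1$end - s1$start >= 0.1 - 1e-12))
  expect_error(generate_states(synth_params(up_mean = -1), 10), "> 0")
})

test_that("deterministic durations give exact 1 Hz alternation", {
  p <- synth_params(up_mean = 0.5, down_mean = 0.5,
                    up_shape = Inf, down_shape = Inf)
  s <- generate_states(p, 20, seed = 1)
  expect_equal(nrow(s), 40)
  expect_equal(unique(round(s$end - s$start, 9)), 0.5)
})

test_that("cycle rate of default-shape states lies in the slow-oscillation band", {
  p <- synth_params()  # mean up 0.4 s, mean down 0.6 s
  s <- generate_states(p, 600, seed = 2)
  n_cycles <- sum(s$label == "UP")
  expect_gte(n_cycles, 500)
  freq <- n_cycles / 600
  expect_gte(freq, 0.2)
  expect_lte(freq, 1)
})

test_that("noise-free LFP spans exactly [-A, +A] with the right polarity", {
  p <- synth_params(bg_sd_up = 0, pink_sd = 0, delta_amplitude = 2)
  s <- generate_states(p, 30, seed = 1)
  lfp <- generate_lfp(s, p, rate = 1000, seed = 1)
  expect_equal(max(lfp$samples), 2, tolerance = 1e-6)
  expect_equal(min(lfp$samples), -2, tolerance = 1e-6)
  # depth-positive in down, depth-negative in up (interior samples)
  mids <- (s$start + s$end) / 2
  v <- lfp$samples[round(mids * 1000) + 1]
  expect_true(all(v[s$label == "DOWN"] > 0))
  expect_true(all(v[s$label == "UP"] < 0))
  expect_error(generate_lfp(s, p, rate = 200), ">= 300")
})

test_that("beta/gamma running RMS is higher in up states by the set ratio", {
  # no 1/f background, so the in-band RMS is the state-modulated noise alone
  p <- synth_params(pink_sd = 0)
  ses <- generate_session(p, duration = 120, seed = 7)
  filt <- elliptic_filter(ses$lfp, "band", c(10, 51))
  rms <- running_rms(filt, 0.005)
  tt <- ts_times(ses$lfp)
  lab <- state_at(ses$states, tt)
  # interior samples only: the narrowband filter rings for ~0.2 s around
  # each transition, so stay 250 ms clear of boundaries
  tb <- sort(c(ses$states$start, ses$states$end))
  d2b <- vapply(tt[seq(1, length(tt), by = 3)],
                function(x) min(abs(tb - x)), numeric(1))
  lab3 <- lab[seq(1, length(tt), by = 3)]
  r3 <- rms$samples[seq(1, length(tt), by = 3)]
  interior <- d2b > 0.25
  ratio <- mean(r3[interior & lab3 == "UP"]) /
    mean(r3[interior & lab3 == "DOWN"])
  expect_gt(ratio, 3 * 0.9)
  expect_lt(ratio, 3 * 1.1)
})

test_that("delta phase sits near 180 degrees at up-state midpoints", {
  ses <- fixture_session()
  mids <- with(as.data.frame(ses$states), (start + end) / 2)
  up_mid <- mids[ses$states$label == "UP"]
  ph <- phase_at(ses$phase, up_mid)
  mu <- locking_stats(ph)$preferred_phase_deg
  expect_lt(abs(mu - 180), 15)
})

test_that("realized spike counts match configured state rates", {
  p <- synth_params()
  ses <- fixture_session(duration = 300, seed = 11)
  tl <- segmentation_time_by_label(ses$states)
  for (src in c("pv", "vpm")) {
    tr <- ses$spikes[[src]]
    lab <- state_at(ses$states, tr$times)
    rates <- c(UP = p[[paste0(src, "_rate_up")]],
               DOWN = p[[paste0(src, "_rate_down")]])
    for (l in c("UP", "DOWN")) {
      expected <- rates[[l]] * tl[[l]]
      observed <- sum(lab == l)
      expect_lt(abs(observed - expected), 3 * sqrt(expected) + 1,
                label = sprintf("%s %s count", src, l))
    }
  }
})

test_that("causal coupling produces a VPM-to-PV delay peak at the set lag", {
  ses <- fixture_session(duration = 300, seed = 13, coupling_gain = 1)
  lab_pv <- state_at(ses$states, ses$spikes$pv$times)
  lab_vpm <- state_at(ses$states, ses$spikes$vpm$times)
  pv_d <- ses$spikes$pv$times[lab_pv == "DOWN"]
  vpm_d <- ses$spikes$vpm$times[lab_vpm == "DOWN"]
  # forward delays from each VPM down spike to PV spikes within 60 ms
  del <- unlist(lapply(vpm_d, function(s) {
    d <- pv_d - s
    d[d > 0 & d < 0.06]
  }))
  h <- hist(del, breaks = seq(0, 0.06, by = 0.005), plot = FALSE)
  peak <- h$mids[which.max(h$counts)]
  expect_lt(abs(peak - 0.02), 0.005)
  expect_error(
    generate_spikes(ses$states, ses$phase,
                    synth_params(coupling_gain = 1e6), seed = 1),
    "gain|intensity")
})

test_that("voltage trace synthesis handles edge cases", {
  p <- synth_params()
  empty <- list(pv = spike_train(numeric(0), "PV", 1),
                vpm = spike_train(numeric(0), "VPM", 1))
  v <- generate_voltage_traces(empty, p, rate = 10000, seed = 1)
  expect_lt(abs(sd(v$juxta$samples) - p$spike_noise_sd), 0.05)
  expect_lt(max(abs(v$juxta$samples)), 6 * p$spike_noise_sd)
  dense <- list(pv = spike_train(seq(0.001, 0.999, by = 0.005), "PV", 1),
                vpm = spike_train(numeric(0), "VPM", 1))
  expect_error(generate_voltage_traces(dense, p), "overlap")
})

test_that("opto sessions only insert transitions for onsets in down states", {
  p <- synth_params()
  ses <- generate_opto_session(p, n_trials = 40, seed = 6)
  tr <- ses$truth$trials
  st <- ses$truth$states
  # no latency recorded when the onset fell in an up state
  expect_true(all(is.na(tr$latency[!tr$in_down])))
  # inserted transitions: the labeled boundary is half a ramp after
  # onset + latency
  ins <- tr[!is.na(tr$latency), ]
  for (i in seq_len(nrow(ins))) {
    b <- st$start[st$label == "UP"]
    expect_lt(min(abs(b - (ins$onset[i] + ins$latency[i] + p$ramp / 2))), 1e-9)
  }
  # programmed latency distribution matches the control defaults
  expect_lt(abs(mean(ins$latency) - p$opto_latency_mean),
            4 * p$opto_latency_sd / sqrt(nrow(ins)) + 0.005)
  # muscimol mode: longer programmed latencies
  sesM <- generate_opto_session(p, n_trials = 40, seed = 6, mode = "muscimol")
  latM <- sesM$truth$trials$latency
  expect_gt(mean(latM, na.rm = TRUE), 0.18)
})

test_that("ground truth is internally consistent with emitted traces", {
  ses <- fixture_session()
  expect_true(all(ses$spikes$pv$times < ts_duration(ses$lfp)))
  expect_true(all(ses$spikes$vpm$times >= 0))
  expect_equal(max(ses$states$end), ts_duration(ses$lfp))
  expect_equal(length(ses$phase$phase), length(ses$lfp$samples))
})
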