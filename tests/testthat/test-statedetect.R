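test_that("cosine-method delta evidence hits its analytic extremes", {
  # trace whose delta phase is pinned: pure 1 Hz cosine
  rate <- 1000
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  lfp <- time_series(cos(2 * pi * t), rate)
  e <- delta_evidence(lfp, bands = list(c(0.5, 2)), method = "cosine")
  # phase = 180 deg (trough, t = 0.5 + k): evidence 1; peak: evidence 0
  troughs <- round((seq(5.5, 25.5, by = 1)) * rate) + 1
  peaks <- round(seq(5, 25, by = 1) * rate) + 1
  expect_true(all(e[troughs] > 0.99))
  expect_true(all(e[peaks] < 0.01))
  # analytic method obeys the same extremes
  ea <- delta_evidence(lfp, bands = list(c(0.5, 2)), method = "analytic")
  expect_true(all(ea[troughs] > 0.99))
  expect_true(all(ea[peaks] < 0.01))
  expect_error(delta_evidence(lfp, bands = list()), "empty")
})

test_that("beta/gamma evidence is scale invariant and maps min/p95 to 0/1", {
  ses <- fixture_session()
  e1 <- betagamma_evidence(ses$lfp)
  e2 <- betagamma_evidence(time_series(7.3 * ses$lfp$samples, 1000))
  expect_lt(max(abs(e1 - e2)), 1e-6)
  expect_equal(min(e1), 0)
  expect_equal(max(e1), 1)
  # about 5% of samples sit at the clip value 1
  expect_lt(abs(mean(e1 >= 1 - 1e-12) - 0.05), 0.02)
  expect_error(betagamma_evidence(time_series(rep(1, 20000), 1000)),
               "constant|dynamic")
})

test_that("combined evidence is the exact average and bounded", {
  ses <- fixture_session()
  ev <- evidence_trace(ses$lfp)
  expect_lt(max(abs(ev$s_comb - (ev$s_delta + ev$s_betagamma) / 2)), 1e-12)
  expect_true(all(ev$s_delta >= 0 & ev$s_delta <= 1))
  expect_true(all(ev$s_betagamma >= 0 & ev$s_betagamma <= 1))
  expect_length(ev$s_delta, length(ses$lfp$samples))
})

test_that("three-Gaussian EM recovers known mixture parameters", {
  true_mu <- c(0.15, 0.5, 0.85)
  for (seed in 1:5) {
    set.seed(100 + seed)
    n <- 50000
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
    x <- rnorm(n, true_mu[comp], 0.05)
    fit <- fit_three_gaussians(x, seed = seed, exclude_percentile = 1)
    expect_false(fit$degenerate)
    expect_lt(max(abs(unname(fit$means) - true_mu)), 0.02)
    expect_equal(fit$theta_up, unname(fit$means["UP"] - 2 * fit$sds["UP"]))
    expect_equal(fit$theta_down,
                 unname(fit$means["DOWN"] + 2 * fit$sds["DOWN"]))
  }
  expect_error(fit_three_gaussians(rep(0.5, 20000)), "degenerate")
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(42)
  n <- 30000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.15, 0.4))
  x <- rnorm(n, c(0.2, 0.5, 0.8)[comp], c(0.05, 0.08, 0.06)[comp])
  fit <- fit_three_gaussians(x, seed = 1, exclude_percentile = 1)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(unname(fit$means)) - sort(mc$parameters$mean))),
            0.01)
})

test_that("segmentation applies the merge and minimum-duration rules in order", {
  fit <- structure(list(means = c(DOWN = 0.2, INDET = 0.5, UP = 0.8),
                        sds = c(DOWN = 0.05, INDET = 0.05, UP = 0.05),
                        weights = c(0.4, 0.2, 0.4),
                        theta_up = 0.7, theta_down = 0.3,
                        loglik = 0, n_iter = 1, degenerate = FALSE),
                   class = "gmm_fit")
  rate <- 1000
  # UP(200) INDET(40) UP(200): short INDET gap merged -> single 440-ms UP
  s <- c(rep(0.9, 200), rep(0.5, 40), rep(0.9, 200), rep(0.1, 300))
  seg <- segment_states(s, fit, rate = rate)
  expect_equal(seg$label[1], "UP")
  expect_equal(seg$end[1] - seg$start[1], 0.44)
  # isolated 80-ms UP -> INDET
  s2 <- c(rep(0.1, 300), rep(0.5, 200), rep(0.9, 80), rep(0.5, 200),
          rep(0.1, 300))
  seg2 <- segment_states(s2, fit, rate = rate)
  expect_false("UP" %in% seg2$label)
  # threshold ties go to INDET
  s3 <- c(rep(0.7, 200), rep(0.1, 200))
  seg3 <- segment_states(s3, fit, rate = rate)
  expect_equal(seg3$label[1], "INDET")
  # labels partition every sample
  ses <- fixture_session()
  det <- detect_states(ses$lfp)
  seg4 <- det$segmentation
  expect_equal(seg4$start[-1], seg4$end[-nrow(seg4)])
  expect_equal(max(seg4$end), ts_duration(ses$lfp))
  expect_true(all(with(as.data.frame(seg4),
                       (end - start)[label != "INDET"] >= 0.1 - 1e-9)))
  # degenerate fit refuses to segment
  fitd <- fit; fitd$degenerate <- TRUE
  expect_error(segment_states(s, fitd, rate = rate), "degenerate")
})

test_that("segmentation is invariant to affine rescaling of the LFP", {
  ses <- fixture_session()
  det1 <- detect_states(ses$lfp)
  scaled <- time_series(4.2 * ses$lfp$samples + 0.7, 1000)
  det2 <- detect_states(scaled)
  # the evidence is exactly scale invariant (asserted above at 1e-6); the
  # mixture fit conditions on it with finite precision, so labels agree
  # nearly -- not bit-wise -- everywhere
  tt <- ts_times(ses$lfp)
  l1 <- state_at(det1$segmentation, tt)
  l2 <- state_at(det2$segmentation, tt)
  expect_gt(mean(l1 == l2, na.rm = TRUE), 0.95)
})

test_that("state metrics compute fractions, active ratios and counts", {
  seg <- state_segmentation(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9),
                            c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                            rep(c("UP", "DOWN"), 5))
  # all spikes in UP intervals
  tr <- spike_train(c(0.5, 2.5, 4.5), "PV", 10)
  m <- state_metrics(seg, tr)
  expect_equal(unname(m$trains[[1]]$fractions), c(1, 0, 0))
  # 3 active DOWN states of 5, 5 spikes total in them
  tr2 <- spike_train(c(1.1, 1.2, 3.5, 5.5, 5.9), "VPM", 10)
  m2 <- state_metrics(seg, tr2)
  expect_equal(unname(m2$trains[[1]]$active_ratio["DOWN"]), 3 / 5)
  expect_equal(unname(m2$trains[[1]]$mean_spikes_per_active["DOWN"]), 5 / 3)
  expect_equal(m2$up_state_freq, 0.5)
  # homogeneous Poisson spikes split by label time fractions
  set.seed(9)
  ses <- fixture_session()
  n <- 2000
  hp <- spike_train(sort(runif(n, 0, 119.99)), "OTHER", 120)
  mh <- state_metrics(ses$states, hp)
  tl <- segmentation_time_by_label(ses$states)
  fr <- tl / sum(tl)
  for (l in c("UP", "DOWN")) {
    se <- sqrt(fr[[l]] * (1 - fr[[l]]) / n)
    expect_lt(abs(mh$trains[[1]]$fractions[[l]] - fr[[l]]), 3 * se + 1e-6)
  }
})

test_that("evoked rate change counts pre/post windows correctly", {
  # burst of 3 spikes 10-50 ms after each onset, silence before
  onsets <- c(1, 2, 3)
  tms <- sort(c(onsets + 0.01, onsets + 0.03, onsets + 0.05))
  tr <- spike_train(tms, "VPM", 5)
  r <- evoked_rate_change(tr, onsets, window = 0.1)
  expect_equal(r$per_onset$pre_rate, c(0, 0, 0))
  expect_equal(r$per_onset$post_rate, c(30, 30, 30))
  empty <- evoked_rate_change(spike_train(numeric(0), "VPM", 5), onsets)
  expect_equal(empty$summary$mean_pre, 0)
  expect_equal(empty$summary$mean_post, 0)
  # homogeneous train: no systematic pre/post difference
  set.seed(10)
  pvals <- replicate(20, {
    hp <- spike_train(sort(runif(3000, 0, 100)), "VPM", 100)
    ons <- seq(5, 95, by = 3)
    evoked_rate_change(hp, ons)$summary$wilcoxon_p
  })
  expect_gte(sum(pvals > 0.05), 19 - 2)
})
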