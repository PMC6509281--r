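test_that("spike-triggered IFR aligns, averages, and handles edge cases", {
  set.seed(15)
  tms <- sort(runif(150, 1, 59))
  tms <- tms[c(TRUE, diff(tms) > 1e-3)]
  tr <- spike_train(tms, "VPM", 60)
  ifr <- kernel_ifr(tr, 0.0125, 1000)
  # self-alignment: peak at lag 0 of about kernel peak + baseline
  curve <- spike_triggered_ifr(ifr, tr$times, window = 0.2)
  mid <- which(curve$lag == 0)
  expect_equal(which.max(curve$mean), mid)
  expect_gt(curve$mean[mid], stats::dnorm(0, sd = 0.0125) * 0.9)
  # single usable trigger: mean equals the segment, SEM 0
  one <- spike_triggered_ifr(ifr, tr$times[5], window = 0.2)
  expect_true(all(one$sem == 0))
  expect_equal(one$n_triggers, 1)
  # triggers independent of a homogeneous train: flat curve at mean rate
  set.seed(16)
  hp <- spike_train(sort(runif(1200, 0, 120)), "VPM", 120)
  ifr_h <- kernel_ifr(hp, 0.0125, 1000)
  trig <- seq(2, 118, by = 0.5)
  fl <- spike_triggered_ifr(ifr_h, trig, window = 0.3)
  expect_true(all(abs(fl$mean - 10) <= 3 * pmax(fl$sem, 1e-6) + 1))
  # edge triggers are dropped and counted
  dr <- spike_triggered_ifr(ifr, c(0.05, 30), window = 0.2)
  expect_equal(dr$n_dropped, 1)
  expect_error(spike_triggered_ifr(ifr, 0.01, window = 0.2), "usable")
})

test_that("surrogate ensembles respect all stated constraints", {
  ses <- fixture_session()
  ens <- generate_surrogates(ses$states, ses$spikes$pv, ses$phase,
                             n_surrogates = 50, seed = 1)
  seg <- ses$states
  iv <- interval_at(seg, ses$spikes$pv$times)
  down_rows <- which(seg$label == "DOWN")
  real_dn <- ses$spikes$pv$times[!is.na(iv) & iv %in% down_rows]
  active <- unique(iv[!is.na(iv) & iv %in% down_rows])
  for (s in ens$sets) {
    expect_length(s, ens$n_real)
    siv <- interval_at(seg, s)
    # every surrogate spike sits in a PV-silent DOWN state
    expect_true(all(seg$label[siv] == "DOWN"))
    expect_false(any(siv %in% active))
    # per-state cap and state-count cap
    expect_lte(max(table(siv)), ens$max_per_state)
    expect_lte(length(unique(siv)), ens$n_states_real)
  }
  expect_equal(length(real_dn), ens$n_real)
  # pooled surrogate phases match the real down-state spike phases
  real_ph <- phase_at(ses$phase, real_dn)
  pool <- phase_at(ses$phase, unlist(ens$sets[1:10]))
  ks <- suppressWarnings(ks.test(pool, real_ph))
  expect_gt(ks$p.value, 0.05)
})

test_that("surrogate z-scores and normalized variation follow definitions", {
  surr <- c(1, 2, 3, 4, 5)
  z <- surrogate_zscore(3, 3, surr, surr)
  expect_equal(z$z_pre, 0)
  expect_equal(z$p_pre, 0.5)
  expect_error(surrogate_zscore(1, 1, rep(2, 10), rep(2, 10)), "zero")
  expect_equal(unname(normalized_variation(4, 2, 4)), c(0, -50))
  expect_equal(unname(normalized_variation(8, 0, 4)), c(100, -100))
  expect_error(normalized_variation(1, 1, 0), "> 0")
})

test_that("pre/post comparison is time-reversal symmetric", {
  set.seed(17)
  tms <- sort(runif(500, 0.5, 59.5))
  tr <- spike_train(tms, "VPM", 60)
  ifr <- kernel_ifr(tr, 0.0125, 1000)
  trig <- seq(1, 59, by = 0.8)
  fwd <- prepost_rates(ifr, trig, 0.1)
  # reverse the recording: spikes and triggers mirrored around 60 s
  rev_tr <- spike_train(sort(60 - tms), "VPM", 60)
  ifr_r <- kernel_ifr(rev_tr, 0.0125, 1000)
  rev <- prepost_rates(ifr_r, sort(60 - trig), 0.1)
  rev_sorted <- rev[order(-rev$trigger), ]
  expect_equal(fwd$pre, rev_sorted$post, tolerance = 0.05)
  expect_equal(fwd$post, rev_sorted$pre, tolerance = 0.05)
  # calibration: independent homogeneous data give uniform two-sided p
  set.seed(18)
  ps <- replicate(60, {
    hp <- spike_train(sort(runif(600, 0, 60)), "VPM", 60)
    ifr_h <- kernel_ifr(hp, 0.0125, 1000)
    tg <- runif(40, 1, 59)
    pre_post_comparison(ifr_h, tg, alternative = "two.sided")$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.05)
})

test_that("causal coupling yields pre-spike VPM excess", {
  ses <- fixture_session(duration = 300, seed = 13, coupling_gain = 1)
  res <- sta_analysis(ses$states, ses$spikes$pv, ses$spikes$vpm, ses$phase,
                      seed = 5)
  expect_gt(res$real$pre, res$real$post)
  expect_lt(res$z$p_pre, 0.05)
  expect_lt(res$wilcoxon$p, 0.05)
  # the excess peaks before the trigger near the programmed lag
  curve <- res$real$curve
  surr_mean <- res$surrogate$overall_mean
  excess <- curve$mean - surr_mean
  pk_lag <- curve$lag[which.max(excess)]
  expect_lt(pk_lag, 0)
  expect_lt(abs(-pk_lag - 0.02), 0.03)
})

test_that("BH procedure matches an exhaustive step-up oracle", {
  # oracle: largest k with p_(k) <= k alpha / m by direct enumeration
  oracle <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * alpha / m)
    rej <- rep(FALSE, m)
    if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
    rej
  }
  expect_equal(fdr_bh(c(0.001, 0.02, 0.04))$rejected, rep(TRUE, 3))
  expect_equal(fdr_bh(rep(1, 5))$rejected, rep(FALSE, 5))
  expect_true(fdr_bh(0.04)$rejected)
  grid <- c(0.001, 0.01, 0.04, 0.2, 0.5, 0.9)
  set.seed(19)
  for (i in 1:50) {
    p <- sample(grid, 8, replace = TRUE)
    expect_equal(fdr_bh(p)$rejected, oracle(p, 0.05))
    expect_equal(fdr_bh(p)$adjusted, p.adjust(p, "BH"))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("binomial tail reproduces printed combination-test values", {
  expect_equal(signif(binomial_tail(18, 11, 0.05), 3), 1.12e-10)
  expect_equal(round(binomial_tail(18, 2, 0.05), 4), 0.2265)
  expect_equal(round(binomial_tail(18, 3, 0.05), 4), 0.0581)
  expect_equal(binomial_tail(18, 0, 0.05), 1)
  expect_equal(binomial_tail(5, 5, 0.5), 0.03125)
  expect_error(binomial_tail(5, 6, 0.5), "k <= n")
  # brute-force mass summation oracle for all n <= 25
  for (n in 1:25) {
    for (k in c(0, 1, n %/% 2, n)) {
      brute <- sum(choose(n, k:n) * 0.05^(k:n) * 0.95^(n - (k:n)))
      expect_lt(abs(binomial_tail(n, k, 0.05) - brute) / max(brute, 1e-300),
                1e-12)
    }
  }
})
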