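test_that("CDF rescaling uniformizes phases and centers the median", {
  ses <- fixture_session()
  # rescaled all-sample distribution is uniform
  resc <- rescale_phases(ses$phase)
  sub <- resc[seq(1, length(resc), by = 41)]
  expect_gt(suppressWarnings(ks.test(sub, "punif", -pi, pi)$p.value), 0.05)
  # phase at the trace median maps to 0
  med <- median(ses$phase$phase)
  expect_lt(abs(rescale_phases(ses$phase, med)), 0.01)
  # already-uniform trace: rescaling is near identity
  set.seed(11)
  unif <- structure(list(phase = runif(20000, -pi, pi), rate = 1000, t0 = 0,
                         band = c(0.1, 4)), class = "phase_trace")
  q <- seq(-3, 3, by = 0.5)
  expect_lt(max(abs(rescale_phases(unif, q) - q)), 2 * pi / sqrt(20000) * 3)
  expect_error(rescale_phases(structure(list(phase = numeric(0)),
                                        class = "phase_trace")), "empty")
})

test_that("Rayleigh test matches its closed form at the extremes", {
  r0 <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_lt(r0$r_bar, 1e-12)
  expect_gt(r0$p, 0.99)
  r1 <- rayleigh_test(rep(1.2, 50))
  expect_lt(r1$p, 1e-10)
  expect_error(rayleigh_test(0.5), "at least 2")
  # power: von Mises kappa = 1.4, n = 200 rejects at 0.01 almost always
  rej <- vapply(1:20, function(s) {
    set.seed(s)
    rayleigh_test(rvonmises(200, 0, 1.4))$p < 0.01
  }, logical(1))
  expect_gte(sum(rej), 19)
})

test_that("locking statistics match hand-computed cases and rotate", {
  l1 <- locking_stats(rep(pi / 2, 10))
  expect_equal(l1$preferred_phase_deg, 90)
  expect_equal(l1$locking_strength, 1)
  l2 <- locking_stats(c(0, pi / 2))
  expect_equal(l2$preferred_phase_deg, 45)
  expect_equal(l2$locking_strength, sqrt(2) / 2)
  l3 <- locking_stats(c(350, 10) * pi / 180)
  expect_lt(min(l3$preferred_phase_deg, 360 - l3$preferred_phase_deg), 1e-9)
  expect_equal(l3$locking_strength, cos(10 * pi / 180))
  # rotation equivariance
  set.seed(12)
  a <- rvonmises(500, 1, 2)
  base <- locking_stats(a)
  rot <- locking_stats(a + 0.7)
  expect_lt(abs(rot$locking_strength - base$locking_strength), 1e-12)
  expect_lt(abs((rot$preferred_phase_deg - base$preferred_phase_deg) %% 360 -
                  0.7 * 180 / pi), 1e-9)
})

test_that("von Mises fitting inverts kappa and recovers parameters", {
  # uniform grid -> kappa ~ 0
  grid <- seq(-pi, pi - 1e-6, length.out = 360)
  expect_lt(fit_von_mises(grid)$kappa, 0.02)
  # Newton inversion vs grid search for A1(kappa) = 0.5
  kg <- seq(0.5, 2, by = 1e-5)
  k_grid <- kg[which.min(abs(slowstates:::vm_a1(kg) - 0.5))]
  # build a sample with exact resultant 0.5 via two opposed clusters is
  # fiddly; instead check the solver output against the grid oracle
  set.seed(13)
  a <- rvonmises(100000, 0, 1.1593)
  fit <- fit_von_mises(a)
  expect_lt(abs(fit$kappa - k_grid), 0.02)
  expect_lt(abs(k_grid - 1.1593), 1e-3)
  # recovery at the published concentration
  set.seed(14)
  a2 <- rvonmises(5000, 188 * pi / 180, 1.38)
  f2 <- fit_von_mises(a2)
  expect_lt(abs(f2$mu_deg - 188), 5)
  expect_lt(abs(f2$kappa - 1.38), 0.15)
})

test_that("phase locking summary is coherent on a synthetic session", {
  ses <- fixture_session()
  pl <- phase_locking(ses$phase, ses$spikes$pv)
  expect_equal(sum(pl$histogram$density), 1)
  expect_true(pl$locking_strength >= 0 && pl$locking_strength <= 1)
  expect_lt(pl$rayleigh_p, 0.01)
  expect_lte(pl$von_mises$kappa, 1e3)
  # PV locks more strongly than VPM under the default concentrations
  pl_vpm <- phase_locking(ses$phase, ses$spikes$vpm)
  expect_gt(pl$locking_strength, pl_vpm$locking_strength)
})

test_that("homogeneous Poisson spikes show no phase locking after rescaling", {
  ses <- fixture_session()
  rej <- vapply(1:40, function(s) {
    set.seed(300 + s)
    hp <- spike_train(sort(runif(300, 0, 119.99)), "OTHER", 120)
    phase_locking(ses$phase, hp)$rayleigh_p <= 0.01
  }, logical(1))
  expect_lte(mean(rej), 0.05)
})

test_that("state-restricted distributions respect ranges and relative time", {
  ses <- fixture_session()
  # spikes exactly at interval midpoints -> relative time 0.5
  ups <- as.data.frame(ses$states)
  ups <- ups[ups$label == "UP", ]
  mids <- (ups$start + ups$end) / 2
  tr <- spike_train(mids, "PV", 120)
  d <- state_restricted_distribution(ses$states, ses$phase, tr, "UP")
  expect_false(d$empty)
  expect_true(all(abs(d$relative_time - 0.5) < 1e-9))
  expect_equal(d$median_relative_time, 0.5)
  # wrap rule for the down range [295, 75]
  expect_true(slowstates:::in_circular_range(350, c(295, 75)))
  expect_true(slowstates:::in_circular_range(10, c(295, 75)))
  expect_false(slowstates:::in_circular_range(200, c(295, 75)))
  # uniform-in-time down spikes give a flat relative-time histogram when the
  # full phase circle is kept (the percentile phase trim clips state edges,
  # which in these synthetic sessions are tightly phase-locked)
  chi_ok <- vapply(1:20, function(s) {
    set.seed(400 + s)
    dn <- as.data.frame(ses$states)
    dn <- dn[dn$label == "DOWN" & (dn$end - dn$start) > 0.2, ]
    tms <- sort(unlist(mapply(function(a, b) runif(8, a, b - 1e-6),
                              dn$start, dn$end, SIMPLIFY = FALSE)))
    tr2 <- spike_train(tms, "PV", 120)
    dd <- state_restricted_distribution(ses$states, ses$phase, tr2, "DOWN",
                                        range_deg = c(0, 359.999),
                                        n_bins = 5)
    cnt <- dd$time_hist$density * dd$n_spikes
    suppressWarnings(chisq.test(cnt)$p.value) > 0.05
  }, logical(1))
  expect_gte(sum(chi_ok), 18)
  # with the default trimmed range the median relative time stays central
  set.seed(431)
  dn <- as.data.frame(ses$states)
  dn <- dn[dn$label == "DOWN" & (dn$end - dn$start) > 0.2, ]
  tms <- sort(unlist(mapply(function(a, b) runif(8, a, b - 1e-6),
                            dn$start, dn$end, SIMPLIFY = FALSE)))
  dd <- state_restricted_distribution(ses$states, ses$phase,
                                      spike_train(tms, "PV", 120), "DOWN")
  expect_lt(abs(dd$median_relative_time - 0.5), 0.1)
  # no spikes in state -> flagged empty
  none <- spike_train(numeric(0), "PV", 120)
  expect_error(phase_locking(ses$phase, none), "empty")
  lone <- spike_train(1e-4, "PV", 120)
  de <- state_restricted_distribution(ses$states, ses$phase, lone, "UP")
  expect_true(de$empty || de$n_spikes <= 1)
})
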