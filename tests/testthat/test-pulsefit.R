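test_that("decay histogram construction conserves counts", {
  h <- build_decay(c(0.1, 0.1, 0.2, 0.3), bin_width_ps = 100,
                   pulse_period_ns = 12.5)
  expect_equal(sum(h$counts), 4)
  expect_equal(h$counts[2:4], c(2L, 1L, 1L))       # bins starting 100/200/300 ps
  expect_error(build_decay(numeric(0)), "empty")
  expect_error(build_decay(13), "pulse_period")
  # all photons in one bin
  h1 <- build_decay(rep(5.001, 10), bin_width_ps = 25)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(max(h1$counts), 10)
})

test_that("amplitude-weighted average lifetime behaves as a weighted mean", {
  expect_equal(tau_av(c(0.4, 1.8), c(0.5, 0.5)), 1.1)
  expect_equal(tau_av(c(1.8, 0.4), c(0.5, 0.5)), 1.1)  # order-invariant
  expect_equal(tau_av(2.3, 1), 2.3)                    # mono
  expect_error(tau_av(c(1, 2), 1), "length")
})

test_that("noiseless model data is recovered to numerical precision", {
  irf <- irf_gaussian(0.2, 1.0)
  h <- build_decay(simulate_decay_photons(1000, 1.8, seed = 1))
  mu <- switchprint:::.decay_model_counts(h, taus = c(0.5, 2.2),
                                          amps = c(3e5, 7e5), t0 = 1.0,
                                          sigma = irf$sigma_ns, bg_per_bin = 2)
  h$counts <- mu
  h$total <- round(sum(mu))
  fit <- fit_decay(h, irf, 2)
  expect_equal(fit$components$tau_ns, c(0.5, 2.2), tolerance = 1e-3)
  expect_equal(fit$components$amplitude, c(0.3, 0.7), tolerance = 1e-3)
  expect_equal(fit$t0_ns, 1.0, tolerance = 1e-3)
  expect_lt(fit$chi2_red, 1e-6)
})

test_that("mono- and biexponential decays are recovered from photon noise", {
  irf <- irf_gaussian(0.2, 1.0)
  mt <- simulate_decay_photons(3e5, 1.8, irf = irf, seed = 4)
  f1 <- fit_decay(build_decay(mt), irf, 1)
  expect_equal(f1$components$tau_ns, 1.8, tolerance = 0.02)
  expect_gt(f1$chi2_red, 0.8)
  expect_lt(f1$chi2_red, 1.2)
  expect_equal(f1$tau_av_ns, f1$components$tau_ns)     # tau_av = tau1 for mono
  mt2 <- simulate_decay_photons(3e5, c(0.4, 1.8), c(0.4, 0.6), irf = irf,
                                seed = 5)
  f2 <- fit_decay(build_decay(mt2), irf, 2)
  expect_equal(f2$components$tau_ns, c(0.4, 1.8), tolerance = 0.1)
  expect_equal(f2$components$amplitude, c(0.4, 0.6), tolerance = 0.15)
  expect_equal(sum(f2$components$amplitude), 1)
})

test_that("reduced chi-square is calibrated on Poisson-resampled model data", {
  irf <- irf_gaussian(0.2, 1.0)
  h0 <- build_decay(simulate_decay_photons(1000, 1.8, seed = 2))
  mu <- switchprint:::.decay_model_counts(h0, 1.8, 4e5, 1.0, irf$sigma_ns, 3)
  set.seed(8)
  chis <- vapply(1:40, function(i) {
    h <- h0
    h$counts <- stats::rpois(length(mu), mu)
    h$total <- sum(h$counts)
    fit_decay(h, irf, 1)$chi2_red
  }, 0)
  expect_gt(mean(chis), 0.9)
  expect_lt(mean(chis), 1.1)
})

test_that("a biexponential fit of a truly mono decay returns the mono lifetime", {
  irf <- irf_gaussian(0.2, 1.0)
  mt <- simulate_decay_photons(2e5, 1.8, irf = irf, seed = 6)
  f2 <- fit_decay(build_decay(mt), irf, 2)
  expect_equal(f2$tau_av_ns, 1.8, tolerance = 0.05)
})

test_that("automatic model selection distinguishes mono from bi decays", {
  irf <- irf_gaussian(0.2, 1.0)
  f_mono <- fit_decay(build_decay(simulate_decay_photons(2e5, 1.8, irf = irf,
                                                         seed = 7)),
                      irf, "auto")
  expect_equal(f_mono$selected_model, "mono")
  f_bi <- fit_decay(build_decay(
    simulate_decay_photons(5e5, c(0.4, 1.8), c(0.5, 0.5), irf = irf,
                           seed = 8)), irf, "auto")
  expect_equal(f_bi$selected_model, "bi")
})

test_that("components below twice the bin width are flagged unresolvable", {
  irf <- irf_gaussian(0.2, 1.0)
  h <- build_decay(simulate_decay_photons(1000, 1.8, seed = 9))
  mu <- switchprint:::.decay_model_counts(h, c(0.04, 1.8), c(3e5, 7e5), 1.0,
                                          irf$sigma_ns, 1)
  h$counts <- mu
  h$total <- round(sum(mu))
  fit <- fit_decay(h, irf, 2)
  expect_true(fit$components$unresolvable[1])
  expect_false(fit$components$unresolvable[2])
})

test_that("fast FLIM lifetime is the mean arrival time minus the IRF origin", {
  mt <- simulate_decay_photons(3e4, 2.0, irf = irf_gaussian(0.2, 1.0),
                               pulse_period_ns = 50, seed = 10)
  expect_equal(flim_fast_lifetime(mt, irf_t0 = 1.0), 2.0, tolerance = 0.03)
  expect_equal(flim_fast_lifetime(1.0, irf_t0 = 1.0), 0)   # single photon at t0
  est <- flim_fast_lifetime(list(px1 = rep(2, 20), px2 = 3.0),
                            irf_t0 = 1.0, min_photons = 5)
  expect_equal(unname(est), c(1, NA))
})
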