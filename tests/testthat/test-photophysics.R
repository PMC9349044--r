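test_that("Forster transfer rate follows the r^-6 law", {
  expect_equal(et_rate(4, 4, 1.8), 1 / 1.8)
  expect_equal(et_rate(2, 4, 1), 64)
  r <- seq(1, 20, by = 0.5)
  expect_true(all(diff(et_rate(r, 4.5, 1.8)) < 0))
  expect_error(et_rate(-1, 4, 1.8), "r must be")
  expect_error(et_rate(3, 0, 1.8), "R0 must be")
  expect_error(et_rate(3, 4, 0), "tau0 must be")
})

test_that("quenched lifetime and FRET efficiency are mutually consistent", {
  expect_equal(quenched_lifetime(1.8, 1 / 1.8), 0.9)
  expect_equal(quenched_lifetime(1.8, numeric(0)), 1.8)
  expect_equal(quenched_lifetime(1.8, 2 / 1.8), 0.6)
  # 1 - tau/tau0 == R0^6/(R0^6 + r^6) for a single acceptor
  for (r in c(2, 4, 4.5, 7)) {
    tau_q <- quenched_lifetime(1.8, et_rate(r, 4.5, 1.8))
    expect_equal(1 - tau_q / 1.8, fret_efficiency(r, 4.5))
  }
  expect_equal(fret_efficiency(4.5, 4.5), 0.5)
  # strictly decreasing in the summed rate
  taus <- vapply(c(0, 0.5, 1, 2, 5), function(k) quenched_lifetime(1.8, k), 0)
  expect_true(all(diff(taus) < 0))
})

test_that("rate constants are validated", {
  rc <- rate_constants()
  expect_s3_class(rc, "rate_constants")
  expect_equal(tau0_ns(rc), 1.8)
  expect_error(rate_constants(cis_lifetime = 0), "must be > 0")
  expect_error(rate_constants(isc_yield = -0.1), "must be >= 0")
  expect_error(rate_constants(trans_to_cis_yield = 1.5), "must be <= 1")
  expect_error(rate_constants(trans_to_cis_yield = 0.5, off_switch_yield = 0.4,
                              isc_yield = 0.2),
               "branching yields")
  expect_error(rate_constants(recovery_delay = -1), "recovery_delay")
})

test_that("excitation rate from intensity has the right magnitude", {
  k <- excitation_rate_from_intensity(5)
  expect_gt(k, 1e7)
  expect_lt(k, 2e7)
  expect_equal(excitation_rate_from_intensity(0), 0)
})

test_that("emitter geometry builds a valid distance matrix", {
  g <- emitter_geometry(rbind(c(0, 0), c(3, 0), c(3, 4)))
  d <- g$pairwise_distances
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d[1, 2], 3)
  expect_equal(d[1, 3], 5)
  # triangle inequality
  expect_lte(d[1, 3], d[1, 2] + d[2, 3])
  expect_error(emitter_geometry(rbind(c(0, 0), c(0, 0))), "coincident")
})

test_that("joint transition rates enumerate the coupled state space", {
  rc <- rate_constants()
  g2 <- emitter_geometry(rbind(c(0, 0), c(3, 0)))
  et <- energy_transfer_config()
  # all bleached: absorbing, no transitions
  expect_equal(nrow(joint_transition_rates(c("BLEACHED", "BLEACHED"), rc, g2,
                                           et)), 0)
  # zero excitation: a lone ON fluorophore has no photo-driven channels
  rc0 <- rate_constants(excitation_rate = 0)
  tr0 <- joint_transition_rates("ON", rc0, single_fluor(), et)
  expect_equal(nrow(tr0), 0)
  # unknown label
  expect_error(joint_transition_rates(c("ON", "GHOST"), rc, g2, et),
               "unknown state")
  # targets are valid states
  tr <- joint_transition_rates(c("ON", "OFF"), rc, g2, et)
  expect_true(all(tr$target_state %in% c("ON", "CIS", "TRIPLET", "OFF",
                                         "BLEACHED")))
  expect_true(all(tr$rate > 0))
})

test_that("ET-mediated recovery rate scales as (r2/r1)^6 between distances", {
  rc <- rate_constants()
  et <- energy_transfer_config()
  rate_at <- function(r) {
    g <- emitter_geometry(rbind(c(0, 0), c(r, 0)))
    tr <- joint_transition_rates(c("ON", "OFF"), rc, g, et)
    tr$rate[tr$fluorophore == 2] - rc$photoactivation_rate
  }
  expect_equal(rate_at(3) / rate_at(18), (18 / 3)^6, tolerance = 1e-10)
})

test_that("cis steady-state occupancy reproduces the configured equilibrium", {
  # two-state trans/cis subsystem: equilibrium fraction from the rate balance
  rc <- rate_constants(off_switch_yield = 0, bleach_yield = 0, isc_yield = 0)
  k_tc <- rc$excitation_rate * rc$trans_to_cis_yield
  k_ct <- 1 / rc$cis_lifetime + rc$excitation_rate * rc$cis_to_trans_photoyield
  f_expected <- k_tc / (k_tc + k_ct)
  expect_equal(f_expected, 0.5, tolerance = 0.01)  # paper-style equilibrium
  res <- simulate_trajectory(rc, single_fluor(), no_energy_transfer(), 5,
                             seed = 21, photons = FALSE)
  sp <- res$state_path
  tb <- c(0, sp$time_s, res$duration)
  st <- c("ON", sp$state)
  f_sim <- sum(diff(tb)[st == "CIS"]) / res$duration
  expect_equal(f_sim, f_expected, tolerance = 0.02)
})
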