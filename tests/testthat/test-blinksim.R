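test_that("simulation is deterministic under a seed", {
  rc <- fast_rates()
  g <- template_geometry("origami_6nm")
  a <- simulate_trajectory(rc, g, energy_transfer_config(), 30, seed = 4)
  b <- simulate_trajectory(rc, g, energy_transfer_config(), 30, seed = 4)
  expect_identical(a$state_path, b$state_path)
  expect_identical(a$photons, b$photons)
})

test_that("zero excitation yields no photons and no photo-driven events", {
  rc <- rate_constants(excitation_rate = 0)
  sim <- sim_settings(background_rate = 0)
  res <- simulate_trajectory(rc, single_fluor(), no_energy_transfer(), 5,
                             seed = 1, sim = sim)
  expect_equal(nrow(res$state_path), 0)
  expect_equal(nrow(res$photons), 0)
  expect_error(simulate_trajectory(rc, single_fluor(), no_energy_transfer(),
                                   -1), "duration")
})

test_that("state path is valid: increasing times, absorbing bleach", {
  rc <- fast_rates(bleach_yield = 1e-5)
  g <- template_geometry("origami_3nm")
  res <- simulate_trajectory(rc, g, energy_transfer_config(), 120, seed = 8,
                             photons = FALSE)
  sp <- res$state_path
  expect_true(all(diff(sp$time_s) > 0))
  expect_true(all(sp$state %in% c("ON", "CIS", "TRIPLET", "OFF", "BLEACHED",
                                  "PRIMED")))
  for (j in 1:4) {
    st_j <- sp$state[sp$fluorophore == j]
    bl <- which(st_j == "BLEACHED")
    if (length(bl)) expect_equal(bl, length(st_j))  # nothing after bleach
  }
})

test_that("photons are emitted only during ON dwells of their emitter", {
  rc <- fast_rates()
  res <- simulate_trajectory(rc, single_fluor(), no_energy_transfer(), 20,
                             seed = 3, sim = sim_settings(background_rate = 0))
  sp <- res$state_path
  tb <- c(0, sp$time_s, res$duration) * 1e9
  st <- c("ON", sp$state)
  idx <- findInterval(res$photons$macrotime_ns, tb,
                      rightmost.closed = FALSE)
  expect_true(all(st[idx] == "ON"))
  # microtimes quantized to the configured resolution, within the period
  expect_true(all(res$photons$microtime_ps %% 25 == 0))
  expect_true(all(res$photons$microtime_ps >= 0 &
                    res$photons$microtime_ps < 12.5 * 1000))
})

test_that("off-dwell durations are exponential with the photoactivation rate", {
  rc <- fast_rates()
  dw <- pooled_off_dwells(45, 400, rc)
  expect_gte(length(dw), 500)
  ks <- stats::ks.test(dw, "pexp", rc$photoactivation_rate)
  expect_gt(ks$p.value, 0.01)
})

test_that("on-event count matches the bleach/off-switch branching mean", {
  # manifold visits until bleach are geometric: mean = 1 + y_off/y_bleach
  rc <- fast_rates(bleach_yield = 1.667e-5 / 2)
  m_expected <- 1 + rc$off_switch_yield / rc$bleach_yield
  counts <- vapply(1:800, function(s) {
    res <- simulate_trajectory(rc, single_fluor(), no_energy_transfer(), 120,
                               seed = 9000 + s, photons = FALSE)
    sp <- res$state_path
    if (!any(sp$state == "BLEACHED")) return(NA_real_)
    sum(sp$state == "OFF") + 1
  }, 0)
  counts <- counts[!is.na(counts)]
  expect_gt(length(counts), 700)
  expect_equal(mean(counts), m_expected, tolerance = 0.05)
})

test_that("disabling energy transfer makes blinking independent of geometry", {
  rc <- fast_rates()
  sim <- sim_settings(background_rate = 0)
  out <- lapply(c("origami_3nm", "origami_18nm"), function(tpl) {
    res <- simulate_trajectory(rc, template_geometry(tpl),
                               no_energy_transfer(), 60, seed = 13, sim = sim)
    res
  })
  # identical event structure and photon times; only positions differ
  expect_identical(out[[1]]$state_path, out[[2]]$state_path)
  expect_identical(out[[1]]$photons$macrotime_ns, out[[2]]$photons$macrotime_ns)
})

test_that("telegraph simulator has consistent dwells and photon counts", {
  tg <- simulate_telegraph(50, k_on = 2, k_off = 20, photon_rate = 1e4,
                           seed = 6)
  expect_true(all(tg$photons$macrotime_ns >= 0 &
                    tg$photons$macrotime_ns <= 50e9))
  expect_true(!is.unsorted(tg$photons$macrotime_ns))
  # mean dwells near 1/k
  expect_equal(mean(tg$off_dwells), 1 / 2, tolerance = 0.25)
  expect_equal(mean(tg$on_dwells), 1 / 20, tolerance = 0.25)
  # photon count ~ rate x total on time
  total_on <- sum(tg$on_dwells)
  expect_equal(nrow(tg$photons), 1e4 * total_on, tolerance = 0.15)
})

test_that("pulsed emitter streams respect the one-photon-per-pulse limit", {
  ph <- simulate_pulsed_emitters(5e4, 3, p_emit = 0.05, seed = 2)
  expect_true(!is.unsorted(ph$macrotime_ns))
  expect_true(all(ph$channel %in% c(0, 1)))
  pulse <- floor(ph$macrotime_ns / 12.5)
  # per emitter, at most one photon per pulse (delays can cross a boundary,
  # so allow the rare spill into the neighbouring pulse window)
  for (i in 1:3) {
    tab <- table(pulse[ph$emitter == i])
    expect_lt(mean(tab > 1), 0.01)
  }
  expect_equal(nrow(ph), 3 * 5e4 * 0.05, tolerance = 0.1)
})
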