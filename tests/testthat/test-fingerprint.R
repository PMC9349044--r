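test_that("photon filtering is a strict threshold and order-preserving", {
  tb <- toy_locs(0:2, photons = c(600, 500, 400))
  expect_equal(nrow(filter_localizations(tb, 500)), 1)
  expect_equal(filter_localizations(tb, 500)$photons, 600)
  expect_identical(filter_localizations(tb, 0), tb)
  expect_equal(nrow(filter_localizations(tb[0, ], 500)), 0)
  expect_error(filter_localizations(tb, -1), "min_photons")
})

test_that("track linking separates distant structures and merges close ones", {
  tb <- rbind(toy_locs(0:9, x = 0, y = 0), toy_locs(0:9, x = 1000, y = 0))
  expect_equal(length(link_tracks(tb)), 2)
  set.seed(1)
  tb2 <- data.frame(frame = 0:49, x_nm = runif(50, 0, 50),
                    y_nm = runif(50, 0, 50), photons = 1000)
  expect_equal(length(link_tracks(tb2)), 1)
  expect_error(link_tracks(tb, radius_nm = 0), "radius")
})

test_that("greedy linking matches single-linkage clustering on sparse fields", {
  # density ~1 per um^2 over 10x10 um, radius 200 nm
  set.seed(7)
  n <- 100
  tb <- data.frame(frame = sample(0:999, n, TRUE),
                   x_nm = runif(n, 0, 10000), y_nm = runif(n, 0, 10000),
                   photons = 1000)
  greedy <- length(link_tracks(tb, 200))
  oracle <- length(unique(stats::cutree(
    stats::hclust(stats::dist(cbind(tb$x_nm, tb$y_nm)), "single"), h = 200)))
  expect_lte(abs(greedy - oracle) / oracle, 0.10)
})

test_that("fingerprint statistics follow the stated run and gap conventions", {
  tr <- link_tracks(toy_locs(c(10, 11, 12, 50, 51, 200)))[[1]]
  s <- fingerprint_stats(tr, 0.005)
  expect_equal(s$on_times, c(3L, 2L, 1L))
  expect_equal(s$off_times, c(37L, 148L))
  expect_equal(s$n_on_events, 3)
  expect_equal(s$n_on_events, length(s$off_times) + 1)
  # single-frame blip
  s1 <- fingerprint_stats(link_tracks(toy_locs(0))[[1]], 0.005)
  expect_equal(s1$on_times, 1L)
  expect_equal(length(s1$off_times), 0)
  expect_equal(s1$n_on_events, 1)
  # T80: 10 localizations at frames 1..10 -> frame 8 -> 0.040 s
  s10 <- fingerprint_stats(link_tracks(toy_locs(1:10))[[1]], 0.005)
  expect_equal(s10$t80, 0.040)
  expect_error(fingerprint_stats(list(frames = integer(0)), 0.005), "empty")
})

test_that("on/off conventions tile the acquisition exactly", {
  set.seed(11)
  for (rep in 1:20) {
    frames <- sort(sample(0:199, sample(3:40, 1)))
    s <- fingerprint_stats(link_tracks(toy_locs(frames))[[1]], 0.005)
    n_frames <- 200
    lead <- min(frames)
    trail <- n_frames - max(frames) - 1
    expect_equal(sum(s$on_times) + sum(s$off_times) + lead + trail, n_frames)
  }
})

test_that("cumulative curves are monotone and consistent with per-track T80", {
  expect_equal(cumulative_curve(list(), 10), rep(0L, 10))
  set.seed(3)
  frames <- sort(sample(0:499, 60))
  tr <- link_tracks(toy_locs(frames))[[1]]
  cc <- cumulative_curve(tr, 500)
  expect_true(all(diff(cc) >= 0))
  expect_equal(cc[500], 60)
  s <- fingerprint_stats(tr, 0.005)
  expect_equal(s$t80, t80_from_curve(cc, 0.005))
  expect_error(cumulative_curve(tr, 10), "n_frames")
})

test_that("Poisson-constant localization rates give a linear cumulative curve", {
  set.seed(5)
  frames <- sort(sample(0:9999, 600))
  cc <- cumulative_curve(link_tracks(toy_locs(frames)), 10000)
  ideal <- 600 * (1:10000) / 10000
  # binomial-style error band around the straight line
  expect_lt(max(abs(cc - ideal)), 4 * sqrt(600 * 0.25) + 5)
})

test_that("aggregation normalizes histograms and scales with fluorophore number", {
  tr <- link_tracks(toy_locs(c(1, 2, 10)))[[1]]
  agg1 <- aggregate_fingerprints(list(fingerprint_stats(tr, 0.005)))
  for (h in agg1$histograms)
    if (nrow(h)) expect_equal(sum(h$relative_occurrence), 1)
  expect_error(aggregate_fingerprints(list()), ">= 1")
  # independent blinking: mean on-events scale ~4x from 1 to 4 fluorophores
  rc <- fast_rates()
  ev_mean <- vapply(c("receptor_monomer", "receptor_tetramer_7nm"),
                    function(tpl) {
    ds <- generate_dataset(tpl, "dstorm", 16, seed = 17, rates = rc,
                           et_config = no_energy_transfer(),
                           n_frames = 24000)
    fp <- fingerprint_table(ds$localizations, 0.005)
    mean(vapply(fp$summaries, `[[`, 0, "n_on_events"))
  }, 0)
  expect_equal(unname(ev_mean[2] / ev_mean[1]), 4, tolerance = 0.25)
})

test_that("photon filtering before linking never increases on-event counts", {
  rc <- fast_rates()
  ds <- generate_dataset("origami_18nm", "dstorm", 4, seed = 23, rates = rc,
                         n_frames = 24000)
  ev <- function(min_ph) {
    fp <- fingerprint_table(ds$localizations, 0.005, min_photons = min_ph)
    sum(vapply(fp$summaries, `[[`, 0, "n_on_events"))
  }
  expect_lte(ev(500), ev(0))
})
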