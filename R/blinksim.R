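# Event-driven stochastic simulator of coupled photoswitching fluorophores.
#
# Exact continuous-time Markov chain (Gillespie) sampling of the state model
# defined in photophysics.R, with photon emission sampled as a Poisson
# process during ON dwells.  Microtimes reflect the instantaneous
# energy-transfer environment (quenched lifetime frozen per photon at
# emission time).

# integer state codes used in the hot loop.  PRIMED is an internal
# sub-state of the off manifold: an off-state that has absorbed
# energy-transfer excitation from an on-state donor and is converting back
# to the fluorescent on-state (mean conversion time rates$recovery_delay).
.ST <- c(ON = 1L, CIS = 2L, TRIPLET = 3L, OFF = 4L, BLEACHED = 5L,
         PRIMED = 6L)

#' Acquisition and detection settings for the simulator
#'
#' @param detection_efficiency Fraction of emitted photons detected
#'   (default 0.08).
#' @param background_rate Background count rate per detector channel in
#'   counts/s (default 100); background photons get uniform macrotimes,
#'   microtimes and positions.
#' @param pulse_period_ns Excitation pulse period in ns (default 12.5,
#'   i.e. 80 MHz).
#' @param microtime_resolution_ps Microtime quantization in ps (default 25).
#' @param irf_fwhm_ns FWHM of the Gaussian instrument response applied to
#'   photon microtimes (default 0.2 ns).
#' @param irf_t0_ns Position of the IRF peak within the pulse period
#'   (default 1 ns).
#' @param annihilation_radius_nm Range within which simultaneous on-state
#'   emission is brightness-suppressed when the energy-transfer config has
#'   \code{annihilate_on_on = TRUE} (default 10 nm).
#' @param quench_brightness If TRUE, the detected emission rate of an
#'   on-state fluorophore is additionally scaled by tau_q/tau0, its
#'   quenched quantum yield (energy transfer dims the donor as well as
#'   shortening its lifetime).  Default FALSE: the emission rate is
#'   excitation_rate x quantum_yield x detection_efficiency and quenching
#'   affects microtimes only.
#' @param background_box_nm Half-width of the box around the structure in
#'   which background photons are placed (default 500 nm).
#' @param initial_state State all fluorophores start in (default "ON": at
#'   the beginning of an acquisition every fluorophore is fluorescent).
#' @return A list of class \code{sim_settings}.
#' @export
sim_settings <- function(detection_efficiency = 0.08,
                         background_rate = 100,
                         pulse_period_ns = 12.5,
                         microtime_resolution_ps = 25,
                         irf_fwhm_ns = 0.2,
                         irf_t0_ns = 1.0,
                         annihilation_radius_nm = 10,
                         quench_brightness = FALSE,
                         background_box_nm = 500,
                         initial_state = "ON") {
  stopifnot(detection_efficiency > 0, detection_efficiency <= 1,
            background_rate >= 0, pulse_period_ns > 0,
            microtime_resolution_ps > 0, irf_fwhm_ns >= 0,
            irf_t0_ns >= 0, initial_state %in% FLUOR_STATES)
  structure(as.list(environment()), class = "sim_settings")
}

#' Simulate a photoswitching trajectory of a coupled fluorophore system
#'
#' Exact Gillespie sampling of the coupled photoswitching CTMC: exponential
#' waiting times from the total transition rate and categorical channel
#' choice, with the energy-transfer-mediated OFF to ON recovery rate updated
#' as donors enter and leave the ON state.  Photons are generated during ON
#' (trans) dwells as a Poisson process at rate
#' \code{excitation_rate * quantum_yield * detection_efficiency}; each
#' photon's microtime is drawn from the exponential with the quenched
#' lifetime given the emitter's energy-transfer environment at that instant,
#' jittered by the Gaussian IRF and folded into the pulse period.  Detector
#' channel is Bernoulli(1/2).  Identical seeds give identical output.
#'
#' @param rates A [rate_constants()] object.
#' @param geometry An [emitter_geometry()].
#' @param et_config An [energy_transfer_config()] (use
#'   [no_energy_transfer()] for independent fluorophores).
#' @param duration Acquisition duration in seconds.
#' @param seed Optional integer seed.
#' @param sim A [sim_settings()] object.
#' @param photons If FALSE, skip photon generation (state path only).
#' @return A list of class \code{simulation_result} with elements
#'   \code{state_path} (data.frame: time_s, fluorophore, state — the state
#'   entered at that time), \code{photons} (data.frame: channel,
#'   macrotime_ns, microtime_ps, emitter; emitter 0 marks background),
#'   \code{geometry}, \code{rates}, \code{et_config}, \code{sim},
#'   \code{duration}, \code{seed}.
#' @export
simulate_trajectory <- function(rates, geometry, et_config = no_energy_transfer(),
                                duration, seed = NULL, sim = sim_settings(),
                                photons = TRUE) {
  if (!is.numeric(duration) || duration <= 0)
    stop("simulate_trajectory: duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- geometry$n
  kx <- rates$excitation_rate

  # per-state exit rates and branch tables
  k_on_ch <- kx * c(rates$trans_to_cis_yield, rates$isc_yield,
                    rates$off_switch_yield, rates$bleach_yield)
  on_targets <- c(.ST[["CIS"]], .ST[["TRIPLET"]], .ST[["OFF"]],
                  .ST[["BLEACHED"]])
  k_on_tot <- sum(k_on_ch)
  k_cis <- 1 / rates$cis_lifetime + kx * rates$cis_to_trans_photoyield
  k_tri <- 1 / rates$triplet_lifetime
  k_act <- rates$photoactivation_rate
  ry_kx <- rates$recovery_yield * kx
  k_conv <- if (rates$recovery_delay > 0) 1 / rates$recovery_delay else Inf
  cm <- recovery_coupling_matrix(geometry, et_config)  # (R0/r)^6, ON->OFF

  st <- rep(.ST[[sim$initial_state]], n)
  coup <- if (st[1] == .ST[["ON"]] && n > 1) colSums(cm) else numeric(n)
  if (n == 1) coup <- 0
  # recompute coup for arbitrary initial state
  on_mask <- st == .ST[["ON"]]
  coup <- if (any(on_mask) && n > 1) colSums(cm[on_mask, , drop = FALSE]) else
    rep(0, n)

  cap <- 1024L
  ev_t <- numeric(cap); ev_f <- integer(cap); ev_s <- integer(cap)
  m <- 0L
  t <- 0
  rate_j <- numeric(n)
  repeat {
    for (j in seq_len(n)) {
      sj <- st[j]
      rate_j[j] <- if (sj == 1L) k_on_tot
      else if (sj == 2L) k_cis
      else if (sj == 3L) k_tri
      else if (sj == 4L) k_act + ry_kx * coup[j]
      else if (sj == 6L) k_act + k_conv
      else 0
    }
    rtot <- sum(rate_j)
    if (rtot <= 0) break                      # all bleached (or frozen): idle
    t <- t + stats::rexp(1L, rtot)
    if (t >= duration) break
    u <- stats::runif(1L) * rtot
    j <- 1L
    acc <- rate_j[1L]
    while (acc < u && j < n) { j <- j + 1L; acc <- acc + rate_j[j] }
    sj <- st[j]
    new <- if (sj == 1L) {
      v <- stats::runif(1L) * k_on_tot
      kk <- 1L; a2 <- k_on_ch[1L]
      while (a2 < v && kk < 4L) { kk <- kk + 1L; a2 <- a2 + k_on_ch[kk] }
      on_targets[kk]
    } else if (sj == 4L && is.finite(k_conv) &&
               stats::runif(1L) * rate_j[j] >= k_act) {
      6L                                      # ET-primed: delayed conversion
    } else 1L                                 # dark states return to ON
    # maintain ET coupling sums
    if (n > 1) {
      if (sj == 1L) coup <- coup - cm[j, ]
      if (new == 1L) coup <- coup + cm[j, ]
    }
    st[j] <- new
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      length(ev_t) <- cap; length(ev_f) <- cap; length(ev_s) <- cap
    }
    ev_t[m] <- t; ev_f[m] <- j; ev_s[m] <- new
  }
  state_path <- data.frame(
    time_s = ev_t[seq_len(m)],
    fluorophore = ev_f[seq_len(m)],
    state = names(.ST)[ev_s[seq_len(m)]],
    stringsAsFactors = FALSE
  )
  res <- structure(list(state_path = state_path, photons = NULL,
                        geometry = geometry, rates = rates,
                        et_config = et_config, sim = sim,
                        duration = duration, seed = seed),
                   class = "simulation_result")
  if (photons) res$photons <- .emit_photons(res)
  res
}

# Internal: per-acceptor-state quench matrices (1/ns), indexed [donor, acceptor]
.quench_matrices <- function(geometry, et_config, tau0) {
  n <- geometry$n
  d <- geometry$pairwise_distances
  out <- vector("list", 6L)
  for (a in et_config$enabled_pairs) {
    m <- matrix(0, n, n)
    if (n > 1) {
      off_diag <- d > 0
      m[off_diag] <- (et_config$r0[[a]] / d[off_diag])^6 / tau0
    }
    out[[.ST[[a]]]] <- m
  }
  out[[.ST[["PRIMED"]]]] <- out[[.ST[["OFF"]]]]  # primed quenches like OFF
  out
}

# Internal: sample detected photons given a simulated state path.
.emit_photons <- function(res) {
  n <- res$geometry$n
  sim <- res$sim
  rates <- res$rates
  tau0 <- tau0_ns(rates)
  rate_det <- rates$excitation_rate * rates$quantum_yield *
    sim$detection_efficiency                       # detected photons /s
  qm <- .quench_matrices(res$geometry, res$et_config, tau0)
  sigma_irf <- sim$irf_fwhm_ns / 2.3548
  period <- sim$pulse_period_ns
  qres <- sim$microtime_resolution_ps
  ann <- res$et_config$annihilate_on_on
  ann_near <- res$geometry$pairwise_distances < sim$annihilation_radius_nm

  sp <- res$state_path
  tb <- c(0, sp$time_s, res$duration)
  nint <- length(tb) - 1L
  st <- rep(.ST[[sim$initial_state]], n)
  acc_t <- vector("list", 64L); acc_m <- vector("list", 64L)
  acc_e <- vector("list", 64L)
  nacc <- 0L
  for (k in seq_len(nint)) {
    len <- tb[k + 1L] - tb[k]
    on_idx <- which(st == 1L)
    if (len > 0 && length(on_idx)) {
      for (i in on_idx) {
        q <- 0
        if (n > 1L) for (j in seq_len(n)) {
          if (j != i && !is.null(qm[[st[j]]])) q <- q + qm[[st[j]]][i, j]
        }
        tau_q <- 1 / (1 / tau0 + q)
        fac <- if (ann && length(on_idx) > 1L)
          1 / sum(ann_near[i, on_idx]) else 1
        if (isTRUE(sim$quench_brightness)) fac <- fac * tau_q / tau0
        nph <- stats::rpois(1L, rate_det * fac * len)
        if (nph > 0L) {
          macro <- (tb[k] + stats::runif(nph) * len) * 1e9
          micro <- sim$irf_t0_ns + stats::rnorm(nph, 0, sigma_irf) +
            stats::rexp(nph, 1 / tau_q)
          micro <- micro %% period
          nacc <- nacc + 1L
          if (nacc > length(acc_t)) {
            length(acc_t) <- 2L * length(acc_t)
            length(acc_m) <- length(acc_t); length(acc_e) <- length(acc_t)
          }
          acc_t[[nacc]] <- macro
          acc_m[[nacc]] <- micro
          acc_e[[nacc]] <- rep.int(i, nph)
        }
      }
    }
    if (k <= nrow(sp)) st[sp$fluorophore[k]] <- .ST[[sp$state[k]]]
  }
  macro <- unlist(acc_t[seq_len(nacc)], use.names = FALSE)
  micro <- unlist(acc_m[seq_len(nacc)], use.names = FALSE)
  emitter <- unlist(acc_e[seq_len(nacc)], use.names = FALSE)
  if (is.null(macro)) { macro <- micro <- emitter <- numeric(0) }
  # background: uniform macrotime, microtime and position
  nbg <- stats::rpois(1L, 2 * sim$background_rate * res$duration)
  if (nbg > 0L) {
    macro <- c(macro, stats::runif(nbg, 0, res$duration * 1e9))
    micro <- c(micro, stats::runif(nbg, 0, period))
    emitter <- c(emitter, rep.int(0L, nbg))
  }
  ord <- order(macro)
  data.frame(
    channel = stats::rbinom(length(macro), 1L, 0.5),
    macrotime_ns = macro[ord],
    microtime_ps = floor(micro[ord] * 1000 / qres) * qres,
    emitter = as.integer(emitter[ord])
  )
}

#' Completed dwell times of a state from a simulated trajectory
#'
#' Extracts the durations of completed visits to one state, per fluorophore,
#' from the state path (exact CTMC dwells, independent of any frame
#' discretization).
#'
#' @param result A \code{simulation_result}.
#' @param state State name, e.g. "OFF" or "ON".
#' @param fluorophore Optional fluorophore index to restrict to.
#' @param include_initial Include the dwell started at time zero (default
#'   FALSE, since its start is not an observed entry).
#' @return Numeric vector of dwell durations in seconds.
#' @export
state_dwells <- function(result, state = "OFF", fluorophore = NULL,
                         include_initial = FALSE) {
  stopifnot(state %in% names(.ST))
  sp <- result$state_path
  n <- result$geometry$n
  fls <- if (is.null(fluorophore)) seq_len(n) else fluorophore
  out <- numeric(0)
  for (j in fls) {
    ev <- sp[sp$fluorophore == j, , drop = FALSE]
    times <- c(0, ev$time_s)
    states <- c(result$sim$initial_state, ev$state)
    in_state <- states == state
    if (!any(in_state)) next
    k <- which(in_state)
    ended <- k[k < length(times)]              # completed dwells only
    if (!include_initial) ended <- ended[ended > 1L]
    out <- c(out, times[ended + 1L] - times[ended])
  }
  out
}

#' Simulate a two-state telegraph emitter
#'
#' Alternating exponential ON/OFF dwells with Poisson photon emission during
#' ON periods.  Used for DNA-PAINT-mode binding kinetics (arrivals at
#' \code{k_on}, bright times \code{1/k_off}) and as an analytic reference for
#' autocorrelation tests.
#'
#' @param duration Trace duration in seconds.
#' @param k_on OFF to ON rate in 1/s.
#' @param k_off ON to OFF rate in 1/s.
#' @param photon_rate Detected photon rate while ON (counts/s).
#' @param lifetime_ns Fluorescence lifetime used for microtimes (ns).
#' @param start_on Start in the ON state? Default FALSE (equilibrium draws
#'   are up to the caller; OFF start suits binding kinetics).
#' @param seed Optional integer seed.
#' @param sim A [sim_settings()] (pulse period, IRF, quantization).
#' @return List with \code{photons} (channel, macrotime_ns, microtime_ps),
#'   \code{on_dwells}, \code{off_dwells} (completed dwells, s).
#' @export
simulate_telegraph <- function(duration, k_on, k_off, photon_rate,
                               lifetime_ns = 2.0, start_on = FALSE,
                               seed = NULL, sim = sim_settings()) {
  stopifnot(duration > 0, k_on > 0, k_off > 0, photon_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  # generate alternating dwells until the duration is covered
  t <- 0; on <- start_on
  starts <- numeric(0); ends <- numeric(0)
  on_dw <- numeric(0); off_dw <- numeric(0)
  while (t < duration) {
    d <- stats::rexp(1L, if (on) k_off else k_on)
    d_clip <- min(d, duration - t)
    if (on) {
      starts <- c(starts, t); ends <- c(ends, t + d_clip)
      if (t + d <= duration) on_dw <- c(on_dw, d)
    } else {
      if (t + d <= duration) off_dw <- c(off_dw, d)
    }
    t <- t + d
    on <- !on
  }
  nph <- stats::rpois(length(starts), photon_rate * (ends - starts))
  macro <- unlist(Map(function(a, b, k) if (k > 0) a + stats::runif(k) * (b - a)
                      else numeric(0),
                      starts, ends, nph), use.names = FALSE)
  if (is.null(macro)) macro <- numeric(0)
  macro <- sort(macro) * 1e9
  sigma_irf <- sim$irf_fwhm_ns / 2.3548
  micro <- (sim$irf_t0_ns + stats::rnorm(length(macro), 0, sigma_irf) +
              stats::rexp(length(macro), 1 / lifetime_ns)) %% sim$pulse_period_ns
  data_ph <- data.frame(
    channel = stats::rbinom(length(macro), 1L, 0.5),
    macrotime_ns = macro,
    microtime_ps = floor(micro * 1000 / sim$microtime_resolution_ps) *
      sim$microtime_resolution_ps,
    emitter = rep.int(1L, length(macro))
  )
  list(photons = data_ph, on_dwells = on_dw, off_dwells = off_dw)
}

#' Simulate photon streams under pulsed excitation for antibunching analysis
#'
#' Each of \code{n_emitters} independent emitters emits at most one photon
#' per excitation pulse with probability \code{p_emit}; photons are delayed
#' by an exponential excited-state lifetime and routed 50:50 onto two
#' detector channels (Hanbury Brown-Twiss geometry).  Optional uncorrelated
#' background photons are placed uniformly in time.
#'
#' @param n_pulses Number of excitation pulses.
#' @param n_emitters Number of independent identical emitters.
#' @param p_emit Detected-photon probability per pulse per emitter.
#' @param period_ns Pulse period in ns (default 12.5).
#' @param lifetime_ns Emission delay time constant in ns (default 1.8).
#' @param background_fraction Background photons as a fraction of signal
#'   photons (default 0).
#' @param seed Optional integer seed.
#' @return A data.frame photon stream (channel, macrotime_ns, microtime_ps,
#'   emitter; 0 = background), macrotime-sorted.
#' @export
simulate_pulsed_emitters <- function(n_pulses, n_emitters, p_emit = 0.01,
                                     period_ns = 12.5, lifetime_ns = 1.8,
                                     background_fraction = 0, seed = NULL) {
  stopifnot(n_pulses >= 1, n_emitters >= 1, p_emit >= 0, p_emit <= 1,
            period_ns > 0, background_fraction >= 0)
  if (!is.null(seed)) set.seed(seed)
  macro <- numeric(0); emitter <- integer(0)
  for (i in seq_len(n_emitters)) {
    pulses <- which(stats::runif(n_pulses) < p_emit)
    if (length(pulses)) {
      macro <- c(macro, (pulses - 1L) * period_ns +
                   stats::rexp(length(pulses), 1 / lifetime_ns))
      emitter <- c(emitter, rep.int(i, length(pulses)))
    }
  }
  nbg <- stats::rpois(1L, background_fraction * length(macro))
  if (nbg > 0L) {
    macro <- c(macro, stats::runif(nbg, 0, n_pulses * period_ns))
    emitter <- c(emitter, rep.int(0L, nbg))
  }
  ord <- order(macro)
  data.frame(
    channel = stats::rbinom(length(macro), 1L, 0.5),
    macrotime_ns = macro[ord],
    microtime_ps = floor((macro[ord] %% period_ns) * 1000 / 25) * 25,
    emitter = emitter[ord]
  )
}
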