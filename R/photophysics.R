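# Fluorophore state model and distance-dependent energy-transfer math.
#
# The state space of a photoswitchable cyanine dye (Cy5-like) is modelled as
#   ON       fluorescent trans isomer
#   CIS      non-fluorescent cis isomer (short-lived dark state)
#   TRIPLET  triplet dark state
#   OFF      long-lived dark state (thiol adduct / radical; generic)
#   BLEACHED absorbing photobleached state
# Photo-driven transitions are parameterized as excitation_rate x yield,
# giving effective first-order rates; spontaneous returns are first-order.

FLUOR_STATES <- c("ON", "CIS", "TRIPLET", "OFF", "BLEACHED")

#' Photophysical rate constants of a photoswitchable fluorophore
#'
#' Bundles the per-fluorophore rates and per-excitation branching yields that
#' drive the blinking simulator and the interpretation of photoswitching
#' fingerprints.  Photo-driven transitions are modelled as effective
#' first-order rates \code{excitation_rate * yield}; dark-state returns are
#' spontaneous first-order processes.
#'
#' Default values emulate Cy5 in thiol-based photoswitching buffer at an
#' irradiation intensity of roughly 5 kW cm^-2: an unquenched lifetime of
#' 1.8 ns, a cis state with a lifetime of about 200 microseconds occupied
#' roughly 50% of the time under continuous excitation, on-times of several
#' milliseconds, off-times of seconds, and a handful of switching cycles
#' before photobleaching.  Absolute switching and bleaching yields of Cy5 in
#' MEA buffer are not established constants; the defaults are documented,
#' tunable choices.
#'
#' @param excitation_rate Excitation events per second (1/s).  See
#'   [excitation_rate_from_intensity()] to derive it from an irradiation
#'   intensity in kW cm^-2.
#' @param radiative_plus_nonradiative_rate Depopulation rate of the excited
#'   singlet state (1/s); its inverse is the unquenched lifetime tau0.
#' @param quantum_yield Fluorescence quantum yield (photons emitted per
#'   excitation) used for photon generation in the simulator.
#' @param isc_yield Intersystem-crossing yield per excitation (to TRIPLET).
#' @param triplet_lifetime Triplet lifetime in seconds.
#' @param trans_to_cis_yield Photoisomerization yield per excitation
#'   (ON to CIS).
#' @param cis_lifetime Spontaneous cis lifetime in seconds.
#' @param cis_to_trans_photoyield Back-isomerization yield per cis
#'   excitation.
#' @param off_switch_yield Off-switching yield per excitation (ON to OFF).
#' @param photoactivation_rate Direct OFF to ON recovery rate under red
#'   irradiation (1/s).
#' @param bleach_yield Photobleaching yield per excitation.
#' @param recovery_yield Probability that an energy-transfer excitation of
#'   an OFF-state acceptor initiates its return to the ON state.
#' @param recovery_delay Mean time (s) for an energy-transfer-primed
#'   off-state to complete its conversion to the fluorescent on-state
#'   (default 0.02 s).  The off-state is a metastable chemical species;
#'   its regeneration is not instantaneous, so recovered fluorophores
#'   light up shortly after the donor event that primed them.  Set to 0
#'   for instantaneous recovery.
#' @return An object of class \code{rate_constants} (a validated list).
#' @examples
#' rc <- rate_constants()
#' tau0_ns(rc)  # 1.8
#' @export
rate_constants <- function(excitation_rate = 1.5e7,
                           radiative_plus_nonradiative_rate = 1 / 1.8e-9,
                           quantum_yield = 0.28,
                           isc_yield = 3e-5,
                           triplet_lifetime = 2e-6,
                           trans_to_cis_yield = 4e-4,
                           cis_lifetime = 200e-6,
                           cis_to_trans_photoyield = 1 / 1.5e4,
                           off_switch_yield = 1.667e-5,
                           photoactivation_rate = 0.05,
                           bleach_yield = 1.1e-6,
                           recovery_yield = 2e-4,
                           recovery_delay = 0.02) {
  rc <- list(
    excitation_rate = excitation_rate,
    radiative_plus_nonradiative_rate = radiative_plus_nonradiative_rate,
    quantum_yield = quantum_yield,
    isc_yield = isc_yield,
    triplet_lifetime = triplet_lifetime,
    trans_to_cis_yield = trans_to_cis_yield,
    cis_lifetime = cis_lifetime,
    cis_to_trans_photoyield = cis_to_trans_photoyield,
    off_switch_yield = off_switch_yield,
    photoactivation_rate = photoactivation_rate,
    bleach_yield = bleach_yield,
    recovery_yield = recovery_yield,
    recovery_delay = recovery_delay
  )
  rates <- c("excitation_rate", "radiative_plus_nonradiative_rate",
             "photoactivation_rate")
  lifetimes <- c("triplet_lifetime", "cis_lifetime")
  yields <- c("quantum_yield", "isc_yield", "trans_to_cis_yield",
              "cis_to_trans_photoyield", "off_switch_yield", "bleach_yield",
              "recovery_yield")
  for (f in names(rc)) {
    v <- rc[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate_constants: '", f, "' must be a single finite number")
  }
  for (f in c(rates, yields))
    if (rc[[f]] < 0) stop("rate_constants: '", f, "' must be >= 0")
  for (f in lifetimes)
    if (rc[[f]] <= 0) stop("rate_constants: '", f, "' must be > 0")
  if (rc$recovery_delay < 0)
    stop("rate_constants: 'recovery_delay' must be >= 0")
  for (f in yields)
    if (rc[[f]] > 1) stop("rate_constants: '", f, "' must be <= 1")
  branching <- rc$isc_yield + rc$trans_to_cis_yield + rc$off_switch_yield +
    rc$bleach_yield
  if (branching > 1)
    stop("rate_constants: per-excitation branching yields sum to ",
         signif(branching, 4), " > 1")
  if (rc$radiative_plus_nonradiative_rate <= 0)
    stop("rate_constants: radiative_plus_nonradiative_rate must be > 0")
  structure(rc, class = "rate_constants")
}

#' Unquenched fluorescence lifetime in nanoseconds
#'
#' @param rc A [rate_constants()] object.
#' @return tau0 in ns (1e9 / radiative_plus_nonradiative_rate).
#' @export
tau0_ns <- function(rc) 1e9 / rc$radiative_plus_nonradiative_rate

#' Excitation rate from irradiation intensity
#'
#' Converts an irradiation intensity to an excitation rate using the
#' absorption cross-section derived from the molar extinction coefficient,
#' sigma (cm^2) = 1000 ln(10) / N_A * epsilon = 3.82e-21 * epsilon.
#'
#' @param intensity_kw_cm2 Irradiation intensity in kW cm^-2.
#' @param wavelength_nm Excitation wavelength in nm (default 640).
#' @param epsilon Molar extinction coefficient in M^-1 cm^-1 at the
#'   excitation wavelength (default 250000, Cy5-like).
#' @return Excitation rate in 1/s.
#' @examples
#' excitation_rate_from_intensity(5)  # about 1.5e7 /s
#' @export
excitation_rate_from_intensity <- function(intensity_kw_cm2,
                                           wavelength_nm = 640,
                                           epsilon = 250000) {
  stopifnot(intensity_kw_cm2 >= 0, wavelength_nm > 0, epsilon > 0)
  sigma_cm2 <- 3.82e-21 * epsilon
  h <- 6.62607015e-34
  c_ms <- 2.99792458e8
  e_photon <- h * c_ms / (wavelength_nm * 1e-9)           # J
  flux <- intensity_kw_cm2 * 1000 / e_photon              # photons cm^-2 s^-1
  sigma_cm2 * flux
}

#' State-pair Forster radii for energy transfer between photoswitching states
#'
#' The broad absorption of the dark states (off, cis and triplet) of
#' red-absorbing cyanine dyes overlaps the emission of the fluorescent
#' on-state, so an on-state donor can transfer energy to dark-state
#' acceptors within Forster range.  Each enabled donor-ON to acceptor-state
#' pair carries its own Forster radius R0; disabled pairs contribute zero
#' rate.  The orientation factor kappa^2 is absorbed into R0 (isotropic
#' average), appropriate for freely rotating, highly water-soluble cyanines.
#'
#' Default radii are anchored to the observed lifetime quenching of the
#' on-state at 3 nm spacing: a ~600 ps decay component from trans-to-cis
#' transfer (one to two cis acceptors at 3 nm against tau0 = 1.8 ns gives
#' R0 on->cis of about 3.4 nm), an additional ~400 ps channel to the
#' long-lived off-state in switching buffer (R0 on->off 4.0 nm), and a
#' minor short-lived triplet channel (R0 on->triplet 3.0 nm).  With these
#' values 3 and 6 nm systems couple strongly while 9 and 18 nm spacings are
#' near-independent.  They are tunable model parameters, not measured
#' constants.
#'
#' @param r0_on_off Forster radius (nm) for ON donor, OFF acceptor.
#' @param r0_on_cis Forster radius (nm) for ON donor, CIS acceptor.
#' @param r0_on_triplet Forster radius (nm) for ON donor, TRIPLET acceptor.
#' @param enabled_pairs Character vector of acceptor states with ET enabled;
#'   any subset of \code{c("OFF", "CIS", "TRIPLET")}.  Use
#'   \code{character(0)} to disable energy transfer entirely.
#' @param annihilate_on_on If TRUE, simultaneous emission of multiple
#'   on-state fluorophores within near-field range is brightness-suppressed
#'   in the simulator (energy hopping / singlet-singlet annihilation proxy);
#'   no explicit ON-ON rate is modelled.  Default FALSE: simultaneously
#'   emitting fluorophores add up, giving the slightly higher on-state
#'   intensities seen for closely spaced structures.
#' @return An object of class \code{energy_transfer_config}.
#' @export
energy_transfer_config <- function(r0_on_off = 4.0,
                                   r0_on_cis = 3.4,
                                   r0_on_triplet = 3.0,
                                   enabled_pairs = c("OFF", "CIS", "TRIPLET"),
                                   annihilate_on_on = FALSE) {
  enabled_pairs <- as.character(enabled_pairs)
  bad <- setdiff(enabled_pairs, c("OFF", "CIS", "TRIPLET"))
  if (length(bad))
    stop("energy_transfer_config: unknown acceptor state(s): ",
         paste(bad, collapse = ", "))
  r0 <- c(OFF = r0_on_off, CIS = r0_on_cis, TRIPLET = r0_on_triplet)
  for (p in enabled_pairs)
    if (!is.finite(r0[[p]]) || r0[[p]] <= 0)
      stop("energy_transfer_config: R0 for enabled pair ON->", p,
           " must be > 0")
  structure(list(r0 = r0, enabled_pairs = enabled_pairs,
                 annihilate_on_on = isTRUE(annihilate_on_on)),
            class = "energy_transfer_config")
}

#' Disable all energy transfer
#'
#' Convenience wrapper: an [energy_transfer_config()] with no enabled state
#' pairs, making all fluorophores photophysically independent.
#' @return An \code{energy_transfer_config} with ET off.
#' @export
no_energy_transfer <- function() {
  energy_transfer_config(enabled_pairs = character(0),
                         annihilate_on_on = FALSE)
}

#' Geometry of a multi-fluorophore emitter
#'
#' @param positions Numeric matrix (n x 2) of fluorophore positions in nm,
#'   or a data.frame with columns x and y.
#' @return An object of class \code{emitter_geometry} with fields
#'   \code{positions} (nm) and \code{pairwise_distances} (symmetric nm
#'   matrix, zero diagonal).
#' @examples
#' g <- emitter_geometry(rbind(c(0, 0), c(3, 0)))
#' g$pairwise_distances[1, 2]  # 3
#' @export
emitter_geometry <- function(positions) {
  if (is.data.frame(positions)) positions <- cbind(positions$x, positions$y)
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || !is.numeric(positions) ||
      any(!is.finite(positions)))
    stop("emitter_geometry: positions must be a finite numeric n x 2 matrix")
  d <- as.matrix(stats::dist(positions))
  dimnames(d) <- NULL
  if (nrow(positions) > 1L && any(d[upper.tri(d)] <= 0))
    stop("emitter_geometry: coincident fluorophore positions")
  structure(list(positions = positions, pairwise_distances = d,
                 n = nrow(positions)),
            class = "emitter_geometry")
}

#' Forster energy-transfer rate
#'
#' Standard Forster law: k_ET = (1/tau0) * (R0/r)^6, the transfer rate from
#' an excited donor to an acceptor at distance r for Forster radius R0.
#' Strictly decreasing in r; at r = R0 the transfer rate equals the donor
#' decay rate (efficiency 0.5).
#'
#' @param r Donor-acceptor distance in nm (vectorized).
#' @param R0 Forster radius in nm.
#' @param tau0 Unquenched donor lifetime in ns.
#' @return Transfer rate in 1/ns.
#' @examples
#' et_rate(4, 4, 1.8)     # = 1/1.8
#' et_rate(2, 4, 1)       # = 64
#' @export
et_rate <- function(r, R0, tau0) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("et_rate: r must be > 0")
  if (!is.finite(R0) || R0 <= 0) stop("et_rate: R0 must be > 0")
  if (!is.finite(tau0) || tau0 <= 0) stop("et_rate: tau0 must be > 0")
  (1 / tau0) * (R0 / r)^6
}

#' Forster transfer efficiency for a single acceptor
#'
#' E = R0^6 / (R0^6 + r^6); equals 0.5 at r = R0.
#'
#' @inheritParams et_rate
#' @return Efficiency in (0, 1).
#' @export
fret_efficiency <- function(r, R0) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("fret_efficiency: r must be > 0")
  if (!is.finite(R0) || R0 <= 0) stop("fret_efficiency: R0 must be > 0")
  R0^6 / (R0^6 + r^6)
}

#' Quenched fluorescence lifetime
#'
#' Energy transfer adds depopulation channels to the excited state:
#' tau = 1 / (1/tau0 + sum of ET rates).  Equals tau0 when no acceptor is
#' present and decreases monotonically with the summed transfer rate.
#'
#' @param tau0 Unquenched lifetime in ns.
#' @param et_rates Numeric vector of transfer rates in 1/ns (possibly empty).
#' @return Quenched lifetime in ns.
#' @examples
#' quenched_lifetime(1.8, 1 / 1.8)        # 0.9: one acceptor at r = R0
#' quenched_lifetime(1.8, numeric(0))     # 1.8
#' @export
quenched_lifetime <- function(tau0, et_rates = numeric(0)) {
  if (!is.finite(tau0) || tau0 <= 0) stop("quenched_lifetime: tau0 must be > 0")
  if (length(et_rates) && (any(!is.finite(et_rates)) || any(et_rates < 0)))
    stop("quenched_lifetime: et_rates must be finite and >= 0")
  1 / (1 / tau0 + sum(et_rates))
}

# Internal: (R0/r)^6 coupling matrix for the ON->OFF recovery pathway.
# Zero diagonal; zero everywhere when the OFF pair is disabled.
recovery_coupling_matrix <- function(geometry, et_config) {
  n <- geometry$n
  m <- matrix(0, n, n)
  if (!("OFF" %in% et_config$enabled_pairs) || n < 2L) return(m)
  r0 <- et_config$r0[["OFF"]]
  d <- geometry$pairwise_distances
  off_diag <- d > 0
  m[off_diag] <- (r0 / d[off_diag])^6
  m
}

#' All enabled state transitions of a coupled multi-fluorophore system
#'
#' Enumerates the currently possible transitions and their rates given the
#' instantaneous state vector.  Photo-driven channels are
#' \code{excitation_rate * yield}; dark-state returns are spontaneous.  The
#' energy-transfer-mediated OFF to ON recovery rate of acceptor j is
#' \code{recovery_yield * excitation_rate * sum_i (R0/r_ij)^6} summed over
#' fluorophores i currently in the ON state (the time-averaged
#' low-transfer-limit rate at which donor excitations are funnelled into an
#' off-state acceptor).  BLEACHED is absorbing.
#'
#' @param states Character vector of per-fluorophore states, each one of
#'   \code{c("ON", "CIS", "TRIPLET", "OFF", "BLEACHED")}.
#' @param rates A [rate_constants()] object.
#' @param geometry An [emitter_geometry()] with one position per fluorophore.
#' @param et_config An [energy_transfer_config()].
#' @return A data.frame with columns \code{fluorophore} (1-based index),
#'   \code{target_state} and \code{rate} (1/s); zero rows if no transition
#'   is possible (e.g. all bleached).
#' @examples
#' g <- emitter_geometry(rbind(c(0, 0), c(3, 0)))
#' joint_transition_rates(c("ON", "OFF"), rate_constants(), g,
#'                        energy_transfer_config())
#' @export
joint_transition_rates <- function(states, rates, geometry, et_config) {
  states <- as.character(states)
  bad <- setdiff(states, FLUOR_STATES)
  if (length(bad))
    stop("joint_transition_rates: unknown state label(s): ",
         paste(unique(bad), collapse = ", "))
  n <- length(states)
  if (geometry$n != n)
    stop("joint_transition_rates: geometry has ", geometry$n,
         " positions for ", n, " states")
  kx <- rates$excitation_rate
  cm <- recovery_coupling_matrix(geometry, et_config)
  on_idx <- which(states == "ON")
  out <- vector("list", n)
  for (j in seq_len(n)) {
    s <- states[j]
    if (s == "ON") {
      tg <- c("CIS", "TRIPLET", "OFF", "BLEACHED")
      rt <- kx * c(rates$trans_to_cis_yield, rates$isc_yield,
                   rates$off_switch_yield, rates$bleach_yield)
    } else if (s == "CIS") {
      tg <- "ON"
      rt <- 1 / rates$cis_lifetime + kx * rates$cis_to_trans_photoyield
    } else if (s == "TRIPLET") {
      tg <- "ON"
      rt <- 1 / rates$triplet_lifetime
    } else if (s == "OFF") {
      donors <- setdiff(on_idx, j)
      et <- if (length(donors)) sum(cm[donors, j]) else 0
      tg <- "ON"
      rt <- rates$photoactivation_rate + rates$recovery_yield * kx * et
    } else {  # BLEACHED: absorbing
      tg <- character(0)
      rt <- numeric(0)
    }
    keep <- rt > 0
    out[[j]] <- data.frame(fluorophore = rep(j, sum(keep)),
                           target_state = tg[keep], rate = rt[keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
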