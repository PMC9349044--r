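---
title: "Photoswitching fingerprints: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photoswitching fingerprints: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-molecule localization microscopy (SMLM) separates fluorophores in
time: in dSTORM, cyanine dyes such as Cy5 are driven into a long-lived dark
("off") state by thiol-based photoswitching buffer, and sparse, stochastic
returns to the fluorescent on-state are localized frame by frame.
Localization *precision* of 1–5 nm is routine; yet structures with
interfluorophore distances below ~10 nm image poorly.  The reason is not
precision but localization *probability*: fluorophores closer than a
Förster radius exchange energy.  An on-state donor can excite the
dark-state absorption of a neighbour — the off-state of Cy5-type dyes has a
broad absorption overlapping the donor emission, and the cis isomer and
triplet state absorb there too — so dark-state neighbours are pumped back
toward the on-state, blinking accelerates, and the limited photobleaching
budget of each dye is spent in the first seconds of the acquisition.

The same coupling is an opportunity: the *photoswitching fingerprint* of a
diffraction-limited spot — its on-times, off-times, number of on-events,
intensity, the temporal distribution of its localizations, its fluorescence
lifetime, and its photon antibunching signature — encodes both the number
of fluorophores and their sub-10-nm distances.  `switchprint` implements
that analysis chain, together with a stochastic simulator of the coupled
photophysics that generates all of the package's test data.

## The photophysical state model

Each fluorophore occupies one of five states:

| state    | meaning                                   | leaves by                                    |
|----------|-------------------------------------------|----------------------------------------------|
| ON       | fluorescent trans isomer                  | photo-driven branching (below)               |
| CIS      | dark cis isomer                           | spontaneous (~200 µs) + photo back-reaction  |
| TRIPLET  | triplet dark state                        | spontaneous (µs)                             |
| OFF      | long-lived dark state (thiol adduct or radical; modelled generically) | photoactivation + energy-transfer recovery |
| BLEACHED | photobleached                             | absorbing                                    |

Photo-driven transitions are parameterized as `excitation_rate × yield`,
i.e. effective first-order rates; sub-nanosecond excited-state dynamics are
not explicit states — they live only in photon microtime sampling.  The
identity of the off-state is deliberately generic: the literature has not
settled between a thiol adduct and a radical anion, and nothing downstream
depends on which it is.

Defaults (`rate_constants()`) describe Cy5-like dyes in MEA photoswitching
buffer at ~5 kW cm⁻² irradiation at 640 nm:

* `excitation_rate = 1.5e7 /s`, from intensity × absorption cross-section
  (`excitation_rate_from_intensity(5)`);
* unquenched lifetime τ₀ = 1.8 ns (`radiative_plus_nonradiative_rate`);
* trans/cis isomerization tuned so the cis state (lifetime 200 µs) is
  occupied ~50 % of the time under continuous excitation — the
  photostationary equilibrium reported for Cy5 in aqueous buffer;
* `off_switch_yield` giving on-times of several milliseconds and
  `bleach_yield` giving ≈15 switching cycles before photobleaching;
* `photoactivation_rate = 0.05 /s`: off-times of tens of seconds, so that
  an isolated fluorophore spreads its switching cycles over a 10-minute
  acquisition and cumulative localization curves of uncoupled structures
  stay quasi-linear, as observed experimentally.

Absolute switching and bleaching yields of Cy5 in MEA buffer are not
established constants; these defaults are documented, tunable model
choices, and the parameter-recovery tests validate the machinery, not the
constants.

## Distance coupling

Energy transfer follows the standard Förster law,
`k_ET = (1/τ₀)(R₀/r)⁶`, with a separate Förster radius per donor–acceptor
state pair (`energy_transfer_config()`).  The orientation factor κ² is
absorbed into R₀ (isotropic average), appropriate for freely rotating,
water-soluble cyanines.  Default radii are anchored to the observed
lifetime quenching of closely spaced dyes: at 3 nm spacing the cis pathway
produces a ~600 ps decay component (so R₀(on→cis) ≈ 3.4 nm against τ₀ =
1.8 ns with one to two cis acceptors), the off-state adds a ~400 ps channel
in switching buffer (R₀(on→off) = 4.0 nm), and the short-lived triplet is a
minor channel (R₀(on→triplet) = 3.0 nm).  With these values, 3 and 6 nm
structures couple strongly while 9 and 18 nm spacings are near-independent.

**Quenched lifetimes.**  Each detected photon's microtime is drawn from the
exponential with `quenched_lifetime(τ₀, k_ET rates)` given the acceptor
states *at the instant of emission* (frozen per photon, not dwell-averaged),
then jittered by the Gaussian IRF and folded into the pulse period.  By
default the *brightness* is not rescaled by quenching — the emission rate is
`excitation_rate × quantum_yield × detection_efficiency` — so quenching is
visible in lifetime observables (FLIM maps, decay components) but does not
dim localizations; `sim_settings(quench_brightness = TRUE)` enables
quantum-yield dimming for sensitivity analyses.

**Off-state recovery.**  The rate at which donor excitations are funnelled
into an off-state acceptor j is the time-averaged, low-transfer-limit
expression `recovery_yield × excitation_rate × Σ_i (R₀/r_ij)⁶` summed over
current on-state donors (this is what `joint_transition_rates()` reports;
note it preserves the pure r⁻⁶ distance scaling, e.g. a factor (18/3)⁶
between 3 and 18 nm).  Near r < R₀ the linearization overestimates
transfer; for the geometries shipped here that regime is only entered at
3 nm, where recovery is saturated anyway.

**Delayed conversion.**  The off-state is a metastable chemical species;
its regeneration to the fluorescent state after absorbing transferred
energy is a chemical conversion (adduct cleavage or radical oxidation), not
an instantaneous electronic transition.  The simulator therefore moves an
energy-transfer-excited off-state into an internal *primed* sub-state that
completes conversion with mean `recovery_delay` (default 20 ms; 0 restores
instantaneous recovery).  This choice matters for what a camera sees.  If
recovery were instantaneous, a recovered fluorophore would always light up
*while its donor is still on*, so recovery could only extend existing
bright runs — it could merge events and burn the switching budget, but
never create the separately detected, rapidly repeated on-events that
closely spaced structures show.  With a conversion time of a few camera
frames, recovered fluorophores light up shortly *after* a donor event,
producing the characteristic population of short off-times at small
distances.  The default 20 ms (4 frames at 5 ms) is a model choice on a
timescale the source experiments do not resolve; the qualitative
fingerprint ordering is insensitive to it within roughly a factor of a few.

`recovery_yield = 2e-4` places the coupling regimes where the experiments
place them: at 3 nm a donor event primes its off neighbours essentially
always (dense event trains until the structure bleaches), at 6 nm with
order-one probability (visible chains of recovery events), at 9 nm
occasionally (~10 % of events), and at 18 nm negligibly.

## The simulator

`simulate_trajectory()` samples the coupled continuous-time Markov chain
exactly (Gillespie: exponential waiting times from the summed rates,
categorical channel choice), with the off→on recovery rates updated as
donors enter and leave the on-state.  Dwell times span microseconds
(cis/triplet) to tens of seconds (off), which is why an exact event-driven
scheme is used rather than fixed-step discretization.  All fluorophores
start in the on-state: at the beginning of a real acquisition everything
is fluorescent, and the initial collective decay into the dark state is
part of the fingerprint (it is what front-loads the 3 nm curves).

Photons are generated within ON dwells as a Poisson process at the
detected rate, with Bernoulli(½) detector routing (Hanbury Brown–Twiss
split), microtimes as above, quantized to 25 ps within a 12.5 ns pulse
period (80 MHz).  Background counts (default 100 /s per channel) carry
uniform macrotimes, microtimes and positions.

`render_frames()` integrates photons into camera frames (a photon at time
t belongs to frame ⌊t/frame_time⌋).  Emitters within `merge_radius`
(default 200 nm) always merge into one candidate spot — a diffraction-
limited camera cannot resolve them — positioned at the photon-weighted true
centroid plus Gaussian localization jitter with σ = `psf_sigma/√N`
(default) or the Mortensen formula (`precision_model = "mortensen"`).
Every spot with ≥1 photon is emitted; photon thresholds are an analysis
step, not a rendering step.  `generate_dataset()` arranges structures on a
≥1 µm grid (no optical cross-talk) and records full ground truth.

**DNA-PAINT mode** replaces photophysics with binding kinetics: each
docking site binds imager strands as an independent telegraph process
(Poisson arrivals, default 0.005 /s as for ~5 nM imager; exponential
bright times, default 0.5 s), with no energy transfer and no bleaching.
Its fingerprints are distance-independent by construction — the
experimental control that separates photophysical coupling from geometry.

## Fingerprint conventions

`fingerprint_table()` chains the analysis: photon filtering (strictly
greater than 500 photons/frame for dSTORM, 6 000 for DNA-PAINT), track
linking, per-track statistics, aggregation.

* **Linking**: structures are immobile, so tracks are built by greedy
  agglomerative spatial clustering on (x, y), ignoring time: a
  localization joins the nearest existing track whose running centroid is
  within the 200 nm tracking radius, else seeds a new track; ties break by
  distance then lowest track id.  (Kalman-filter trackers used for mobile
  emitters reduce to this on stationary targets; on well-separated
  structures the assignments are identical.)  Same-frame localizations of
  one track merge with photons summed.
* **On-time**: length of a maximal run of consecutive frames with a
  localization.  A single-frame blip is a valid on-event.
* **Off-time**: `start − end − 1` frames — the frames with no localization
  strictly between two events.  The conventions tile exactly:
  Σon + Σoff + leading + trailing frames = total frames.
* **Intensity**: mean photons per on-frame, reported per millisecond
  (off-frames are not averaged in).
* **T80**: the time at which the cumulative localization count first
  reaches 80 % of the track's total (ceiling convention, well-defined for
  small counts).  `t80_from_curve()` on the track's cumulative curve gives
  the identical value.
* **Aggregation** reports normalized histograms ("relative occurrence",
  summing to one) and medians; medians, not means, are the headline
  statistics because event-count and dwell distributions are heavily
  skewed.

Whether per-spot intensity should average over on-frames only or over all
frames is ambiguous in common usage; this package averages over on-frames
and says so here.

## Intensity traces and autocorrelation

`bin_photons()` bins macrotimes into 1 ms bins by default.  Two G(τ)
estimators are exposed, both defined bit-exactly as
`G(τ) = mean(I_t I_{t+τ}) / (mean(I_head) mean(I_tail))` (symmetric
normalization):

* `autocorrelate_trace()` — direct evaluation at explicit lags, for short
  traces and closed-form comparisons;
* `autocorrelate_photons()` — multiple-tau estimator, 8 points per octave
  with factor-two coarsening, spanning µs–s as photon streams require.

Curves can be normalized to their value at a reference lag (1 ms
convention) for trajectory comparisons.  `segment_on_off()` uses threshold
segmentation (default: mean + 3 sd of the lowest-decile bins), matching
how dwell structure is read off trajectories by eye; an HMM would be a
natural extension but is not implemented.

## TCSPC decay fitting

`fit_decay()` minimizes Neyman-weighted least squares
(σ² = max(count, 1)) of the model
`background + Σ aᵢ (IRF ⊛ exp(−t/τᵢ))` with Levenberg–Marquardt
(`minpack.lm`).  For the Gaussian IRF (default FWHM 200 ps) the
convolution has the closed exponentially-modified-Gaussian form, evaluated
in log space (`pnorm(..., log.p = TRUE)`) for stability at large
arguments, and wrapped across the pulse period (at 80 MHz, 12.5 ns is not
long against ~7τ, so periodic reconvolution is on by default; wraps −1…3
cover the tail to < 10⁻⁶).  Lifetimes and component photon numbers are
fitted on the log scale, so positivity holds by construction; amplitude
fractions are normalized to Σaᵢ = 1 and components sorted by lifetime.
The amplitude-weighted average lifetime is τ_av = Σ aᵢτᵢ.  A fitted
component below twice the bin width is flagged `unresolvable` rather than
reported as physical.  Model selection (`n_components = "auto"`) accepts
the monoexponential fit iff χ²_red < 1.3 and the weighted residuals pass a
runs test at α = 0.05 — an explicit rule standing in for the usual "the
simpler model was adequate" judgment.

`flim_fast_lifetime()` serves FLIM-style maps recorded at ~5 µs per pixel,
where photon counts cannot support fitting: the mean microtime minus the
IRF origin, clamped at zero, unbiased for monoexponential decays when the
period is long against the lifetime, with low-count pixels masked.

## Antibunching analysis

`coincidence_histogram()` histograms cross-channel photon-pair delays
(channel 0 vs channel 1 only; using both detectors avoids dead-time
artifacts).  Under pulsed excitation the histogram is a comb at multiples
of the pulse period.  `nc_nl_ratio()` integrates peak windows of one full
inter-pulse interval centered on each peak — the windows tile the delay
axis, which is robust to timing jitter (a narrow-window mode is available
through the bin grid).  For N equal, independent emitters in the
low-excitation limit, the central-to-average-lateral ratio is
`expected_ratio(N) = (N−1)/N` (0, 0.5, 0.67, 0.75 for N = 1–4): a
same-pulse pair requires two distinct emitters while lateral pairs do not.
Because measured ratios fall between these discrete values whenever
emitters are partially coupled, the result reports the bracketing pair of
emitter numbers rather than forcing an integer.  Background correction
(flat-baseline subtraction from the outer quarters of each window) is off
by default — the conventional ratios neglect background — and the finite
emission lifetime leaks a small fraction of consecutive-pulse pairs into
the central window (~e^(−T/2τ)/2), which is why idealized comparisons in
the tests use sub-nanosecond delays.

## What the generator emulates, and what it does not

The simulator reproduces: coupled blinking kinetics and their distance
dependence; photon statistics at the detector (shot noise, background,
50:50 splitting, TCSPC quantization); camera integration and localization
jitter; DNA-PAINT binding kinetics; receptor-stoichiometry scenarios
(1, 2 at ~5 nm, 4 at ~7 nm).  It does not emulate: pixelated EMCCD images
or PSF fitting (it works at the localization-table level); stage drift;
dye orientation heterogeneity (κ² is averaged); spectral changes of the
dark states; detector afterpulsing; sample-to-sample labeling
incompleteness.  Passing tests therefore validate the analysis chain and
the model's internal consistency against real blinking *statistics*, not
against raw camera movies.

## Numerical choices and problem sizes

Frames are 0-based; intervals are half-open `[start, end)`; coordinates
are nm; times s (TCSPC quantities ns/ps).  All stochastic entry points
take explicit seeds and are deterministic given them.  The test-suite
problem sizes are chosen to give clear statistical separation at
interactive runtimes: 50 structures per origami template at 120 000
frames × 5 ms for the distance series, 40 per receptor template, 10⁶
photons for decay-fitting recovery, 10⁶ pulses for antibunching Monte
Carlo, 100 s of telegraph signal for autocorrelation, and ≥500 pooled
dwells for distribution tests.

## Known limitations

* The off-state recovery rate uses the linearized low-transfer limit and
  a single generic off-state; recovery saturation and multi-step dark-state
  chemistry are folded into two effective parameters (`recovery_yield`,
  `recovery_delay`).
* The greedy tracker assumes immobile structures; it is not suitable for
  mobile emitters.
* Threshold segmentation of traces underestimates dwell times when dwells
  approach the bin width; keep dwells ≳10 bins.
* The mean-arrival FLIM estimator is biased low for multi-exponential
  pixels and biased by background; it is a mapping tool, not a fitting
  substitute.
* `expected_ratio()` assumes equal, independent emitters in the
  low-excitation limit; partially coupled systems legitimately fall
  between the discrete values, which is why only brackets are reported.
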