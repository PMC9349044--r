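# switchprint

Photoswitching fingerprint analysis for sub-10-nm single-molecule
localization microscopy (SMLM), with a distance-coupled photophysics
simulator.

## The problem

dSTORM routinely localizes single fluorophores with 1–5 nm precision, yet
structures whose fluorophores sit less than ~10 nm apart image poorly.
The cause is not localization precision but localization *probability*:
within Förster range, an on-state donor excites the overlapping absorption
of its neighbours' dark states (the long-lived off-state, the cis isomer,
the triplet), pumping them back toward the fluorescent state.  Blinking
accelerates, and the limited photoswitching budget of each dye is burned
in the first seconds of the experiment.  The flip side: the blinking
statistics of a diffraction-limited spot — its *photoswitching
fingerprint* — encode both the number of fluorophores and their distances
in the sub-10-nm range.

`switchprint` is for microscopists and method developers who want to read
those fingerprints out of standard SMLM data products, and to study the
underlying photophysics in simulation:

* **fingerprint** — on-times, off-times (gap = start − end − 1 frames),
  on-event counts, intensity (photons ms⁻¹ over on-frames), cumulative
  localization curves and T80 (time to 80 % of localizations), from
  localization tables (ThunderSTORM-style CSV headers accepted);
* **timetrace** — 1-ms binned intensity trajectories, direct and
  multiple-tau autocorrelation G(τ) (normalized at 1 ms), threshold
  on/off segmentation;
* **pulsefit** — TCSPC decay histograms (25 ps bins), multiexponential
  lifetime fitting by least-squares IRF reconvolution (Neyman weights,
  reduced χ², periodic wrap at 80 MHz), amplitude-weighted
  τ_av = Σ aᵢτᵢ, and a fast mean-arrival-time estimator for FLIM maps;
* **antibunch** — cross-channel interphoton-time (coincidence) histograms,
  the central-to-lateral peak ratio N_c/N_l,av (average of the nearest
  eight lateral peaks), and the emitter-number bracket from
  (N−1)/N = 0.0, 0.5, 0.67, 0.75 for N = 1–4;
* **blinksim** — an exact Gillespie simulator of coupled photoswitching
  (states ON/CIS/TRIPLET/OFF/BLEACHED; photo-driven rates
  k_exc × yield; Förster coupling k_ET = (1/τ₀)(R₀/r)⁶ per state pair;
  energy-transfer recovery of the off-state with a finite conversion
  time), producing photon streams, camera-frame localization tables, and
  DNA-PAINT-mode controls whose kinetics are geometry-independent.

## Worked example

```r
library(switchprint)

# simulate ten 4xCy5 DNA origami at 3 nm and at 18 nm spacing (dSTORM mode:
# 120,000 frames x 5 ms) and fingerprint the localization tables
fp <- lapply(c(origami_3nm = "origami_3nm", origami_18nm = "origami_18nm"),
             function(tpl) {
  ds <- generate_dataset(tpl, "dstorm", n_structures = 10, seed = 1)
  fingerprint_table(ds$localizations, frame_time = 0.005, min_photons = 500)
})
for (nm in names(fp)) {
  agg <- fp[[nm]]$aggregate
  cat(sprintf("%-12s median off-time %6.2f s | on-events %2.0f | T80 %5.1f s\n",
              nm, agg$medians["off_time"], agg$medians["on_events"],
              median(sapply(fp[[nm]]$summaries, `[[`, "t80"))))
}
#> origami_3nm  median off-time   0.03 s | on-events 18 | T80   2.3 s
#> origami_18nm median off-time   9.31 s | on-events 27 | T80 374.6 s
```

At 18 nm the four dyes blink independently: off-times of seconds, events
spread over the whole acquisition (late T80).  At 3 nm, energy-transfer
recovery of the off-state compresses the same switching budget into rapid
event trains — off-times collapse to tens of milliseconds and 80 % of the
localizations arrive within the first seconds.

```r
# photon antibunching: how many independent emitters?
ph <- simulate_pulsed_emitters(1e6, n_emitters = 4, p_emit = 0.05, seed = 2)
nc_nl_ratio(coincidence_histogram(ph))
#> Antibunching: Nc = 7381, Nl,av = 9919.0, Nc/Nl,av = 0.744
#>   consistent with 3 - 4 independent emitter(s)

# TCSPC lifetime of a quenched (biexponential) decay
mt <- simulate_decay_photons(1e6, taus = c(0.4, 1.8), amplitudes = c(0.4, 0.6),
                             seed = 3)
fit_decay(build_decay(mt), irf_gaussian(fwhm_ns = 0.2, t0_ns = 1), "auto")
#> TCSPC reconvolution fit: 2 component(s)
#>   tau1 = 0.401 ns  (a = 0.400)
#>   tau2 = 1.793 ns  (a = 0.600)
#>   tau_av = 1.237 ns, chi2_red = 1.068, t0 = 0.999 ns
```

A command-line interface wraps the same functions
(`exec/switchprint`): subcommands `simulate`, `fingerprint`, `trace`,
`lifetime`, `antibunch` and `demo` (a miniature end-to-end reproduction of
the origami distance series and the receptor stoichiometry scenarios).

```sh
Rscript exec/switchprint simulate --template origami_3nm --mode dstorm \
        --n 50 --seed 7 --out out/
Rscript exec/switchprint fingerprint out/localizations.csv --mode dstorm \
        --out out/fingerprint
```

The methods vignette
(`vignettes/photoswitching-fingerprints.Rmd`) documents the state model,
the energy-transfer coupling, every estimator's exact definition, the
default parameter values with units and rationale, and known limitations.

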