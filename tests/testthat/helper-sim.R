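# shared fixtures: small, fast simulation configurations

# rates sped up for unit tests: short off-times and early bleaching keep
# trajectories small while preserving the model structure
fast_rates <- function(...) {
  rate_constants(photoactivation_rate = 0.5, ...)
}

single_fluor <- function() emitter_geometry(rbind(c(0, 0)))

# tiny deterministic localization table
toy_locs <- function(frames, photons = 1000, x = 0, y = 0) {
  data.frame(frame = frames, x_nm = x + 0 * frames, y_nm = y + 0 * frames,
             photons = rep_len(photons, length(frames)))
}

# pooled completed OFF dwells from replicate single-fluorophore runs
pooled_off_dwells <- function(n_rep, duration, rates, seed0 = 5000) {
  unlist(lapply(seq_len(n_rep), function(s) {
    res <- simulate_trajectory(rates, single_fluor(), no_energy_transfer(),
                               duration, seed = seed0 + s, photons = FALSE)
    state_dwells(res, "OFF")
  }), use.names = FALSE)
}
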