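# shared fixtures: published presets and small synthetic inputs

tbl1 <- pk_preset("table1-verbatim")

# a small, fully synthetic parameter set with round numbers, handy when a
# test wants to reason about the arithmetic by hand
toy_params <- function(k_o = 100, decay_const = 0.024, k_elim = 0.02,
                       V_d = 1e5, ...) {
  drug_params("TOY",
    k_o = k_o, Cl = V_d * k_elim / 1000, t_half = log(2) / k_elim,
    k_elim = k_elim, V_d = V_d, decay_const = decay_const,
    conc_unit = "ng/mL", therapeutic_low = 0.5, therapeutic_high = 2,
    ...
  )
}

# single patch applied at 0 and never removed
one_patch <- function(horizon = 1000) {
  regimen(patch_event(0, "apply_new"), horizon = horizon)
}

# sub-therapeutic onset delay for NGMN after a partial detachment at t0:
# hours from detachment until the trajectory first crosses below `low`
detachment_onset <- function(params, t0, area_fraction = 0.5,
                             duration = 90, low = 0.6) {
  reg <- detachment(t0, area_fraction, duration)
  s <- simulate_difference(params, reg, sim_grid(0.1, reg$horizon))
  rw <- range_crossings(s, low, params$therapeutic_high,
                        span = c(t0, t0 + duration))$risk_windows
  if (nrow(rw) == 0) Inf else rw$start[1] - t0
}
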