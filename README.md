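# patchpk

One-compartment pharmacokinetic modelling of the weekly transdermal
contraceptive patch (norelgestromin/ethinylestradiol, the Ortho Evra
combination), for pharmacometricians and modellers who want to simulate
serum hormone profiles under compliant and non-compliant wear, estimate
the model's kinetic constants from concentration data, and quantify time
spent inside the contraceptively effective serum band.

## The model

Each hormone's serum concentration `C(t)` evolves in a single well-mixed
plasma compartment under two streams:

    dC/dt = f(t) * (k_o / V_d) * exp(-λ·s(t))  −  k_elim * C(t)

* `k_o / V_d` — release rate of a fresh patch over the volume of
  distribution (NGMN in ng/mL/h, EE in pg/mL/h),
* `λ` — an empirical attenuation constant (`α` for NGMN, `β` for EE)
  lumping patch depletion and skin saturation; `s(t)` is the *patch age*,
  which resets when a patch is replaced but not when a detached patch is
  pressed back on,
* `f(t)` — the attached fraction of the contact area (partial detachment
  scales absorption proportionally),
* `k_elim = ln2 / t_half` — first-order elimination.

Trajectories are integrated by the model's native forward-difference
scheme (`simulate_difference()`, default Δt = 0.1 h) and cross-checked
against the exact piecewise closed form (`simulate_analytic()`).
Regimens are event timelines (`apply_new`, `replace`, `detach`,
`reattach`, `remove`) with constructors for the standard 3-week cycle
and the classic non-compliance scenarios (delayed replacement, partial
or total detachment). Estimators recover `k_elim` from the post-removal
terminal slope (log-linear OLS) and the attenuation constant by bounded
scalar least squares; a synthetic-data module generates sparse noisy
"clinical" sampling for parameter-recovery testing.

## Worked example

```r
library(patchpk)

pars <- pk_preset("table1-verbatim")   # published kinetic constants
reg  <- standard_cycle()               # apply 0 h, replace 168/336 h, remove 504 h
g    <- sim_grid(dt = 0.1, horizon = 600)

ngmn <- simulate_difference(pars$NGMN, reg, g)
pk_summary(ngmn, pars$NGMN)
#> <pk_summary> NGMN
#>   C_ss           0.7845 ng/mL
#>   AUC/week      100.39, 131.29, 131.80 (mean 121.16 ng/mL*h)
#>   t_half         28.41 h
#>   time in range  445.5 h; 1 risk window(s), 0 overexposure window(s)

ee <- simulate_difference(pars$EE, reg, g)
pk_summary(ee, pars$EE)
#> <pk_summary> EE
#>   C_ss           54.62 pg/mL
#>   AUC/week      7774.3, 9174.3, 9176.5 (mean 8708.3 pg/mL*h)
#>   t_half         18 h
#>   time in range  488.37 h; 1 risk window(s), 0 overexposure window(s)
```

Reading the output: `C_ss` is the third-week time-averaged plateau —
0.78 ng/mL NGMN and 54.6 pg/mL EE, against reference values of
0.83 ± 0.21 and 56.7 ± 22.6 — and the weekly AUCs show the ramp-in of
week 1 (the drug-naive start) followed by two essentially identical
established weeks. The single "risk window" for each hormone is the
first hours of week 1, before concentrations first climb into the
therapeutic band (0.6–1.2 ng/mL NGMN, 25–75 pg/mL EE); after that both
hormones stay in range for the whole compliant cycle.

Estimating `k_elim` back from the post-removal decay phase:

```r
tt   <- seq(510, 576, by = 6)           # 12 samples after the 504 h removal
full <- simulate_analytic(pars$NGMN, reg, g)
dec  <- conc_series(tt, approx(full$times, full$values, tt)$y, "ng/mL")
fit_kelim(dec)
#> <fit_result> k_elim = 0.0244 1/h  (se 4.35e-18)
#>   RSS = 9.736e-31  on 12 points
```

Non-compliance, e.g. half the patch area lost at the end of day 3 for a
day:

```r
reg <- detachment(detach_time = 72, area_fraction = 0.5, duration = 24)
s   <- simulate_difference(pars$NGMN, reg, sim_grid(0.1, reg$horizon))
range_crossings(s, 0.6, 1.2, span = c(72, 96))  # risk windows during detachment
```

A configuration-driven pipeline (`load_config()` + `run_pipeline()`)
writes trajectory CSVs, a PK-summary JSON and a manifest for a whole
scenario in one call; a thin CLI wrapper for shell use lives at
`inst/cli/patchpk.R` (subcommands `simulate`, `scenario`, `fit`,
`metrics`, `synth`).

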