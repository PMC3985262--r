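---
title: "A one-compartment model of hormone release from a weekly contraceptive patch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A one-compartment model of hormone release from a weekly contraceptive patch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchpk)
```

## The model

The weekly transdermal contraceptive patch delivers two hormones —
norelgestromin (NGMN, the progestin) and ethinylestradiol (EE, the
estrogen) — through the skin into systemic circulation. `patchpk` treats
the body as a single well-mixed plasma compartment per hormone. Two
streams act on the serum concentration $C(t)$:

* **absorption** from the patch, at a rate that starts at $k_o/V_d$ when a
  fresh patch is applied and attenuates exponentially with patch age $s$,
  scaled by the attached fraction $f$ of the 20 cm² contact area:
  $$R_{abs}(t) = f \, \frac{k_o}{V_d}\, e^{-\lambda s(t)},$$
* **first-order elimination**, $R_{elim}(t) = k_{elim}\, C(t)$.

so that $dC/dt = R_{abs} - R_{elim}$. The attenuation constant $\lambda$
(conventionally written $\alpha$ for NGMN and $\beta$ for EE) does not
represent a single physical mechanism: it lumps depletion of the hormone
reservoir, progressive saturation of the stratum corneum, and changes in
patch permeability into one empirical decay. The model deliberately skips
diffusion through the individual patch and skin layers; the lumped
exponential is the entire absorption description, which is what makes the
model tractable and its two attenuation constants the only quantities
that ever need fitting.

Patch *age*, not cycle time, drives the attenuation: the release rate is
restored to $k_o/V_d$ each time a fresh patch goes on (`apply_new` or
`replace` events), while a patch that is pressed back after a partial
detachment (`reattach`) has kept aging in the meantime. This distinction
matters for the non-compliance scenarios below.

## Parameters

The shipped presets (`pk_preset()`) carry the published constants:

| quantity | NGMN | EE | unit |
|---|---|---|---|
| $k_o$ | 150 (updated: 200) | 20.5 (updated: 35) | µg/day |
| $Cl$ | 7.89 | 18.3 | L/h |
| $t_{1/2}$ | 28.4 | 15.2 | h |
| $k_{elim}$ | 0.0244 | 0.0385 | 1/h |
| $V_d$ | 323,300 | 401,385 | mL |
| $\lambda$ | 0.0028 | 0.0034 | see below |
| therapeutic band | 0.6–1.2 ng/mL | 25–75 pg/mL | |

Internally all kinetics run in hours; $k_o$ is divided by 24 on ingestion
and concentrations stay in each hormone's conventional serum unit (ng/mL
for NGMN, pg/mL for EE) end to end, with unit mismatches treated as
errors rather than silently converted.

Two published irregularities are surfaced rather than hidden:

1. **The EE row is internally inconsistent.** Its printed $k_{elim}$
   (0.0385/h) does not equal $\ln 2 / t_{1/2} = 0.0456$/h, and its
   printed $V_d$ equals $Cl/(\ln 2 / t_{1/2})$, not $Cl/k_{elim}$. The
   default `"table1-verbatim"` preset keeps the printed numbers and flags
   the object `consistent = FALSE`; `"halflife-consistent"` rederives
   $k_{elim}$ and $V_d$ from the half-life for users who prefer a
   self-consistent set.
2. **Two release rates are in circulation** — the original label values
   (150/20.5 µg/day) and the manufacturer's updated averages
   (200/35 µg/day). Both are available (`"table1-verbatim"` vs
   `"updated-k0"`); the verbatim set is the default because it is the one
   that reproduces the reference plateau concentrations and weekly AUCs
   (see below).

### The attenuation-constant unit

The constants 0.0028 and 0.0034 were published without units, and the
choice matters enormously: read per day, absorption falls only ~2% over a
week of wear; read per hour, ~38%. `patchpk` defaults to **per day**
(`decay_unit = "1/day"`) because only that reading reproduces the
reference pharmacokinetics of a compliant cycle — the NGMN plateau of
about 0.77 ng/mL and mean weekly AUC near 123 ng·h/mL (per hour, the
week-long plateau collapses and the plateau average drops ~18% below the
reference). The per-hour reading remains available on every constructor
and in configurations because the delayed-replacement behaviour reported
for this patch — NGMN sagging below its effective bound when a patch is
worn days past its scheduled replacement — only materialises when wear
attenuates absorption on an hourly scale. No single reading reproduces
both the compliant-cycle table and all non-compliance window durations;
the package therefore pins the default to the reading validated by the
quantitative table and runs the delayed-replacement window analysis under
the explicit per-hour override, asserting orderings and band membership
rather than exact window lengths. The printed durations (22 h, 26 h,
34 h, 14 h) should be treated as convention-dependent illustrations, not
reproducible constants.

## Numerics

`simulate_difference()` advances the explicit forward difference
$$C(t+\Delta t) = C(t) + \left[R_{abs}(t) - k_{elim} C(t)\right]\Delta t$$
with $\Delta t = 0.1$ h by default, mirroring the model's native
difference-equation form. Steps are restricted to $\Delta t \le 1$ h and
$\Delta t < 1/k_{elim}$ (beyond which the scheme would oscillate
negative; the package raises an error instead of clipping). Round-off
negatives are clipped to zero with a warning; they do not occur for the
shipped parameter sets.

`simulate_analytic()` is the accuracy oracle: between regimen events the
ODE is linear with constant coefficients, so the solution over an
interval of length $\tau$ starting at concentration $C_0$ and patch age
$s_0$ is
$$C_0 e^{-k\tau} + f\,\frac{k_o}{V_d} e^{-\lambda s_0}
  \frac{e^{-\lambda\tau} - e^{-k\tau}}{k-\lambda},$$
chained exactly across events (the limiting form
$f (k_o/V_d) e^{-\lambda s_0}\,\tau e^{-k\tau}$ is used when
$|k - \lambda|$ falls below $10^{-8}\,\max(k,\lambda)$). The difference
scheme is first order: its maximum deviation from the closed form over a
full cycle is about $3.6\times10^{-4}$ ng/mL at $\Delta t = 0.1$ h and
halves when $\Delta t$ halves.

Therapeutic-band crossings are located by linear interpolation between
grid points (`range_crossings()`), consistent with the first-order
accuracy of the integrator; AUCs are trapezoidal with interpolated
endpoints, which makes them exactly additive over abutting windows.

### Reporting conventions

The reference table this model is checked against never states its
averaging conventions, so the package fixes them once:

* **Plateau concentration** `css()`: time average over the third wear
  week (hours 336–504), the fully established weekly pattern. The window
  is an argument for users who prefer another convention.
* **Weekly AUC**: the AUC of each 168 h week is reported individually and
  the *mean over the three weeks* is the headline value, which best
  matches the reference predictions under the model (week 1 is depressed
  by the ramp-in from the drug-naive start).

## Estimation

* `fit_kelim()` — the terminal slope: after the final removal the model
  decays purely exponentially, so ordinary least squares of $\ln C$ on
  $t$ estimates $-k_{elim}$. Unweighted OLS is used, matching the
  conventional straight-line linearisation of post-removal data.
* `derive_vd()` — $V_d = Cl / k_{elim}$.
* `fit_decay_const()` — with every other constant fixed from independent
  sources, $\lambda$ is the model's only free parameter. It is estimated
  by bounded scalar least squares (Brent's method on
  $[0, 10\lambda_{preset}]$ against the closed-form trajectory), which is
  deterministic — no multi-start heuristics. An optimum pinned at a bound
  is flagged `converged = FALSE` (constant-zero data, for instance, push
  the estimate to the upper bound).

**Identifiability caveat.** Under the default per-day reading, a week of
wear attenuates absorption by only ~2%. Against 5% multiplicative assay
noise and a realistic sampling budget (a few dozen points), that signal
is below the noise floor: across 200 simulated datasets (CV = 0.05,
n = 20) only ~19% of estimates of $\alpha = 0.0028$/day fall within 25%
of the truth, and no estimator could do fundamentally better at that
design. The same experiment under the per-hour reading (signal ~38% per
week) recovers the constant within 25% essentially always. Parameter-
recovery tests therefore exercise the noiseless per-day case (exact
recovery) and the noisy per-hour case (informative recovery); a noisy
per-day fit should be interpreted as bounded above, not estimated.

## Synthetic data

`generate_observations()` emulates the sparse serum sampling of clinical
patch studies: the exact model trajectory evaluated at the design times,
multiplied by independent lognormal noise with mean 1 and CV 0.05 by
default (assay error in this concentration range is roughly
proportional). The default schedule samples every 12 h during wear and
every 6 h during the post-removal decay, the resolution at which weekly
patch PK profiles are typically reported. Draws are made under an
isolated, design-carried seed, so identical designs are bit-reproducible
and the caller's RNG stream is untouched.

What the generator does *not* emulate — and hence what passing
recovery tests do not establish about clinical data: between-subject
variability (it is a single-individual model), assay quantification
limits and censoring, time-varying compliance within a wear interval,
and any model misspecification (the noise is generated from the same
one-compartment model that is then fitted).

## Non-compliance scenarios

Three parameterised constructors cover the deviations of practical
interest, all expressed as event timelines over a 504 h cycle with a
96 h observation tail:

* `standard_cycle()` — apply at 0, replace at 168 and 336, remove at
  504 h.
* `delayed_replacement(delay_days)` — the day-14 replacement slips by
  whole days (a missed replacement is the same timeline); day counts map
  as day $n$ → $24n$ h.
* `detachment(detach_time, area_fraction, duration, reattach_as_new)` —
  partial or total loss of contact area within one wear week. "End of
  day three" maps to $t = 72$ h. After a prolonged *total* detachment
  the manufacturer instructs a fresh patch, so `reattach_as_new = TRUE`
  resets the patch age; re-adhering the same patch
  (`reattach_as_new = FALSE`, the default) does not — the patch kept
  depleting while dangling. Which behaviour the original scenario
  simulations assumed is not recorded, so both are exposed.

Properties that are robust across the unit conventions, and are asserted
as such in the test suite: the sub-therapeutic onset after a 50%
detachment comes later in weeks 2–3 than at 72 h of week 1 (serum levels
start higher); an earlier week-1 detachment (48 h) leaves a shorter safe
window than one at 72 h; and the onset moves earlier as the detached
fraction grows.

## Problem sizes and runtime

The shipped tests and the acceptance script simulate single cycles of
504–600 h at $\Delta t = 0.1$ h (5,000–6,000 steps; the oracle-agreement
check refines to $\Delta t = 0.01$ h, ~60,000 steps) and Monte-Carlo
checks use 200–1,000 replicate draws. These sizes hold every check well
under a second to a few seconds while leaving discretisation error two
orders of magnitude below the tolerances being asserted.

## Known limitations

* One compartment, single individual: no distribution phase, no
  population variability, no pharmacodynamics (ovulation or pregnancy
  risk are out of scope).
* The lumped exponential absorption term has no mechanistic
  interpretation; extrapolating far beyond a 3-week wear (patch ages
  ≫ 168 h) extrapolates an empirical fit.
* The published constants embed the inconsistencies described above; the
  package preserves them verbatim by default and flags them, but cannot
  resolve which convention generated every published figure.
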