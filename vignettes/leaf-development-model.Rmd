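---
title: "The phyllosim leaf development model: equations, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The phyllosim leaf development model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllosim)
```

## The model in brief

phyllosim treats the maize shoot as a stack of leaves that develop on a
shared thermal-time clock but grow independently. Thermal time is the
universal developmental clock: every rate in the model is expressed per
degree-day (°Cd), and calendar days only matter through the daily
equivalent thermal time `dtt`. This gives the model its central
invariance, which the test suite checks explicitly: delivering the same
total thermal time faster or slower changes the calendar trajectory but
not the thermal-time-indexed leaf profiles.

Three groups of quantities drive one plant:

* **Ten genotypic parameters** (`genotype_parameters()`): final leaf
  number `n_final`; slope and intercept of the tip-appearance regression
  (`a_tip` — the phyllochron, °Cd leaf⁻¹ — and `b_tip`, °Cd); slope and
  intercept of the pre-breakpoint ligulation regression (`a_ll1`,
  `b_ll1`); the maximum elongation rate of leaf 6 (`a6`, mm °Cd⁻¹) with
  its sensitivities to vapour pressure deficit (`b`, mm °Cd⁻¹ kPa⁻¹,
  typically negative) and soil water potential (`c`, mm °Cd⁻¹ MPa⁻¹,
  typically positive); and the leaf-6 width at reference light (`w6`, mm)
  with its radiation sensitivity (`r_rad`, mm MJ⁻¹).
* **Twelve species constants** (`species_constants()`), shared by all
  genotypes but overridable: the slope ratios and breakpoints of the
  event regressions (`k_bl` = 0.708 above rank `n_bl_lim` = 6;
  `k_ll` = 0.454 above rank `alpha_ll`·`n_final` with
  `alpha_ll` = 0.52), the ligule lag `a_lag` = 5.4 °Cd leaf⁻¹, the
  top-rank synchrony count `n_last` = 2, the widening lag
  `lag_w` = 39 °Cd, the two rank-bell shapes
  (`beta_l` = 0.68, `sigma_l` = 0.46 for elongation;
  `beta_w` = 0.41, `sigma_w` = 0.69 for width) and the radiation base
  `rad_base` = 0.15 MJ plant⁻¹ d⁻¹.
* **Daily forcing** (`environment_series()`): temperature, VPD (kPa),
  soil water potential (MPa, ≤ 0) and plant-intercepted radiation
  (MJ plant⁻¹ d⁻¹).

The per-rank event schedule (`build_schedule()`) consists of two
continuous piecewise-linear regressions in rank (beginning of elongation,
ligulation), the tip regression, the lagged end of elongation with its
top-two-rank tie, and the widening window. Elongation integrates
`LER_norm(n) · max(0, a6 + b·VPD + c·PSI) · dtt` over the elongation
window; width is the rank bell plus `r_rad` times the window-mean
radiation excess over `rad_base`.

## Assumptions worth knowing

* **Linearity of the stress response.** The elongation rate is linear in
  VPD and PSI. Under extreme stress the linear combination can go
  negative; we clamp it at zero because leaf length must be
  non-decreasing in time. The clamp is the only nonlinearity added to the
  printed rate model.
* **No inter-leaf competition.** Leaves interact only through the shared
  schedule. There is no whorl competition, no assimilate budget.
* **Forcing is taken as given.** Meristem temperature, VPD and
  intercepted radiation are inputs; the package does not model the energy
  balance or light interception.
* **No photoperiod effect** on leaf number or timing; `n_final` is a
  parameter, not a prediction.

## Numerical choices

* **Thermal-time response.** A piecewise-linear response with cardinal
  temperatures 8/30/34/44 °C (base, optimum onset, optimum end, maximum),
  applied to sub-daily samples when available, otherwise to the daily
  mean, and averaged over the day. The cardinals are config-exposed
  (`thermal_config()`); the defaults are the usual maize values. Within
  the linear regime the daily value is exactly the mean exceedance of the
  base temperature, a property the tests rely on.
* **Pro-rated boundary days.** A day that straddles a window boundary
  contributes only the overlapping fraction of its thermal time. This
  removes step artefacts and makes the day-stepped integral agree with
  the closed-form rate × duration oracle to machine precision under
  constant forcing — an equality the acceptance suite checks across 100
  random genotypes.
* **Breakpoint convention.** The ligulation branch condition compares the
  integer rank directly with the real-valued breakpoint
  `alpha_ll · n_final` (8.32 for a 16-leaf plant); no rounding is
  applied, and the intercept construction makes both branches agree at
  the breakpoint to algebraic identity. `n_final ≥ 8` is required so both
  breakpoints lie strictly inside the rank range.
* **Widening-window radiation mean.** "Mean radiation from the start of
  widening to now" is implemented as the arithmetic mean of daily
  radiation over the days whose thermal-time midpoints fall inside the
  window. A window narrower than one day falls back to the day containing
  its midpoint. Width is floored at 1 mm (config-exposed) against extreme
  low light, and frozen when the window closes.
* **Width bell is not renormalised.** Unlike the elongation bell, which
  is scaled to exactly 1 at leaf 6, the width bell is used as printed, so
  `base_width(6)` differs from `w6` by up to ~0.2% for typical shapes.
  We keep the printed form rather than forcing the identity.
* **Radiation units.** All radiation quantities (`rad`, `rad_base`, the
  1.5 MJ reference for `w6`) are treated on the per-plant daily scale.
  The reference light is nominally a per-area standard; we do not attempt
  a conversion, and calibrations should supply radiation on the same
  scale they use for simulation.
* **Sensitivity scales.** The platform calibration estimates `b` and `c`
  on a relative scale (well-watered rate ≡ 1), and the empirical coupling
  `b_rel = 0.69 − 2.3·c_rel` is applied on that scale; the simulator's
  rate model needs absolute values, obtained by multiplying by `a6`
  (`to_absolute_sensitivities()`). Whether the published coupling was
  fitted on relative or absolute values is not fully documented; the
  relative-scale choice is internally consistent with an intercept of 1
  and is recorded here rather than certain.
* **Season boundaries.** Event times may fall outside the supplied
  weather series; the simulation clips to the available days and carries
  a truncation flag in the result instead of failing.

## Calibration procedures

* **Stage regressions.** Tip and ligule counts are interval-censored:
  plants are scored every couple of days, so an event is only known to
  lie between two scoring dates. We place each event where the linear
  interpolant of the counts crosses `k − 1/2` — the midpoint convention,
  which is the unbiased choice for an event uniformly located within its
  bracket — pool event times across plants, and fit ordinary least
  squares of event time on rank. The ligule regression uses only ranks at
  or below the breakpoint, since it parameterises the first segment.
  Censoring bounds what any estimator can do: with noise-free counts the
  recovered intercept can be off by up to half the scoring interval when
  events fall exactly on scoring dates; under timing noise the estimator
  is unbiased in expectation, which is what the round-trip tests assert.
* **Growth window and `a6`.** Dimension time courses are smoothed with
  `loess` (default span 0.5, the conventional setting for such curves;
  the synthetic pipeline uses 0.3 so the local window covers about nine
  scoring dates of its denser series), and the 5%/95% crossings of the
  plateau give the operational growth window. The plateau-stability check
  allows, besides a 5% relative variation, three residual standard
  deviations of the smoother — otherwise ordinary measurement noise at
  the series boundary masquerades as continued growth; a genuinely rising
  tail still fails. The `a6` slope is fitted inside the window, guarded by
  a 5–95% value range so corner points cannot flatten it, and must be
  measured under calm, well-watered conditions (otherwise it estimates
  the realised rate `a6 + b·VPD + c·PSI`).
* **Drydown sensitivity.** Normalised expansion rates are regressed on
  soil water potential with the intercept fixed at 1 by construction;
  self-normalisation uses records with `psi ≥ −0.1 MPa` as the
  well-watered baseline, which is only approximately the rate at zero
  potential — supplying an explicit well-watered rate is exact.
* **Flowering cross-validation.** `kfold_rmse()` uses a seeded,
  size-balanced random partition and reports RMSE over held-out
  predictions plus its coefficient of variation.

## What the synthetic generator does and does not emulate

`scenario_spec()`/`generate_environment()` produce constant, seasonal and
drydown forcing; the drydown reproduces the platform protocol's
two-plateau soil drying (−0.05 → −0.4 → −0.6 MPa, with multi-day ramps
and holds). `generate_observations()` emulates the observation protocol:
15 reference plants scored every second day for tip and ligule counts
(per-plant Gaussian event-time jitter, default sd 10 °Cd), and 10 plants
dissected per scoring date with 5% multiplicative dimension noise. The
dissection replicates matter: averaging ten plants per date is what makes
the 95% plateau crossing stable, exactly as in the protocol being
emulated. The noise defaults are invented fixtures — no measured error
model stands behind them — so passing round-trip tests demonstrates that
the procedures are consistent and unbiased under plausible noise, not
that they meet any particular accuracy on real field data. Real data also
differ in ways the generator ignores: spatially correlated weather
errors, destructive-sampling drift between dissected cohorts, missed
scoring dates, and genotype-by-environment interaction beyond the model's
three environmental drivers.

## Problem sizes in the shipped tests

The suites run a 16-leaf reference genotype over 60–90 day seasons,
1,000 random parameter draws for the continuity property, 100 random
genotypes for the integration oracle, and 100 seeded replicates of the
full simulate → observe → calibrate round trip; the whole suite completes
in well under a minute on a single core. These sizes were chosen as the
smallest that make the Monte-Carlo means meaningful at the asserted
tolerances.

## Known limitations

* No sub-daily elongation dynamics (circadian or hydraulic); the day is
  the time step.
* Width responds to intercepted radiation only — no evaporative-demand
  effect on widening, by design.
* The model does not predict `n_final` or flowering from the
  environment; the flowering regression quantifies the leaf-number ↔
  flowering-time association across genotypes, nothing more.
* Schedules with pathological parameters (empty elongation or widening
  windows) are rejected with an error naming the offending rank rather
  than silently clipped.
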