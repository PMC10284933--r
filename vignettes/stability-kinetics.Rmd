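---
title: "Kinetic stability modeling with stabkin: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic stability modeling with stabkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabkin)
```

## The model

`stabkin` describes the temperature-driven change of a stability-indicating
attribute (aggregate content, potency, infectious titer, charge variants,
relative fluorescence, ...) through a normalized degradation extent
$\alpha \in [0, 1]$. The observed rate is a weighted sum of two independent
one-step reactions, each with Arrhenius temperature dependence:

$$
\frac{d\alpha}{dt} =
  v\,A_1 e^{-Ea_1/RT}\,(1-\alpha_1)^{n_1}\,\alpha_1^{m_1}\,C^{p_1}
  + (1-v)\,A_2 e^{-Ea_2/RT}\,(1-\alpha_2)^{n_2}\,\alpha_2^{m_2}\,C^{p_2}.
$$

Each step carries its own sub-extent $\alpha_i$, evolved by its own rate
($d\alpha_i/dt = r_i$), and the observed extent is
$\alpha = v\alpha_1 + (1-v)\alpha_2$. This coupled-but-independent reading
is the only one under which the two-term rate expression is self-consistent:
each term depends only on its own step's progress, and differentiating
$\alpha = v\alpha_1 + (1-v)\alpha_2$ recovers the displayed sum exactly. A
plausible alternative — both terms sharing a single $\alpha$ — would make
the fast step's exhaustion depend on the slow step's progress, which is not
what a competitive-pathway picture intends; we document our convention
rather than assert it as the only possible one.

Special cases cover the classical phenomenology:

| structure | fixed | behaviour |
|---|---|---|
| zero-order | $n=0, m=0, v=1$ | linear |
| first-order | $n=1, m=0, v=1$ | decelerating exponential |
| nth-order | $m=0, v=1$ | decelerating, order fitted |
| autocatalytic | $v=1$, $n,m$ free | S-shaped (Prout–Tompkins type) |
| two-step | all free, $v$ free | fast-then-slow, biphasic, non-Arrhenius-looking |

The sum of two steps with different energy barriers also emulates apparent
non-Arrhenius behaviour of the observed attribute without abandoning
Arrhenius kinetics at the step level.

Parameters and units: time in **days**, temperature in **Kelvin**
internally (degC at every file boundary; 1 month = 30.4375 days). The fit
works with $\ln A$ (log of a per-day frequency factor) rather than $A$,
which keeps $A$ positive by construction and decorrelates the magnitudes,
and with $Ea$ in J/mol. The protein concentration $C$ is the value at the
start of the reaction — a per-dataset covariate, constant during
integration, used only when a concentration exponent $p$ is freed (the
high-concentration aggregation use case).

The attribute maps linearly to extent: $y = y_0 + d\,s\,\alpha$ with
baseline $y_0$ (default: the mean of the time-zero replicates), conversion
span $s > 0$ in attribute units, and direction $d = \pm 1$. The span is
supplied by the analyst (100 for percentage scales, the total
log-titer-loss span for titers, ...) because assay theory, not the data,
says what "full conversion" means; values slightly outside $[0,1]$ from
assay noise are deliberately not clipped before fitting.

## Study-design validation

Before any fit, `validate_design()` applies the accepted design rules for
predictive stability studies: at least 3 incubation temperatures (typically
5, 25 and 37/40 degC), at least 20 data points (30 preferred — between 20
and 30 the report carries a warning rather than a failure), and at least
20% conversion reached at the hottest arm. The 20% rule is interpreted on
the extent scale after the attribute transform — i.e. 20% of the conversion
span, which coincides with "20% of the Y-axis" for full-span percentage
attributes. All four thresholds are arguments with these defaults.

## Numerics

Sub-extents are propagated per step. On isothermal spans with $m = 0$ the
closed forms are used ($\alpha = \alpha_0 + kt$ capped at 1;
$1-(1-\alpha_0)e^{-kt}$; the general-$n$ power solution). Everything else —
autocatalytic steps and genuinely non-isothermal spans — uses an adaptive
embedded Cash–Karp Runge–Kutta 4(5) scheme (compiled, rtol $10^{-8}$, atol
$10^{-10}$, state clamped to $[0,1]$). The kinetic systems here are
non-stiff (bounded smooth rates on a bounded state), so an explicit
adaptive pair is the appropriate solver; the test suite cross-checks it
against an independent stiff-capable multistep solver (`deSolve::lsoda`) on
a two-step autocatalytic problem over a fluctuating profile, and against
the closed forms to $10^{-6}$ absolute over 3-year horizons.

When a step has $m > 0$, $\alpha^m = 0$ at $\alpha = 0$ and the reaction
could never start; sub-extents are therefore initialized at
$\alpha_0 = 10^{-8}$, the standard regularization in thermokinetic
software. `alpha0` is an argument everywhere it matters.

Temperature programs are piecewise-linear in time (`temperature_profile`),
with constant extrapolation beyond the last knot. Linear interpolation
between logger samples reflects smooth physical drift; a step-hold mode is
available for chamber programs and for exact piecewise-isothermal
arithmetic. The integrator always splits spans at profile knots so the
interpolation kink never sits inside a solver step.

## Fitting

`fit_model()` minimizes the unweighted residual sum of squares in extent
units across all isothermal arms simultaneously (per-arm inverse-variance
weights are available but off by default; plain least squares is the
standard practice here). The optimizer is Levenberg–Marquardt with
box bounds (`minpack.lm`), default bounds $Ea \in [10, 300]$ kJ/mol,
$n \in [0,3]$, $m \in [0,2]$, $v \in [0,1]$, $p \in [-2,3]$, and
$\ln A \in [-20, 130]$ (wide enough for any $Ea$ in range at plausible
rates). Starts are deterministic: a data-driven seed (crude per-arm rate
constants pushed through an Arrhenius regression; for the two-step
structure, a two-phase heuristic reading the fast step's plateau off the
coldest arm and the slow step off the hottest arm's late slope) followed by
a coarse grid over $Ea \in \{50, 80, 110, 140\}$ kJ/mol and
$k(40\,^\circ\mathrm{C}) \in \{10^{-3}, 3\times10^{-2}\}$/day, 8 starts by
default. Best residual sum of squares wins; ties go to the start converging
in fewer iterations. Because the starts are deterministic, a fit is
bit-reproducible and invariant to row order (up to optimizer floating-point
noise around $10^{-8}$ relative).

Fitting happens in extent units rather than attribute units: it makes
residual scales comparable across attributes and lets one noise parameter
serve all arms. This is a documented choice; attribute-unit fitting would
differ only by the fixed factor $s$.

Information criteria use the least-squares forms with the error variance
counted as a parameter:

$$AIC = N\ln(RSS/N) + 2(K+1),\quad
  AICc = AIC + \tfrac{2(K+1)(K+2)}{N-K-2},\quad
  BIC = N\ln(RSS/N) + (K+1)\ln N.$$

AIC definitions differ between software packages, so the convention is
stated explicitly; fits are refused outright when $N \le K+2$ (AICc
undefined). On noiseless data $RSS = 0$ is floored at $10^{-30}$ inside the
criteria only, so that comparisons remain finite.

`robustness_check()` refits on restricted temperature ranges (e.g. 5–40 vs
5–25 degC) and compares parameters against the full-range fit; the default
verdict threshold is a 20% relative change in activation energy, the
parameter that extrapolation accuracy hinges on. A pathway change above the
fitted range (different $Ea$ regime) shows up as a failed verdict.

## Model screening and the multiple-model bootstrap

`screen_models()` fits the whole catalog and computes Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ with $\Delta_i$ taken on
**AICc** — the small-sample correction matters at the 20–30-point designs
this method lives on — and analogous BIC weights. Models are ranked by the
combined weight $(w_{AIC} + w_{BIC})/2$ (the combination rule is not fixed
by the methodology; the arithmetic mean is our documented choice, and the
two weight sets are reported separately so any other combination can be
formed). Ties favour fewer parameters. Non-converged models are excluded
with their diagnostics rather than silently dropped.

`residual_bootstrap()` implements the multiple-model bootstrap: the total
loop budget $B$ (default 1000) is split across models proportionally to the
combined weights by largest-remainder rounding (so the allocation always
sums to $B$ exactly; models rounded to zero loops leave the ensemble). Each
loop resamples centered fit residuals with replacement (a parametric
Gaussian flavor is available), adds them to the fitted extents, and refits
its model warm-started from the original estimate. The band at each time is
the empirical quantile pair of the ensemble's predictions at the target
storage profile; the central curve is the top model's original fit. More
than 20% failed loops aborts the band as unreliable.

**Band semantics.** The default band is a *confidence band on the mean
trajectory* (quantiles of predicted central curves). Practitioners' use of
the term *prediction interval* is often ambiguous about whether measurement
noise is included; `band_type = "prediction"` adds resampled
residual noise to each loop's prediction, widening the band to cover
individual future measurements. Batch comparison (`compare_batches`)
always uses prediction semantics — with a Gaussian noise margin at the
fitted residual scale, because resampling ~20 residuals truncates the tails
a 99% band needs — since it asks whether individual observations of the
new batch are consistent with the reference batch.

## Downstream predictions

* `shelf_life()` finds the first crossing of the specification limit by the
  central curve and by the conservative band edge (upper edge for
  attributes growing with degradation, lower for falling), by bracketing
  plus bisection on the interpolated curve to 0.01 day.
* `ich_q1e_baseline()` is the classical comparator: an ordinary
  least-squares line through the storage-arm data only, shelf-life where
  the one-sided 95% confidence limit on the regression mean crosses the
  limit (single-batch convention; no poolability testing, since the
  comparison is against a single-arm regression). On decelerating kinetics
  the line keeps falling where the kinetic model levels off, so the linear
  shelf-life is systematically shorter — the restriction the kinetic
  approach removes.
* `excursion_monitor()` propagates the *fixed* bootstrap ensemble over an
  arbitrary recorded temperature trace (no refitting per excursion — the
  ensemble represents parameter uncertainty, which the excursion does not
  change) and reports the degradation budget as equivalent days at the
  reference storage temperature, $\int k_1(T(s))\,ds / k_1(T_{ref})$ using
  the top model's step-1 rate constant. For one-step separable kinetics
  this is exact (time–temperature superposition); for two-step fits it is
  advisory and labelled as such.
* `compare_batches()` reports the fraction of the new batch's observations
  inside the reference batch's 99% band at matching time/temperature,
  relative differences in $Ea$ and in $k(25\,^\circ\mathrm{C})$ between
  independent fits, and a verdict ("comparable" at inclusion $\ge$ 0.95 by
  default).

## The synthetic-data generator

Real accelerated-stability datasets of marketed biologics are proprietary,
so the package ships a generator (`generate_dataset`) whose presets emulate
the designs such studies use: arms at 5/25/40 degC, pull points at
0/0.25/0.5/1/2/3/6 months (21 points; extendable), additive Gaussian assay
noise with $\sigma_\alpha = 0.005$ of the span by default, and kinetics
chosen per preset:

* **hmw-aggregation** — zero-order, $Ea = 110$ kJ/mol, calibrated so that
  HMW grows by 0.0046%/day at 25 degC (the slow-aggregation regime where
  direct measurement is below assay resolution);
* **live-attenuated-titer** — first-order titer loss in log10 units,
  $Ea = 80$ kJ/mol;
* **mab-acidic-variants** — second-order growth of acidic species,
  $Ea = 100$ kJ/mol, with $k(40\,^\circ\mathrm{C})$ set so the hot arm
  reaches ~55% conversion in 6 months. The depth matters: at shallow
  conversion (~25%) the reaction order is barely identified and structure
  recovery degrades, so the preset is calibrated — by direct integration,
  like all presets — deep enough that $n$ is learnable from the design;
* **decelerating-vaccine** — two-step: a fast low-barrier step
  ($v = 0.3$, $Ea_1 = 30$ kJ/mol, saturating within weeks at all arms) plus
  a slow $Ea_2 = 100$ kJ/mol step, reproducing the
  fast-drop-then-plateau shape that defeats linear extrapolation;
* **concentration-dimer** — first-order with rate $\propto C$ ($p = 1$) at
  50 and 150 mg/mL.

What the generator does *not* emulate: assay plate effects, drifting
reference standards, batch-to-batch heterogeneity, censored values,
non-Gaussian outliers, or irregular pull schedules. Passing tests on these
scenarios therefore demonstrate correctness of the estimation machinery
under the stated noise model, not robustness to every artifact of real
assay data.

## Simulation sizes and reproducibility

The validation suite uses 50 replicates per preset for structure/parameter
recovery and selection consistency, 200 replicates (24 points,
$\sigma_\alpha = 0.01$, $B = 300$) for 95%-band coverage of the true
36-month value at 5 degC, and 4 optimizer starts per fit inside these
replicated screenings; single fits elsewhere use the 8-start default.
These sizes give Monte-Carlo standard errors of a few percent on the
reported rates while keeping the whole suite comfortably re-runnable on a
laptop. Every stochastic routine takes an explicit seed and is
bit-reproducible given one.

## Known limitations

* Extrapolation trusts the Arrhenius law over the fitted range; a pathway
  change above the highest modelled temperature (detected by
  `robustness_check`, e.g. data collected too close to the melting
  transition) invalidates predictions and is the analyst's responsibility
  to exclude.
* The two-step model's 9 free parameters are weakly identified on
  minimal designs; expect broad bands, and prefer the simplest adequate
  model, which the combined-weight ranking encodes.
* Bands quantify parameter (and optionally measurement) uncertainty under
  the chosen model set — not model inadequacy outside the catalog, and not
  batch-to-batch variability (random-batch hierarchical extensions are out
  of scope here).
* The logger temperature is taken as the product temperature (no thermal
  mass of packaging).
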