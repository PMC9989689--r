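---
title: "Modelling postprandial amino-acid effects on glucose and insulin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postprandial amino-acid effects on glucose and insulin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edesprot)
```

## The model

`edesprot` simulates and calibrates a compartmental ODE model of
whole-body glucose homeostasis in which dietary amino acids (AAs) act on
two fluxes: hepatic glucose production and pancreatic insulin secretion.
The base model is a four-balance description of an oral glucose
challenge — glucose mass in the gut, plasma glucose, plasma insulin, and
an interstitial insulin signal — to which the package adds the plasma AA
concentration as a *forcing function* (a measured input, not a state).

The five state variables are:

| state | meaning | unit |
|---|---|---|
| `M_gut` | glucose mass in the gut | mg |
| `G_pl` | plasma glucose | mmol/L |
| `I_pl` | plasma insulin | mU/L |
| `I_if` | interstitial insulin signal (deviation form, basal = 0) | mU/L |
| `Z_int` | running integral of the glucose excursion | mmol·min/L |

Glucose enters the gut as a Weibull-density pulse
$\sigma k_1^\sigma t^{\sigma-1} e^{-(k_1 t)^\sigma} D$ (which integrates
to the dose $D$), is absorbed at rate $k_2 M_{gut}$, and appears in
plasma after a mg→mmol and volume-of-distribution conversion. Plasma
glucose is additionally governed by

$$g_{liv}(t) = g^{b}_{liv} - k_3\,(G_{pl}-G_b) - k_4\,\beta\, I_{if}
  + k_{11}\,(AA_{pl}(t) - AA_b),$$

insulin-independent uptake (Michaelis–Menten in glucose, normalized to
equal $g^{b}_{liv}$ at basal), insulin-dependent uptake
$k_5 \beta I_{if}\, G/(K_M+G)$, and renal excretion above a threshold.
Insulin secretion is a PID-type controller on the glucose excursion
extended with AA terms:

$$i_{pnc}(t) = \beta^{-1}\Big[k_6 (G_{pl}-G_b)
  + \tfrac{k_7}{\tau_i}\!\int (G_{pl}-G_b)\,dt + \tfrac{k_7}{\tau_i} G_b
  + \tfrac{k_8}{\tau_d}\tfrac{dG_{pl}}{dt}
  + k_{12}\tfrac{dAA_{pl}}{dt} + k_{13}(AA_{pl}-AA_b)\Big].$$

Setting $k_{11}=k_{12}=k_{13}=0$ recovers the base model exactly; the
test suite verifies this against an independently coded base-model
simulator shipped under `inst/validation/`.

Two conventions are worth stating explicitly because they are easy to
get wrong:

* **Interstitial insulin is a deviation state.** `I_if` is driven by
  $k_9 (I_{pl}-I_b)$ and decays at rate $k_{10}$, so its basal value is
  0 and the $k_4 \beta I_{if}$ term in the liver equation vanishes at
  basal. With this convention "absolute" and "deviation" readings of the
  liver equation coincide at the basal point, which is the anchoring the
  calibration relies on.
* **The glucose derivative in the secretion controller is algebraic.**
  $dG_{pl}/dt$ inside $i_{pnc}$ is the just-evaluated plasma glucose
  balance, substituted symbolically — not a finite difference and not an
  implicit loop. The integral term is carried as the explicit fifth
  state `Z_int`, keeping the system a pure ODE that any stiff solver can
  handle.

Fluxes are signed and, by default, not clamped at zero: the printed
equations are linear in the deviations and nothing in them forbids a
negative excursion. A `clamp_nonneg` flag is available for users who
want hard non-negativity of EGP and secretion.

## The AA forcing function

Measured plasma AA concentrations are interpolated with a
shape-preserving piecewise cubic Hermite interpolant
(`stats::splinefun(method = "monoH.FC")`, the Fritsch–Carlson scheme).
It passes exactly through every knot, is $C^1$ on the sampled window,
and preserves monotonicity between knots, so it cannot overshoot local
data extrema. The derivative fed to the $k_{12}$ term is the analytic
derivative of the same polynomial (the tests compare it against central
finite differences at $10^{-4}$ min spacing). Fritsch–Carlson interior
slopes differ slightly from the Fritsch–Butland/Moler weighted-harmonic
variant found in some numerical environments; both carry the same
shape-preservation guarantees, and none of the package's conclusions
depend on the difference.

Beyond the last sample the forcing is extended as a constant with zero
derivative. The solver routinely evaluates a few steps past the final
observation time, and constant extension avoids fabricating post-window
AA dynamics. The basal AA concentration `AA_b_pl` is defined as the
t = 0 value of the series — the same "first data point" convention used
for basal glucose and insulin.

When a 20-AA panel is supplied, the panel is summed pointwise into a
total-AA (tAA) series before interpolation (`total_aa()`); grids must
match exactly, and the package refuses to resample silently. The package
convention is mmol/L for AA concentrations; $k_{11}$–$k_{13}$ inherit
their units from that choice, and data in µmol/L must be converted
before fitting.

## Calibration

The cost is the pooled weighted sum of squared residuals over glucose
and insulin, $\sum_j \sum_i (\gamma_j (y_{ij} - d_{ij}))^2$, with
$\gamma = 1$ for glucose (mmol/L) and $\gamma = 0.1$ for insulin (mU/L).
The insulin weight compresses the unit gap between the two channels so
that neither dominates the joint fit. Residual sign convention is
simulated − observed.

Minimization uses bound-constrained Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), multi-started: by default 25 initializations,
each free parameter starting at its population value times an
independent uniform draw from $[0.75, 1.25]$ (the start perturbation is
interpreted as multiplicative and uniform; multiplicative because the
free parameters span four orders of magnitude, uniform as the least
structured bounded choice). Three numerical choices matter in practice:

* **Multiplier space.** Optimization runs on parameter/population
  ratios, so every coordinate is O(1) and the default bounds
  $[0, 100\times]$ population are simple box constraints. The bounds
  enforce non-negativity without binding in any fit we have examined.
* **Finite-difference step vs. solver noise.** The residuals are
  computed through an adaptive ODE solver, so they carry noise at the
  solver-tolerance level. A machine-epsilon Jacobian step sits below
  that noise and stalls the optimizer after a few iterations; the
  package therefore uses `epsfcn = 1e-6` (step ≈ 1e-3 in multiplier
  space) and tightens the solver to `rtol = 1e-8`, `atol = 1e-10`
  inside the fitting loop (simulation default is `1e-6`/`1e-8`).
* **Failure containment.** If the solver fails at a trial point, the
  residual vector is replaced by a constant penalty whose SSR is
  $10^{12}$; gradient-based least-squares solvers cannot recover from
  exceptions mid-line-search, but they back away from a finite cliff.

Basal values $G_b$, $I_b$, $AA_b$ are always pinned to the t = 0
observations, never estimated. The base-variant scenario frees (a subset
of) $k_1, k_5, k_6, k_8$; the extended variant adds $k_{11}$–$k_{13}$.

## Model selection and identifiability

Fits are compared with $AIC = N\ln(SSR/N) + 2K$ and
$BIC = N\ln(SSR/N) + K\ln N$, where $N$ counts glucose and insulin
observations jointly (the cost pools both channels, so the criterion
must too) and the γ-weighted SSR enters directly. Perfect fits
($SSR = 0$) make the criteria undefined and are reported as errors
rather than silently regularized. Across several challenges, criteria
are averaged per challenge.

Identifiability is assessed by profile likelihood: one parameter is
scanned over a multiplicative grid (default $\times[0.1, 10]$, 21
log-spaced points) and the remaining free parameters are re-estimated at
every grid point, warm-started outward from the optimum. A parameter is
classified `identifiable` when the profile rises above a threshold on
both sides of the optimum, `practically_unidentifiable` on a one-sided
rise, and `structurally_unidentifiable` when flat. The threshold is the
$\chi^2_1$ 95% quantile scaled by the residual variance estimated at the
optimum ($SSR/(N-K)$) — standard profile-likelihood practice — with an
absolute floor of $10^{-6}$ so that noiseless fits (variance ≈ 0) do not
classify everything as identifiable. The canonical structural case is
$k_{12}$ under a constant AA input: its forcing derivative is
identically zero, so the parameter leaves the model.

## Flux decomposition

`compute_fluxes()` re-evaluates every named flux along a simulated
trajectory from the stored states (not from solver internals), so the
plasma balances close identically: the glucose derivative equals gut
appearance + EGP − uptakes − renal excretion at every sampled time, and
likewise for insulin. Incremental areas in `compare_fluxes()` use
trapezoidal integration on the output grid. The qualitative signatures
the model encodes — EGP rising above baseline for protein-only meals,
dipping below baseline near the glycemic peak when glucose is
co-ingested, and insulin secretion peaking higher for AA+glucose than
for AA alone — are asserted as tests, not just illustrated.

## The synthetic-data generator

Real AA-challenge and dairy datasets of the kind this model is built
for are not redistributable, so the package carries a generator that
emulates their designs and is itself first-class, tested code:

* **Sampling grids.** Free-AA challenges: 0, 10, …, 120, 150 min.
  Protein ingredients and dairy: 0, 15, …, 120, 150, 180, 210, 240,
  300 min.
* **AA input curve.** A gamma-shaped pulse
  $b + A\,(t/t_p)^{t_p/\tau} e^{(t_p-t)/\tau}$ anchored at baseline
  $b$ at t = 0 with a single interior maximum of height $A$ at $t_p$.
  Defaults: baseline 2.5 mmol/L (a typical fasting total-AA level) with
  amplitude 1.5 and peak at 40 min for free-AA designs; slower, broader
  excursions (peak 60–90 min, amplitude 1.2–1.3) for intact-protein and
  dairy designs, reflecting slower digestion. Doses: 25 g glucose for
  AA+glucose, 30 g glucose-equivalent carbohydrate for dairy.
* **True AA parameters.** The shipped defaults
  $(k_{11}, k_{12}, k_{13}) = (0.003, 3, 0.5)$ were chosen on
  physiological-magnitude grounds: an AA-only challenge roughly doubles
  insulin while glucose stays near basal; a protein-only meal raises EGP
  by ~10% of its basal value; and with glucose co-ingestion the
  glucose/insulin-mediated EGP suppression outweighs the AA stimulation
  around the glycemic peak. They live in the versioned population
  config, not in code.
* **Noise.** Independent multiplicative Gaussian noise per channel,
  CV-parameterized (defaults 2% glucose, 6% insulin, 3% AA — typical
  assay CVs), capped at 20%. The t = 0 samples stay noise-free because
  the calibration defines basal values from them; perturbing them would
  conflate basal misspecification with fit error. Truth trajectories
  are simulated with the forcing built from the noise-free sampled
  curve, matching how the model consumes AA data in practice.
* **Cohorts.** Per-subject log-normal jitter (default CV 10%) of the
  freeable rate constants, basal levels, and AA-curve shape.

What passing tests on these data do **not** show: the generator draws
its dynamics from the model itself, so recovery and model-selection
results demonstrate internal consistency under realistic designs and
noise — not that the model is correctly specified for real meals, and
not performance under features the generator omits (inter-AA
correlation structure, assay dropout, basal drift, meal-to-meal
carry-over).

## Problem sizes and numerical settings

Default solver: `lsoda` (stiff-capable, variable-step) at
`rtol = 1e-6`, `atol = 1e-8`; tightening by 10× moves trajectories by
less than the coarser tolerance (tested). The test suite and the
acceptance script run the statistical studies at deliberately modest
sizes — 10–20 seeded replicates, single- or two-start fits, 9-point
profile grids — sizes at which every property they assert is already
stable under seed changes. The 25-start, 21-point defaults remain the
interface defaults for real analyses; the multi-start monotonicity
property (more starts never worsen the returned cost) is asserted
directly.

## Known limitations

* Glucagon is not an explicit state; the AA effect on EGP is a direct
  proportional term.
* AA appearance in plasma is a forcing function, not a digestion model;
  the package cannot predict AA curves, only consume them.
* Single-AA interaction effects are out of scope (the model sees one
  series, usually total AA).
* The fat arm of mixed meals is not modelled; dairy carbohydrate is
  treated as glucose equivalents.
* Reported AIC/BIC values from clinical datasets are not reproducible
  here because those data are access-restricted; the package's claims
  about model selection are therefore property-based (generating-model
  recovery), not value-based.
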