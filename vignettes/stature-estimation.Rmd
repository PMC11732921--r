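---
title: "Subadult stature estimation: models, intervals and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subadult stature estimation: models, intervals and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staturekit)
```

## The problem and the models

Stature is part of the biological profile built from skeletal remains. For
skeletally immature individuals the relation between a long bone
measurement and standing height changes shape across growth: bone *lengths*
track stature almost linearly through childhood but decelerate as growth
ends, which a saturating curve captures; bone *breadths* grow slowly in
infancy, accelerate, then plateau, which a sigmoid captures. `staturekit`
therefore works with three mean functions relating a measurement $x$ (mm)
to stature $y$ (cm):

$$y = a x + b, \qquad
  y = a - b\,e^{-c x}, \qquad
  y = \frac{a}{1 + b\,e^{-c x}}.$$

The asymptotic exponential is used for the six length measurements and the
two composite limb lengths (humerus + radius; femur + tibia); the
three-parameter logistic for the ten breadth measurements; a linear model
is fitted to everything as the comparator. With 20 measurements and two
families each, the full grid is 40 models.

Units are fixed throughout: millimetres in, centimetres out. The printed
slopes of the published linear models (for example 0.46 cm stature per unit
of humerus length) are dimensionally consistent only with millimetre
inputs, which also matches standard osteometric protocols. Input validation
enforces plausibility windows — single-bone measurements in (0, 700) mm,
composites in (0, 1400) mm (a composite is a sum of two bones, so the
single-bone cap cannot apply to it), known stature in (30, 230) cm.

## The registry

`load_registry()` returns the 38 published pooled-sex models with their
coefficients exactly as printed (about three significant figures) and the
published validation metadata per model. Two nonlinear models (tibia and
radius distal breadth) never converged in the source analysis and are
deliberately absent. Because coefficients are transcriptions, registry
predictions are *defined* by the printed values; refitting data will not
reproduce them exactly.

Two printed rate constants (tibia midshaft `c = 0.017`, radius proximal
`c = 0.021`) sit an order of magnitude below every sibling breadth model,
and evaluating those curves at typical adult breadths yields statures of
roughly 24–27 cm. `registry_sanity_check()` probes every entry at a typical
adult measurement and flags predictions outside 140–200 cm; exactly these
two entries trip it. They are kept verbatim — they may be typographic, but
correcting a published table is not this package's call — and permanently
flagged, so any estimate they produce carries a warning.

The registry ships as a JSON asset with a recorded MD5 checksum, verified
on every default load.

## Fitting

Linear models are ordinary least squares (`stats::lm`); the fit stores
$n$, the residual SD $s = \sqrt{SSE/(n-2)}$, $\bar x$ and
$S_{xx}$ — everything the exact prediction interval needs.

Nonlinear models are Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with the analytic Jacobian from the package's own
gradient code. Starting values come from linearisations: with
$a_0 = 1.05\max(y)$, regressing $\log(a_0 - y)$ on $x$ gives $(b_0, c_0)$
for the asymptotic exponential, and regressing
$\mathrm{logit}(y/a_0)$ on $x$ gives them for the logistic. These basins
converge for all well-formed growth data we generate. Defaults are 200
iterations and tolerance $10^{-8}$; the accepted-step objective trace is
retained and is non-increasing by construction of the optimizer, which the
tests assert. Non-convergence is a *reported state*, never an exception —
mirroring how the two absent registry models are handled — and a
non-converged model refuses prediction. The parameter covariance is
$s^2 (J^\top J)^{-1}$ at the solution with $s = \sqrt{SSE/(n-3)}$; if
$J^\top J$ is singular the fit is kept but intervals are disabled.
Per-coefficient Wald statistics are reported (`tidy()`), never used as a
filter.

`fit_stature_models()` attempts the whole 40-model grid on a training
cohort, complete-case per measurement (per-model sample sizes legitimately
differ), skipping any measurement with fewer than 20 complete pairs.

## Prediction intervals

A prediction interval must cover a *new* individual, so residual noise
enters alongside estimation uncertainty:

- linear, fitted: $\hat y \pm t_{n-2,1-\alpha/2}\, s
  \sqrt{1 + 1/n + (x_0-\bar x)^2/S_{xx}}$ (method `exact_t`);
- nonlinear, fitted: first-order delta method,
  $\hat y \pm t_{n-p,1-\alpha/2}\, s
  \sqrt{1 + g(x_0)^\top (J^\top J)^{-1} g(x_0)}$ with $g$ the parameter
  gradient (method `delta_t`). A residual bootstrap (refit on resampled
  residuals, percentile interval, `method = "bootstrap"`) is available as a
  cross-check; on well-specified data its half-widths agree with the delta
  method within a few percent.
- registry models: the published tables print $s$ but not $n$, $\bar x$,
  $S_{xx}$ or any covariance, so an exact interval is impossible from the
  publication alone. Rather than return nothing, the package uses
  $\hat y \pm z_{1-\alpha/2}\, s$ (method `approx_z`) and attaches an
  explicit "approximate" warning. This slightly understates width at small
  $n$ or extreme $x_0$; users needing exact intervals should refit.
  A model with no usable residual SD or covariance returns
  `method = "unavailable"` with a point estimate only.

Measurements more than 10% outside the training range attach an
extrapolation warning but are never refused — a forensic practitioner must
still see the estimate. Reports round points and bounds to 0.1 cm; the
underlying tables keep full precision. Estimates are returned one row per
(measurement, model), ordered by the source model's published MAD; no
meta-combination across bones is attempted, since reconciling conflicting
per-bone intervals is a judgement the analyst should make.

## The validation battery

`train_test_split()` draws a seeded random 80/20 partition with
`round(n * frac)` training rows; on a 990-strong cohort this gives 792/198
(a stratified or site-blocked rule could give 793/197; the package
documents its own rule and does not claim to reproduce any particular
membership). All metrics are computed on the held-out set:

- **Kendall's tau-b** (tie-corrected; breadths are coarsely measured, so
  ties happen) between measurement and known stature;
- **two-sample Kolmogorov–Smirnov** D and asymptotic p between predicted
  and known stature distributions (point estimates, not interval
  midpoints, feed this and MAD);
- **MAD**, mean |predicted − known|, the precision metric;
- **test accuracy**, the percent of held-out individuals whose known
  stature falls inside the 95% PI;
- **Bland–Altman** bias and limits of agreement, bias ± 1.96·SD of the
  differences — the standard construct for the "95% confidence interval"
  lines on an agreement plot.

`misclassification_report()` cross-tabulates predictions whose interval
missed the known stature by model type × measurement group, reporting each
cell both as a percent of all predictions and as a percent of
misclassifications (the two numbers sum, respectively, to the overall rate
and to 100), plus the count of individuals with at least one miss.

## The synthetic cohort generator

No open reference dataset of subadult CT measurements with known stature
exists, so the package generates cohorts with the statistical structure the
method assumes:

1. integer age 0–20 drawn from a birth-heavy distribution (24.3% at age 0,
   thin mid-childhood, a second rise in adolescence) matching the reference
   sample the published models were built on;
2. stature = a monotone piecewise-linear growth curve through anchors
   (50 cm at birth, 75 at 1 y, 87 at 2 y, 110 at 5 y, 138 at 10 y, 160 at
   14 y, 170 at 18 y, 171 at 20 y) plus additive Gaussian noise with
   SD = 2 + 0.25·age cm (heteroscedastic: adolescent statures vary more),
   truncated above 45 cm. Piecewise-linear interpolation was chosen over a
   parametric growth model as the simplest structure preserving the
   infancy-steep, adolescence-flattening shape the method's argument
   depends on; the anchors are configuration, not constants.
3. each measurement = the inverse of its generative curve at that stature,
   times multiplicative Gaussian noise (relative SD 0.02). The generative
   curves default to the registry's nonlinear coefficients with four
   substitutions: family-plausible rate constants for the two flagged
   entries (0.17 and 0.21) and synthetic sigmoids for the two measurements
   whose published nonlinear models never converged, calibrated against
   their linear counterparts. These are generator choices, not corrections
   to the publication. Statures are clamped 2% of span inside each curve's
   attainable range before inversion.
4. sex is recorded F/M with P(male) = 0.595 but never used in generation —
   the models are pooled-sex by design.

Under zero noise the cohort inverts exactly: every fitted nonlinear model
recovers its generative parameters to relative error below $10^{-4}$
(observed: ~$10^{-13}$), which is the package's strongest correctness check
on the whole simulate → fit path.

What the generator does **not** emulate: the correlation structure among
measurements beyond what shared stature induces (given stature,
measurement noises are independent — real bones co-vary more); the
diaphyseal vs maximum measurement mixture; secular trends; missing-data
patterns. Passing tests on synthetic cohorts therefore demonstrate the
*machinery* (fitting, intervals, metrics) is right, not that any particular
published coefficient generalises to a new population.

## Numerical choices and degenerate inputs

- $e^{-cx}$ is computed with the exponent clamped at 700, so a pathological
  sign on $c$ overflows to a large finite number rather than NaN;
  underflow goes to 0 naturally.
- Model inversion is closed-form per family and errors outside the
  attainable stature range, naming the admissible interval.
- Constant-$x$ designs and constant-$y$ responses raise immediate,
  specific errors (degenerate design / non-identifiable) rather than
  producing garbage fits.
- Cohort CSVs are locale-independent (period decimal separator), with
  row-level validation that names the offending row and column, and a
  whole-file failure only when more than 10% of rows are invalid.
- The `_kind` columns (diaphyseal vs maximum measurement) are carried as
  metadata and echoed in reports but never select models, matching the
  pooled treatment in the source analysis.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to keep the binomial
noise on coverage estimates well inside the asserted bands: interval
coverage uses 500 training and 2000 test pairs; the end-to-end cohort test
uses 6000 individuals (4800/1200 split) so that per-model accuracy
estimates have standard errors near 0.8 percentage points; oracle
equivalence checks (closed-form OLS, brute-force ECDF and pair-counting
tau) run 100 randomized instances each.

## Known limitations

- Registry prediction intervals are approximate (see above) and inherit
  the ~3-significant-figure rounding of the printed coefficients.
- Delta-method intervals assume homoscedastic Gaussian residuals. On the
  generator's heteroscedastic cohorts, marginal 95% coverage per model
  lands between roughly 91% and 96% — above the 90% floor the package
  asserts, below nominal for the most heteroscedastic breadth curves. The
  same caveat applies to real data, where unweighted fits are standard
  practice for these models.
- The two flagged registry entries produce implausible estimates by
  construction; they are retained for fidelity and always warn.
- Models are pooled-sex; sex-specific coefficients are out of scope.
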