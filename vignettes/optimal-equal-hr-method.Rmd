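---
title: "The optimal equal-HR method: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The optimal equal-HR method: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oehr)
```

## The model and its assumptions

Throughout, survival follows a Cox proportional-hazards model
`h(t | x) = h0(t) exp(f(x))`, where `x` is a continuous predictor and
`f(x) = log λ(x)` is its log relative hazard. Because `λ` is defined only up
to a multiplicative constant, every fitted curve in this package is
*centered*: the mean of `f̂` over the observed predictor values is zero, and
all downstream quantities (percentile heights, candidate pairs) inherit this
convention.

Two assumptions are load-bearing. First, proportional hazards: the effect of
`x` does not change with time. The package does not test or relax this;
time-varying effects are out of scope. Second, a *U-shaped* effect: `f` has
a single interior minimum, falling on the left and rising on the right. The
U-shape is not assumed blindly — it is checked by a diagnostic
(`diagnose_u_shape()`) and the cut-point search refuses to run when the
check fails, unless the user overrides it.

## The P-spline Cox fit

`f` is represented on a cubic B-spline basis over 22 evenly spaced knots
spanning the observed predictor range (24 basis functions; boundary knots
are extended with the same spacing, so the basis is a partition of unity on
the whole range). The penalized Breslow partial log-likelihood

    pl(b) − (s / 2) · bᵀ Dᵀ D b

is maximized by Newton iteration with step-halving; `D` is the
*second-order* difference matrix on adjacent coefficients — the standard
P-spline roughness penalty, whose null space (linear trends) is exactly the
set of effects a plain linear Cox term can represent. Tied event times use
the Breslow approximation everywhere (the penalized fit, the categorical
refits and the log-rank scores), so likelihoods are comparable across
models.

Two numerical points deserve note:

* **Identifiability.** A constant added to all spline coefficients shifts
  `f` by a constant, which changes neither the partial likelihood nor the
  penalty; the Newton system would be singular. The fit therefore works in
  the orthogonal complement of the constant coefficient direction and
  restores the centering convention afterwards.
* **Effective degrees of freedom.** `edf = tr((H + sP)⁻¹H)`, with `H` the
  information of the unpenalized fit at the solution. As the penalty weight
  grows the fit approaches a straight line and `edf → 1`.

The penalty weight is chosen by minimizing `AIC = −2 pl + 2 edf` over a
log-spaced grid, by default 25 points spanning `10⁻²`–`10⁵`, which on
standardized predictors covers effective degrees of freedom from roughly 15
down to the linear limit. Ties are broken toward the larger weight — when
two fits explain the data equally well per AIC, the smoother one is
preferred. Fits are warm-started along the grid. The grid is exposed
(`smoothing_grid` argument) for users whose predictors live on very
different scales.

```{r}
sc  <- sim_scenario(k1 = -2, k2 = 2, a = 0, Pc = 0, n = 500, reps = 1, seed = 1)
d   <- generate_dataset(sc, 1)
fit <- fit_spline_cox(d)
plot(fit)
```

### The U-shape diagnostic

The fitted curve is sampled on a 200-point grid over the *central 90%* of
the observed predictor; cubic splines are least reliable in the outer tails,
where a handful of extreme observations support the fit, and boundary
wiggle there should not veto an otherwise clean U. The flag requires the
first differences to change sign exactly once, from negative to positive. A
nonlinearity p-value accompanies the flag: a chi-square test on
`2 (pl_spline − pl_linear)` with `edf − 1` degrees of freedom (one linear
degree of freedom is already in the null model). This is a pragmatic
reference-distribution choice for a penalized alternative, reported as a
guide rather than an exact test.

Extrapolation beyond the observed range is refused rather than clamped:
every quantity the cut-point search consumes stays inside the support of the
data.

## The equal-HR cut-point search

Candidate construction follows the percentile sweep described above
(`candidate_equal_hr_pairs()`). The open details were resolved as follows:

* **Intersections.** The curve is evaluated on a 401-point grid. For each
  height `Q_k` the crossing *closest to the fitted minimum* on each side is
  used. On a clean U there is exactly one crossing per side and the choice
  is vacuous; under residual boundary wiggle it keeps the pair in the
  U-shaped core.
* **"Closest observations".** Closest in `x` among observations on the
  relevant side of the fitted minimum; ties are broken toward the
  observation whose fitted height is closer to `Q_k`.
* **Interpolation.** When the closest observations miss the `≤ 0.01`
  equal-height constraint, the pair is replaced by the linear interpolants
  on the curve at exactly height `Q_k`; the resulting cut-points need not be
  observed values.
* **Degenerate groups.** Each candidate three-group Cox refit requires
  every group to hold at least 5% of the sample. An unguarded AIC search
  can otherwise select a pair whose outer group contains a handful of
  extreme observations with an enormous, meaningless hazard ratio. The 5%
  floor mirrors common practice for maximally selected statistics and is a
  user-visible argument (`min_group_frac`).
* **Ties in AIC.** Among pairs within numerical tolerance of the minimal
  criterion, the pair with the most balanced group sizes wins; any residual
  tie falls to the smaller percentile index, making the selection
  deterministic.

BIC (`−2 pl + log(events) · k`) is available as an alternative selection
criterion via `criterion = "bic"`.

## The comparator methods

The median and Q1/Q3 splits use the type-7 (linear-interpolation) empirical
percentile throughout — the same convention used for the percentile sweep —
so all methods agree on what "a quantile of the data" means.

The minimum p-value method (`minp_cutpoint()`) is the maximally selected
rank statistic with log-rank scores `a_i = d_i − Λ̂(T_i)` (Nelson–Aalen at
the subject's observed time): for a split at `c`, the score sum of the low
group is standardized by its conditional permutation mean and variance, and
the split maximizing the absolute standardized statistic is selected. This
conditional-moments standardization is the established convention for
maximally selected statistics; it differs from dividing each split's
log-rank numerator by its hypergeometric variance, and the two can prefer
different splits when hazards cross — as they do under a U shape. Splits are
restricted to the inner 10–90% quantile window of the predictor. The
reported p-value is the naive minimum and is flagged as uncorrected: the
method is included as a comparator, and multiplicity-corrected inference for
it is out of scope.

## Performance measures

The five measures are implemented to their original definitions, with these
concrete conventions:

* **c-index** (via `survival::concordance`): pairs are comparable when the
  smaller observed time is an event; ties in predicted risk count 1/2.
* **CPE**: each pair contributes `1/(1 + exp(−|Δlp|))`, the model-implied
  probability that the higher-risk subject fails first; 0.5 by convention
  for a degenerate predictor. The estimate depends on the fitted model
  only, not on the censoring distribution.
* **IBS**: inverse-probability-of-censoring weighted Brier score, censoring
  distribution estimated by Kaplan–Meier on the *training* data (left
  limits at event times), integrated by the trapezoid rule over 50 points
  up to the 95th percentile of observed test times — the tail beyond is
  where censoring weights explode — and normalized by the grid span.
* **R²_PM**: `var(lp) / (var(lp) + π²/6)`, the extreme-value error variance
  implicit in the proportional-hazards model.
* **R²_D**: the prognostic index is rank-transformed to Blom normal scores
  scaled by `κ = √(8/π)`; the Cox coefficient `D` on the scores gives
  `R²_D = (D²/κ²)/(D²/κ² + π²/6)`. Tied prognostic values share averaged
  ranks.

Cross-validation (`cv_performance()`) defaults to the two-fold scheme, with
folds stratified by event status so both folds retain events even under
heavy censoring; a fold draw that still lacks events is redrawn a bounded
number of times. Cut-points and the categorical model are estimated on the
training folds only, and all measures are evaluated on the held-out fold.
Rows are sorted by `(time, status, x)` before fold assignment, so the report
is invariant to row order given the seed. Repeated k-fold schemes
(e.g. 100 × 5-fold) are supported through `n_repeats` and `n_folds`.

## The simulator

`sim_scenario()` / `generate_dataset()` emulate the study conditions under
which the method was designed: a standard-normal predictor, a
piecewise-linear V-shaped log relative hazard

    s(x) = k1 (x − a)  for x ≤ a,      k2 (x − a)  for x > a,

with `k1 < 0 < k2`, Weibull event times drawn by inverse transform
`T0 = (−log U / (λ exp(s(x))))^{1/v}`, and Uniform(0, r) censoring. The
*shifted* form above is used deliberately: writing the two arms as `k1·x`
and `k2·x` would make the log hazard discontinuous whenever the turning
point `a` is non-zero, which contradicts both the intended V shape and the
equal-height interpretation of the cut-point pairs; the shifted form is the
continuous function with `s(a) = 0` that the arm slopes describe.

The censoring bound `r` is not a free dial: given a target censoring
proportion `Pc`, it is calibrated at scenario construction by bisection on
`E[min(T0, r)]/r` over a 200,000-draw Monte-Carlo sample on a fixed RNG
substream (tolerance ±0.005), so the realized censoring fraction matches the
target without touching the scenario's data streams. Each replicate draws
from its own substream derived deterministically from the scenario seed and
the replicate index, so replicates are independent, reproducible and
unaffected by how many of them are run.

What the simulator does *not* emulate: covariate measurement error, ties in
observed times, non-Weibull baselines, informative censoring and predictors
with skewed or multimodal distributions. Passing tests on these synthetic
conditions show that the machinery recovers known truths under the stated
model; they do not certify behavior on data violating it, and the
diagnostic-first workflow exists precisely because real curves may not be
U-shaped.

## Problem sizes used by the test suite

The packaged test suite reruns the Monte-Carlo checks at 30 replicates of
n = 500 (with correspondingly widened Monte-Carlo tolerances where a median
across replicates is compared), and the structural and oracle checks at
n ≤ 500. `scripts/acceptance.R` runs the reference configuration — 100
replicates of n = 500 — for the two headline quantities. These sizes are the
package's choice of a thorough-but-brisk default; `run_scenario()` accepts
any `(n, reps)`.

## Known limitations

* Proportional hazards are assumed, not checked.
* One continuous predictor is discretized at a time; simultaneous
  categorization of several covariates is not supported (adjustment
  covariates may enter the Cox fits linearly and unpenalized).
* The minP comparator's p-value is reported uncorrected.
* The U-shape diagnostic is a shape heuristic plus an approximate test; a
  borderline curve deserves a look at `plot(fit)` before trusting any
  two-cut-point summary.
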