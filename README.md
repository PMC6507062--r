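# oehr: optimal equal-HR cut-points for U-shaped risk in Cox models

Many clinical and epidemiological predictors — body-mass index, blood
pressure, serum cholesterol and other biomarkers — carry *U-shaped* risk:
both low and high values are harmful. Splitting such a predictor at its median, or at
the quartiles, ignores the shape of the risk curve; a single maximally
selected split cannot represent it at all. This package implements the
**optimal equal-HR (OEHR) method** for choosing *two* cut-points of a
continuous predictor in right-censored survival data, together with the
standard comparators and the measures needed to evaluate them.

It is intended for biostatisticians and clinical researchers who need
interpretable low / middle / high risk groups from a continuous prognostic
variable whose relationship with log relative hazard is U-shaped.

## The method

With a Cox proportional-hazards model `h(t | x) = h0(t) exp(f(x))`, the log
relative hazard `log λ(x) = f(x)` is estimated by a penalized B-spline
(P-spline) Cox fit — cubic B-splines on 22 evenly spaced knots, a
second-order difference penalty, and the penalty weight chosen by minimizing
`AIC = −2 pl + 2 edf`. The fitted curve serves first as a graphical
diagnostic of the U shape, then as the search surface for cut-points:

1. For each integer percentile `k = 5, …, 95` of the fitted `log λ̂`
   values, a horizontal line at that height crosses the U-shaped curve at
   two points. The observations closest to the two crossings form a
   candidate pair `(x1, x2)` constrained to have (nearly) equal fitted log
   relative hazard, `|log λ̂(x1) − log λ̂(x2)| ≤ 0.01`; when the closest
   observations violate the constraint, linearly interpolated points on the
   curve (with exactly equal heights) are used instead.
2. Each candidate pair discretizes `x` into low (`x < x1`), middle
   (reference) and high (`x > x2`), and a three-group categorical Cox model
   is fitted.
3. The pair whose categorical model minimizes AIC (optionally BIC) is the
   optimal equal-HR pair.

The equal-height constraint is what makes the result interpretable: the low
and high groups have, by construction, comparable hazard ratios against the
middle range.

Also included, behind the same interfaces:

* comparator discretizations: median split, Q1/Q3 quartile split, and the
  maximally selected log-rank (minimum p-value) split;
* predictive-performance measures with cross-validation wrappers: Harrell's
  c-index, the Gönen–Heller concordance probability estimate (CPE), the
  IPCW integrated Brier score (IBS), and the explained-variation measures
  R²_PM and R²_D;
* a Weibull survival-data simulator with a piecewise-linear V-shaped log
  hazard and censoring calibrated to a target proportion, plus a
  Monte-Carlo study driver.

## Worked example

Simulate one dataset with a moderately asymmetric V-shaped log hazard
(slopes −8/5 and 8/3, turning point 0.5, 20% censoring), diagnose the shape,
find the OEHR cut-points and cross-validate:

```r
library(oehr)

sc  <- sim_scenario(k1 = -8/5, k2 = 8/3, a = 1/2, v = 1, Pc = 0.2,
                    n = 400, reps = 1, seed = 20)
d   <- generate_dataset(sc, 1)
fit <- fit_spline_cox(d)
diagnose_u_shape(fit)
#> U-shape diagnostic: U-shaped (single interior minimum)
#>   fitted minimum at x = 0.365
#>   nonlinearity: LR = 262.08 on 5.7 df, p = 5.34e-54

oehr_cutpoints(d, fit)
#> Cut-point result: method 'oehr'
#>   cut-point(s):  -0.5855, 1.0845
#>            log HR     HR     SE p
#> .grouplow  1.6151 5.0284 0.1347 0
#> .grouphigh 1.9074 6.7357 0.1812 0
#>   group sizes:  middle=237, low=118, high=45
#>   AIC = 3121.287, BIC = 3128.786 (n = 400, events = 314)

cv_performance(d, "oehr", n_folds = 2, seed = 1)
#> Cross-validated performance: method 'oehr', 2-fold x 1 repeat(s)
#>          mean     se
#> cindex 0.6605 0.0150
#> cpe    0.6676 0.0211
#> ibs    0.1556 0.0052
#> r2_pm  0.3811 0.0068
#> r2_d   0.3998 0.0833
```

The diagnostic confirms a single interior minimum (near the true turning
point 0.5) with a strongly significant nonlinear term. The selected
cut-points (−0.59, 1.08) bracket the minimum asymmetrically, as the unequal
slopes require, and the low and high groups have comparable hazard ratios
(about 5 and 6.7) against the middle range — the equal-HR property. The
cross-validated c-index of about 0.66 summarizes the discrimination of the
resulting three-group model.

For file-based workflows there is a thin command-line front end in
`inst/cli/oehr-cli.R` with subcommands `diagnose`, `cutpoints`,
`simulate-study` and `report`.

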