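# labelsimex

Bias correction for outcome regressions on class labels produced by
unsupervised clustering.

## The problem

A standard two-stage analysis in biomarker studies clusters samples on
molecular features and then regresses a clinical outcome (binary response,
overall survival) on the discovered classes. The cluster labels are treated
as known, but every clustering algorithm misassigns part of the sample.
Writing `H` for the latent class, `H*` for the reported label and

    pi_ij = P(H* = i | H = j)

for the entries of the column-stochastic misclassification matrix `Π`,
fitting `g(E(Y | H = h)) = x_h' β` (treatment contrasts, class 1 as
reference) with `H*` plugged in for `H` — the *naive* estimator — attenuates
effects toward zero and destroys confidence-interval coverage. With ~16%
misclassification and n = 1000, a true log-odds effect of 2 is estimated
around 1.3 and the nominal 95% interval essentially never covers the truth.

`labelsimex` implements the two general-purpose corrections, for logistic
and Cox proportional-hazards outcome models:

* **Regression calibration (RC)** — replace the class indicators with the
  posterior class probabilities from the clustering (GMM responsibilities
  or fuzzy c-means memberships) and refit.
* **mcsimex (misclassification simulation-extrapolation)** — with
  `G(λ) = β(Π^(1+λ))`, the naive estimate sits at λ = 0 and the target at
  λ = −1. Simulate extra label noise at grid levels λ > 0 by drawing labels
  from columns of `Π^λ` (spectral decomposition `Π^λ = E Λ^λ E⁻¹`), refit B
  times per level, fit a quadratic in λ through the mean estimates, and
  extrapolate to λ = −1. Jackknife-style and full-bootstrap variance
  estimators are included, the latter propagating the uncertainty of an
  estimated `Π` via out-of-bag re-estimation.

Supporting machinery: misclassification-matrix estimation from a fitted
clustering (Monte Carlo) or by out-of-bag bootstrap, existence diagnostics
for real matrix powers, label-switching alignment, and a Monte Carlo
engine that reproduces the bias/coverage simulation study this
implementation is validated against.

## Worked example

```r
library(labelsimex)

sim <- simulate_mixture(two_class_mixture(0.5), n = 1000, seed = 11) |>
  add_logistic_outcome(beta = c(-1, 2), seed = 12)

ca <- cluster_classes(sim, "gmm", k = 2, seed = 13) |>
  align_classes(sim$true_class)
mean(ca$labels != sim$true_class)
#> [1] 0.154

Pi <- estimate_misclass(ca, n_mc = 1e5, seed = 14)
Pi
#> Misclassification matrix (column-stochastic, 2 classes)
#>        [,1]   [,2]
#> [1,] 0.8377 0.1569
#> [2,] 0.1623 0.8431

tidy(fit_class_model(sim, ca$labels, "logistic"))     # naive
#>   term        estimate std.error conf.low conf.high
#> 1 (Intercept)   -0.702    0.0958   -0.890    -0.515
#> 2 class2         1.29     0.133     1.02      1.55

tidy(fit_rc(sim, ca, "logistic"))                     # regression calibration
#>   term        estimate std.error conf.low conf.high
#> 1 (Intercept)    -1.04     0.117    -1.27    -0.814
#> 2 class2          1.95     0.186     1.59     2.31

fit <- mcsimex(sim, ca$labels, Pi, "logistic", B = 50, seed = 15)
tidy(fit)
#>   term        estimate std.error conf.low conf.high  naive
#> 1 (Intercept)   -0.981     0.114    -1.20    -0.759 -0.702
#> 2 class2         1.83      0.176     1.48     2.17   1.29

autoplot(fit)   # the simulation-extrapolation curve
```

The generating truth is (−1, 2). The naive class effect is attenuated to
1.29; regression calibration recovers 1.95 and mcsimex 1.83, both with
intervals covering the truth. `fit_class_model(sim, "true_class", ...)`
gives the benchmark fit on the true labels (2.07 here).

For survival outcomes use `add_survival_outcome()` and `kind = "cox"`; for
a full-bootstrap interval that also reflects the estimation of `Π`, see
`mcsimex_boot()`. The Monte Carlo engine is driven by `scenario()`,
`run_scenario()` and `summarize_scenario()`; `reproduce_table()` compares
its output against the published reference values shipped under
`inst/extdata/`. The methods vignette
(`vignettes/label-misclassification.Rmd`) documents the model, the
defaults, and the design choices.

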