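# fermopt

Statistical tooling for fermentation medium development: design of
experiments, dual response-surface / neural-network modelling, optimum
location with a confirmation rule, sigmoid fermentation kinetics, and
strain-improvement / purification accounting. The package ships, as
plain-text fixtures, the complete data tables of a protease-production
optimization campaign (a mutagenized *Stenotrophomonas acidaminiphila*
strain grown on cassava processing effluent and corn steep liquor), so the
whole analysis is reproducible at desk scale.

## Who it is for

Bioprocess scientists and statisticians who run medium-optimization
campaigns: screen factors with two-level factorials, climb a path of
steepest ascent, fit a central composite design, compare a quadratic
response surface against a small feed-forward network, locate and confirm
an optimum, and summarize bioreactor runs and downstream purification.

## The models at the core

* **Response surface** — full second-order polynomial in coded units,
  $y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j +
  \sum_i \beta_{ii} x_i^2$, fitted by OLS with a lack-of-fit ANOVA driven
  by the design's replicate structure.
* **Neural network** — a 5–H–1 feed-forward net (tanh hidden, linear
  output) trained by Levenberg–Marquardt,
  $(J^\top J + \mu I)\,\delta = J^\top e$, on $[-1,1]$-normalized data
  with a seeded 70/15/15 split and validation-based early stopping.
* **Kinetics** — logistic biomass growth
  $X(t) = X_0 X_{max} e^{\mu t}/(X_{max} - X_0 + X_0 e^{\mu t})$ and
  modified Gompertz accumulation
  $P(t) = P_{max}\exp(-\exp(r_{max} e (t_L - t)/P_{max} + 1))$, fitted by
  nonlinear least squares, with yield coefficients
  ($Y_{p/s}, Y_{x/s}, Y_{p/x}$) derived from the fitted parameters.
* **Comparison and optimization** — a seven-metric suite ($r^2$, MSE,
  RMSE, MAE, AAD, ARE, Pearson $\chi^2$), grid-plus-polish maximization
  under a linear desirability, and the <5% confirmation-experiment rule.

## Worked example

```r
library(fermopt)

runs <- fermopt_fixture("ccrd_runs")          # the 50-run design, as published
fit  <- fit_quadratic(design_from_actual(runs[, 2:6], protease_factors()),
                      runs$activity_exp)
round(fit$r2, 4)
#> [1] 0.9727

opt <- optimize_surface(protease_surface(), fs = protease_factors())
opt
#> Optimum (coded): 1, 1, 1, 1, 1
#> predicted response: 411,713.7  desirability: 1
#> actual levels: 48.100, 24.600,  6.930,  0.380,  0.039

validate_optimum(opt$predicted, 418763.45)
#> predicted 411,713.7, observed 418,763.5: 1.71% difference -> PASS (threshold 5%)

purification_report(fermopt_fixture("atps_steps"))[, c(1, 5:7)]
#>      label specific_activity yield_pct    fold
#> 1    crude            115.84   100.000  1.0000
#> 2 PEG-1500           6087.00    73.871 52.5483
#> 3 PEG-3000           2024.12    61.969 17.4739
#> 4 PEG-4500           1051.49    41.265  9.0774
#> 5 PEG-6000           3327.81    63.555 28.7286
#> 6 PEG-7500            517.62    29.487  4.4686
```

Reading the output: the refitted quadratic explains 97.3% of the response
variance; its published coefficient vector peaks at the all-high corner of
the design cube (48.1% effluent, 24.6% corn steep liquor, 6.93% casein,
0.38 g/L Mg²⁺, 0.039 g/L Mn²⁺) at a predicted 411,714 U of protease
activity, which the confirmation experiment ratifies at a 1.71% difference;
and the PEG-1500 two-phase system recovers 73.9% of the crude activity at a
52.5-fold purity.

`reproduce_study()` runs every stage on the bundled tables in one call, and
`run_pipeline()` accepts the same stages on your own CSVs. The methods
vignette (`vignettes/fermentation-optimization.Rmd`) documents the models,
parameter conventions, numerical choices and known limitations.

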