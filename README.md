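# fmitools

Fraction of missing information (FMI) from full information maximum
likelihood, for mean-and-covariance structure models on incomplete
multivariate-normal data.

## The problem

When data are missing (dropouts, skipped survey items, planned missingness
designs), reporting missing rates alone says little about how much the
*precision* of a given parameter estimate has suffered: two mechanisms with
identical rates can cost very different amounts of information. The
diagnostic that answers the question directly is the per-parameter fraction
of missing information. Writing `J_Y` for the observed-data information
matrix at the FIML estimate and `J_X` for the information the same sample
would have carried with no missing cells (the missing-information principle:
`J_X = J_Y + J_{X|Y}`), the FMI of parameter `j` is

    delta_j = 1 - (J_X^-1)_jj / (J_Y^-1)_jj = 1 - SE_C^2 / SE_O^2,

the proportion of the sampling variance of the estimate attributable to
missing data. Its one-to-one companion, the width inflation factor
`WIF = SE_O / SE_C = 1 / sqrt(1 - delta)`, says how much wider the
confidence interval is than it would have been with complete data:
`delta = 0.75` doubles the standard error.

`J_X` is not observable, but it can be estimated by evaluating the
complete-data information formulas at the FIML estimates. The package
implements the three computational variants of this idea:

- **delta1** (`delta1_hessian`) — negative numeric Hessian of the
  log-likelihood on both the observed-data and complete-data sides;
- **delta2** (`delta2_structured`) — the analytic first-dominant-term
  information `Delta' H1(mu(theta), Sigma(theta)) Delta`, with `Delta` the
  model Jacobian and `H1` the unstructured observed information, evaluated
  at the model-implied moments;
- **delta3** (`delta3_unstructured`) — the same analytic form evaluated at
  the unstructured (saturated EM) estimates of the means and covariances.

The three coincide on saturated models (e.g. regression path models) and
converge on each other as the sample grows when the structured model is
true.

Everything needed to study these estimators is included: FIML fitting via
missingness-pattern sufficient statistics, saturated EM, MCAR and
linear/nonlinear MAR missingness simulators with percentile-cutoff selection,
and a Monte-Carlo harness (bias, RMSE, 95% equal-tailed-interval width,
failure accounting).

## Worked example

Simulate the two-factor population (eight indicators, loadings 0.49, factor
correlation 0.4), impose a strong nonlinear-MAR mechanism deleting the
indicator pair `X2, X4` when the standardized sum `X1 + X3` is in either
tail (and `Y2, Y4` by `Y1 + Y3`), then fit the CFA by FIML and estimate the
FMI of every parameter:

```r
library(fmitools)
library(dplyr)

mech <- two_factor_mechanism("mar_nonlinear", pi_mis = 0.4)
dat  <- simulate_dataset("two_factor", n = 500, mech, seed = 2026)
tab  <- compute_fmi(dat, two_factor_model())

tab |>
  filter(parameter %in% c("lambda_X2", "phi_F1.F2")) |>
  select(parameter, method, estimate, se_observed, se_complete, fmi, wif)
#> # A tibble: 6 × 7
#>   parameter method              estimate se_observed se_complete   fmi   wif
#>   <chr>     <chr>                  <dbl>       <dbl>       <dbl> <dbl> <dbl>
#> 1 lambda_X2 delta1_hessian         0.542      0.109       0.0540 0.752  2.01
#> 2 phi_F1.F2 delta1_hessian         0.143      0.0990      0.0808 0.334  1.23
#> 3 lambda_X2 delta2_structured      0.542      0.103       0.0540 0.723  1.90
#> 4 phi_F1.F2 delta2_structured      0.143      0.0984      0.0808 0.325  1.22
#> 5 lambda_X2 delta3_unstructured    0.542      0.103       0.0535 0.728  1.92
#> 6 phi_F1.F2 delta3_unstructured    0.143      0.0988      0.0831 0.293  1.19
```

Reading the first row: although only 40% of `X2` values are missing, the
nonlinear selection deletes the informative tails, so roughly 75% of the
sampling variance of the `X2` loading is due to missing data and its
confidence interval is about twice (`wif ≈ 2`) as wide as it would have
been with complete data. The factor correlation loses far less information
(`fmi ≈ 0.3`) from the same mechanism — missing rates alone would not have
revealed the difference.

Population-scale values (one sample of a million cases standing in for the
asymptote) come from `pseudo_population_fmi()`, and whole Monte-Carlo cells
from `simulation_condition()` + `run_condition()`, with `autoplot()` showing
the sampling distributions against the population value.

A thin command-line wrapper over the same functions ships in
`inst/cli/fmi_tool.R` (`simulate`, `fit`, `fmi`, `popfmi`, `study`
subcommands driven by flags or a YAML config).

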