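---
title: "Estimating the fraction of missing information from FIML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the fraction of missing information from FIML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmitools)
```

## Model and estimation

A mean-and-covariance structure model maps a free-parameter vector
$\theta$ (length $q$) to implied moments $\mu(\theta)$, $\Sigma(\theta)$ of
$p$ observed variables. Three families are built in: the saturated model
($\theta$ *is* the moment vector, $q = p + p(p+1)/2$), the bivariate
regression path model ($q = 5$; saturated, zero degrees of freedom), and
single-level CFA with simple structure under std.lv identification (latent
variances fixed at 1, all loadings, error variances, latent correlations and
indicator means free — $q = 25$ for the two-factor, eight-indicator model).

With ignorable (MAR) missingness and multivariate normality, estimation
maximizes the observed-data log-likelihood. Cases are grouped by
missingness pattern $g$, and each pattern contributes through its
sufficient statistics $(n_g, \bar{x}_g, S_g)$ only:

$$\ell(\theta) = \sum_g n_g\left[-\tfrac{p_g}{2}\log 2\pi
 - \tfrac12\log\lvert\Sigma_g(\theta)\rvert
 - \tfrac12\,\mathrm{tr}\{\Sigma_g(\theta)^{-1}(S_g + d_g d_g')\}\right],
 \qquad d_g = \bar{x}_g - \mu_g(\theta),$$

which equals the case-wise sum exactly. Pattern-level evaluation is what
makes million-case fits cheap: the cost scales with the number of patterns,
not cases.

`fit_fiml()` maximizes $\ell$ with a quasi-Newton pass (`stats::nlminb`,
variances log-transformed, correlations atanh-transformed) followed by a
damped Fisher-scoring polish that uses the *analytic* score
$\Delta(\theta)'\,g_{\text{h1}}$ and the first-dominant-term information
(below). The polish matters: finite-difference quasi-Newton alone leaves
the estimate slightly off the stationary point, and the exact coincidence
of the three FMI estimators on saturated models holds only at an accurate
optimum. Convergence is declared from the stationarity of the
log-likelihood itself, $\max_j |g_j| \le 10^{-5}\max(1, |\ell|)$ — the
gradient scale grows with $N$, so an absolute cutoff would be meaningless
across the sample sizes the package spans (50 to $10^6$). Non-convergence
is reported as `converged = FALSE`, never an exception, so replication
loops can count failures.

`fit_saturated_em()` estimates the unstructured mean and covariance by EM
on the same pattern statistics (conditional-normal sweeps per pattern),
stopping at a maximum moment change of $10^{-9}$ or relative
log-likelihood change of $10^{-10}$, capped at 10,000 iterations, then
applies the same Newton polish (EM converges linearly, so its stopping rule
alone can leave the moments $\sim 10^{-5}$ short). The recorded
log-likelihood trace is non-decreasing, which the tests assert.

## The three FMI estimators

For parameter $j$, $\delta_j = 1 - (J_X^{-1})_{jj}/(J_Y^{-1})_{jj}$, with
$J_Y$ the observed-data information at the estimate and $J_X$ the
information the sample would have carried complete. All information
matrices are kept on the total-sample scale so that
$SE_j = \sqrt{(J^{-1})_{jj}}$ directly; mixing per-case and total scales
would silently corrupt the ratio. Hessians are taken on the natural
(untransformed) parameter scale, because the FMI is defined for the
reported parameters.

* **delta1** — $J_Y$ is the negative central-difference Hessian of the
  observed-data log-likelihood; $J_X$ the negative Hessian of a
  complete-data log-likelihood for a pseudo-sample of size $N$ whose sample
  moments are pinned at the implied moments $\mu(\hat\theta)$,
  $\Sigma(\hat\theta)$.
* **delta2** — both sides use the analytic sandwich
  $\Delta'\,H_1(M)\,\Delta$, where $\Delta = \partial(\mu, \mathrm{vech}\,
  \Sigma)/\partial\theta'$ and $H_1$ is the unstructured observed
  information accumulated per pattern in closed form; $M$ is the implied
  moments.
* **delta3** — same sandwich, but $M$ is the saturated EM estimate on both
  the observed and the complete side ("unstructured estimates in all
  moment-dependent parts"), while $\Delta$ stays at $\hat\theta$.

The closed-form $H_1$ blocks (with $A = \Sigma_g^{-1}$,
$T = S_g + d_g d_g'$, $D$ the duplication matrix) are
$n_g A$ (means), $n_g (d_g'A \otimes A) D$ (mean–covariance), and
$\tfrac{n_g}{2} D'(A T A \otimes A + A \otimes A T A - A \otimes A)D$
(covariance). Rather than trusting the transcription, the test suite treats
the numeric Hessian of the saturated log-likelihood as the *normative
definition* and requires the closed form to reproduce it to $10^{-5}$
relative on randomized incomplete datasets.

Estimates with $\hat\delta_j < 0$ (possible in finite samples, where the
information ordering can be violated) are retained with
`status = "negative"` rather than truncated at zero — truncation would bias
Monte-Carlo summaries, so improper values are excluded from aggregation
instead, and a non-positive-definite information matrix marks all
parameters `undefined`. The width inflation factor
$1/\sqrt{1-\delta}$ is reported only for proper estimates.

## What the simulators emulate

`simulate_regression_population()` draws $Y = 0.4X + E$ with standard-normal
$X$ and $Y$; `simulate_two_factor_population()` draws two factors correlated
at $\phi = 0.4$ with four indicators each, loadings $\lambda = 0.49$ and
error variance $1 - \lambda^2$, so indicators have unit variance. (The
source designs describe indicators, factors *and* errors as standard
normal, which is arithmetically impossible with $\lambda = 0.49$; unit
indicator variance is the reading under which the published population FMI
values are reproducible, and it is what the generator implements.)

Missingness mechanisms delete target variables in *groups*: each group
draws one Bernoulli indicator per row, shared by its members. For the
regression design the single target $X$ is conditioned on $Y$; for the
two-factor design the pair $X_2, X_4$ shares one draw driven by
$C_X = X_1 + X_3$ and $Y_2, Y_4$ one driven by $C_Y = Y_1 + Y_3$. The
shared-draw design is deliberate: with independent per-target draws the
two-factor population FMIs come out systematically different (the loading
FMI about 0.05 higher, the correlation FMI lower), which we verified both
by million-case simulation and by an exact expected-information computation
over pattern probabilities; only the shared-draw design reproduces the
published values, for the loading and the correlation simultaneously, so it
is evidently how the original study drew its missingness.

Selection uses percentile cutoffs. Given the high/low missing
probabilities $\pi_1 = 0.9$, $\pi_2 = 0.1$ and a target rate
$\pi_{mis}$, the high-risk mass $\pi_c = (\pi_{mis}-\pi_1)/(\pi_2-\pi_1)$
makes the marginal rate exactly $\pi_{mis}$; linear MAR puts the $\pi_1$
region above $\Phi^{-1}(\pi_c)$ on the standardized conditioner, nonlinear
MAR outside $\pm\Phi^{-1}(0.5 + 0.5\pi_c)$ (both tails, hence more
information loss at equal rates). Conditioners are standardized by their
*theoretical* SD ($1$ for $Y$; $\sqrt{2+2\lambda^2}$ for the indicator
sums) — the cutoffs are population percentiles, and the same population
logic is applied to the sums; with sample SDs the realized rates would
drift in small samples. Each dataset uses one master seed with disjoint
substreams for the complete-data draw and the missingness draw, so
mechanisms can be swapped on identical complete data.

What the generators do *not* emulate: non-normal data, MNAR selection,
weak (more probabilistic) MAR, missingness on conditioning variables, and
model misspecification. Passing tests therefore certify the estimators
under a correctly specified normal model with strong ignorable selection —
not robustness beyond it.

## Monte-Carlo harness

`pseudo_population_fmi()` computes per-parameter FMIs from a single
$N = 10^6$ sample as a stand-in for the asymptote, computing all three
variants, checking their maximum discrepancy (they must agree at that
scale; the value is attached as an attribute) and reporting the
unstructured variant. `run_condition()` runs `n_rep` independent
replicates (replicate $i$ seeds with `base_seed + i`), classifies failures
(non-converged fit → all parameters undefined; converged but non-PD
information → undefined; negative FMI → improper), and summarizes raw bias,
RMSE and the 95% equal-tailed-interval width over proper estimates only —
exclusion is per parameter, matching per-parameter reporting. Quantiles
use linear interpolation (`type = 7`, the common default; the choice moves
ETI widths by $O(1/n_{rep})$). Identical conditions reproduce bit-identical
summaries.

## Numerical choices

* vech ordering: lower-triangular, column-major, diagonal included —
  stated once, used everywhere (moment stacking, Jacobians, duplication
  matrices).
* Jacobian $\Delta$: central differences with step
  $10^{-5}\max(1,|\theta_j|)$, validated by step-halving; the saturated
  model returns the exact identity.
* Numeric Hessians: central differences, step $10^{-4}\max(1,|x_j|)$,
  symmetrized.
* Starting values: saturated EM moments inverted into the structured
  parameterization (regression: moment inversion; CFA: loadings from
  average within-block covariances, correlation from the cross-block
  average, error variances from the residual diagonal), falling back to
  available-case moments if EM fails.
* Degenerate inputs (e.g. fewer cases than needed): EM reports
  `converged = FALSE` instead of raising on singular pattern submatrices,
  and `compute_fmi()` returns an all-`undefined` table.
* All-missing rows contribute nothing to the likelihood and are dropped
  with a count.

## Problem sizes

The test suite exercises closed-form oracles at $n \le 300$, cross-method
and EM-vs-optimizer checks at $n \le 1000$, population-scale recovery on
one $10^6$-case sample per design cell, and a 300-replication Monte-Carlo
cell at $N = 500$ — sizes chosen so the full suite completes in minutes
while keeping Monte-Carlo error well inside the assertion tolerances.

## Limitations

Standard errors and FMIs assume a correctly specified model; under
misspecification only the Hessian variant remains consistent, and that
regime is deliberately out of scope here, as are multiple-imputation FMI,
bootstrap standard errors for FMI, sandwich/robust information, and general
SEM syntax beyond single-level simple-structure CFA.
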