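---
title: "Testing mean and variance effects with jointvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing mean and variance effects with jointvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointvar)
```

Most association analyses of continuous outcomes ask whether an exposure
shifts the *mean* of the outcome. Whether the exposure changes the
*variability* of the outcome is informative too — variance heterogeneity can
flag gene–environment interaction, treatment-response heterogeneity, or
violations of instrumental-variable assumptions — and in high-dimensional
settings such as epigenome-wide association studies (EWAS) a single joint
test of "any mean or variance effect" can be more powerful than running two
tests and correcting. This vignette describes the models and tests the
package implements, the choices behind them, and what the simulation
machinery does and does not emulate.

## Location test

The mean model is the ordinary linear regression

$$ y_i = \alpha + x_i'\beta + \varepsilon_i, $$

fit by OLS, with a z-test per exposure coefficient and a joint Wald test
across the exposure columns (`location_test()`). Two covariance estimators
are offered: the classical $\hat\sigma^2 (X'X)^{-1}$ and the HC1
degrees-of-freedom-scaled sandwich, which stays valid when
$\mathrm{Var}(\varepsilon_i)$ depends on $x_i$. HC1 was chosen as the
finite-sample default among the HC family; the package's hand-computed
covariances are verified in the test suite against `lm()` plus
`sandwich::vcovHC(type = "HC1")`.

## Scale tests

For a categorical exposure, the Brown-Forsythe test (`brown_forsythe()`)
runs a one-way ANOVA of $z_{ij} = |y_{ij} - \tilde y_j|$, the absolute
deviations from group medians, with an $F_{k-1,\,n-k}$ null. Using medians
rather than means is what makes the test robust to heavy tails and
outliers; Bartlett's test (`bartlett_test()`, provided mainly as the
cautionary comparator and delegated to `stats::bartlett.test()`) is
exquisitely sensitive to non-normality and on skewed data behaves as a test
of non-normality rather than of variance heterogeneity.

The Brown-Forsythe test has an exact regression reformulation
(`brown_forsythe_ext()`): (i) fit a least absolute deviation (LAD)
regression of the outcome on exposure and covariates and keep the absolute
residuals $d_i$; (ii) regress $d_i$ on the same columns by OLS and apply a
partial F-test to the exposure columns. For a categorical exposure without
covariates the LAD fit is exactly the group medians, so the two forms agree
to machine precision — the package's categorical LAD fast path and the
classic test share the same median convention (average of the two middle
order statistics for even groups) precisely so this equivalence is exact.
The regression form does not require a categorical exposure, which is the
point: with continuous exposures it has the structure of the Glejser and
Breusch–Pagan heteroskedasticity tests. Stage 2 regresses $d_i$ on the
identity of the exposure columns; nonlinear spread patterns (for example a
spread symmetric in a centered exposure) need explicit extra columns such
as a squared exposure, and a spread that is purely symmetric in the
exposure is invisible to the identity form by construction.

### The LAD solver

No linear-programming or quantile-regression dependency is used. The
solver is iteratively reweighted least squares (IRLS) with
epsilon-smoothing of the absolute value (floor $10^{-8}$ on the scaled
residual), followed by an exact *vertex polish*: an LAD optimum
interpolates at least $p+1$ observations, so the solver fits exactly
through subsets of the current smallest-absolute-residual points and
accepts any strict improvement, stopping at a fixed point. Plain IRLS
crawls near such vertices (linear convergence along a face of the
objective); the polish lands on the vertex exactly, and on small instances
matches a brute-force search over all interpolating point pairs to
$10^{-8}$. Purely categorical designs bypass the solver for exact group
medians. Convergence failures raise an error carrying the iteration count
and last step size rather than returning a doubtful fit.

## Joint tests

`jlsp()` combines the location p-value and the extended Brown-Forsythe
p-value with Fisher's method, $-2(\log p_1 + \log p_2) \sim \chi^2_4$.
This is valid when the two p-values are independent, which holds for
symmetric outcomes; for skewed outcomes the mean and variance estimates
are correlated and JLSp inflates (reproduced in the acceptance tests under
log-normal nulls).

`jlssc()` is a joint *score* test that accounts for that correlation. With
$\tilde y_i = y_i - \bar y$, $\tilde x_i = x_i - \bar x$,
$\hat\sigma^2 = \tfrac1n\sum \tilde y_i^2$ and
$\tilde d_i = \tilde y_i^2 - \hat\sigma^2$, it estimates

$$ \hat\beta = (\tilde X'\tilde X)^{-1}\tilde X'\tilde y, \qquad
   \hat\delta = (\tilde X'\tilde X)^{-1}\tilde X'\tilde d, $$

stacks $\hat\theta = (\hat\beta, \hat\delta)$, and forms

$$ S = \hat\theta' \left( \hat\Sigma^{-1} \otimes \tilde X'\tilde X \right) \hat\theta,
   \qquad
   \hat\Sigma = \frac1n \sum_i
   \begin{pmatrix} \tilde y_i^2 & \tilde y_i \tilde d_i \\
                   \tilde y_i \tilde d_i & \tilde d_i^2 \end{pmatrix}, $$

with $S \sim \chi^2_{2k_x}$ under the joint null of no mean and no
variance effect ($k_x$ = number of exposure columns). Two structural
points matter. First, the auxiliary variable is the squared *globally
centered* outcome, not a squared OLS residual: the mean restriction
$\beta = 0$ is imposed under the null, which enhances power relative to
the Breusch–Pagan construction with $\hat\varepsilon_i^2$. Second, the
default $\hat\Sigma$ is consistent under the additional assumption that
the conditional skewness and kurtosis of the outcome given the exposure
are constant (automatic under normality); the result records this
assumption in its state. $S$ is invariant to affine transforms of $y$ and
to invertible linear transforms of the exposure block — both asserted
numerically in the tests.

`jlssc(robust = TRUE)` drops the constant-skewness/kurtosis assumption by
replacing the Kronecker covariance with a stacked estimating-equation
sandwich built from the per-observation moment contributions
$g_i = (\tilde x_i \tilde y_i,\; \tilde x_i \tilde d_i)$:
$\hat V = (I_2 \otimes (\tilde X'\tilde X)^{-1})\, \sum_i g_i g_i' \,
(I_2 \otimes (\tilde X'\tilde X)^{-1})$ and
$S_{\text{robust}} = \hat\theta' \hat V^{-1} \hat\theta$. This is the
standard estimating-equation route to dropping the moment assumption; it
is this package's construction (no external reference implementation is
claimed), agrees with the plain statistic under normality at large $n$,
and pays for its robustness with some power, both verified in tests.

Covariates ("adjust for, don't test") are removed by OLS residualization
of *both* the outcome and every exposure column before the score test;
regression-style tests instead carry covariates as model columns in all
stages. Categorical exposures expand to $k-1$ indicators against the first
sorted level, giving $2(k-1)$ degrees of freedom. An optional squared
centered-exposure block doubles $k_x$ and targets variance effects that
are nonlinear in a continuous exposure; with squared terms or small
categorical groups, trimming outcome outliers (`outlier_sd = 3`) is
advisable to preserve the test's size, and the trimming is always
reported, never silent.

### Numerical safeguards

Degenerate situations raise typed errors rather than silently producing
numbers: constant outcomes (zero variance), a moment matrix $\hat\Sigma$
with condition number above $10^{12}$, rank-deficient designs (the error
names the collinear columns), groups smaller than two for grouped tests,
and zero within-group spread for the Brown-Forsythe denominator. P-values
are floored at the smallest positive double so $-\log_{10} p$ stays
finite; no multiplicity correction happens inside test functions
(`adjust_pvalues()` is available downstream).

## Transformations

`m_value()` maps methylation beta values through
$\log_2\!\big(y/(1-y)\big)$, and `inverse_normal_rank()` maps ranks
through normal quantiles with the Blom offset,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, average ranks for ties. The
Blom offset is the conventional default in genetic-epidemiology pipelines;
the transform is applied per feature, before any covariate adjustment.
Forcing marginal normality restores the calibration of
normality-dependent tests, but it distorts mean/variance attribution: on a
skewed outcome a pure location shift becomes a variability signal after
the transform (the package's tests reproduce this — Brown-Forsythe
rejection near 100% on rank-transformed log-normal data with only a mean
effect). With a balanced binary exposure and a *symmetric* outcome the
two groups are mirror-image slices of the pooled distribution and no
variance difference is induced; the caveat bites exactly when the raw
outcome is skewed or the groups are unbalanced. `remove_outliers()` is the
single-pass 3-SD rule; it never re-iterates after removal.

## What the simulator emulates

`gen_cpg_profiles()` draws per-feature (mean, SD) pairs from a
three-component mixture: low-methylated (mean 0.03–0.15), high-methylated
(0.85–0.97) and intermediate (0.20–0.80) features with weights
0.35/0.35/0.30, SD a uniform fraction of the feasibility bound
$\sqrt{m(1-m)}$ (up to 0.30 for boundary features, 0.35 for intermediate
ones). Instantiated as method-of-moments beta distributions at $n = 500$, a
clear majority of features have sample skewness in $(-1, 1)$ and excess
kurtosis below 3 (the test suite checks at least 60% and 65%
respectively) — the near-symmetric majority plus a strongly skewed
minority characteristic of array methylation data. The generated
features are somewhat lighter-tailed than real arrays (real data has more
extreme-kurtosis sites, and probe-level artifacts, batch structure and
inter-feature correlation are not modelled at all), so calibration results
here understate how badly normality-dependent tests misbehave on real
data, and "passing" simulations do not certify behaviour under batch
effects or correlated features. For robustness contrasts the strongly
skewed subset is defined as implied beta skewness $\ge 1.5$ in absolute
value (`profile_skewness()`).

`gen_outcome()` adds effects on the beta-distributed baseline: a mean
effect of `mean_effect` feature-SDs per unit of centered exposure, and a
variance effect scaling the centered residual by
$(1 + \texttt{var\_effect})^{z}$ with $z$ the standardized exposure, so
`var_effect = 1` doubles the SD per SD of exposure (for a binary exposure:
between groups). Residual families are moment-matched to $(0, s^2)$:
normal, rescaled $t_4$ (heavy-tailed), shifted log-normal (skewed).
Values are clipped to $(10^{-6}, 1-10^{-6})$ so the M-value stays defined.
These effect constructions are this package's own concrete choices — power
curves are qualitatively comparable to published methylation simulations,
not numerically identical to any external study.

The experiment engines (`type1_experiment()`, `power_experiment()`) use
the standard exposure generators — Bernoulli(0.5), N(0,1), Binomial(2,
0.3) for three categories — plus null-outcome menus including
log-normal(0,1) and the contaminated normal 90% N(0,1) + 10% N(5,1).
Power is the proportion of replicates below $p < 10^{-7}$ with 1000
replicates at $n = 1000$ by default. Every replicate's seed is spawned
deterministically from the master seed by a counter scheme, so results
are bit-reproducible across process restarts and any replicate can be
re-run in isolation. The engines are test-agnostic: any named callable
`(y, x, covariates) -> p` can be benchmarked alongside the built-in
registry.

Problem sizes in the shipped tests are the package's own choices:
module-level calibration checks run at 1,500–2,000 replicates with
3-Monte-Carlo-SE bands; the end-to-end acceptance checks run the headline
claims at 5,000–10,000 replicates and $n = 1000$.

## Known limitations

* The score test's $\chi^2$ reference is asymptotic; it relies on 4th
  (and, for the variance of $\hat\delta$, up to 8th) moments. With a
  **binary** exposure and strongly skewed outcomes (log-normal), jlssc is
  *conservative* rather than inflated — rejection sits below the nominal
  5% level because the tail moments converge slowly — and power in that
  corner is correspondingly reduced. With a continuous exposure,
  calibration at $n = 1000$ is accurate (this is the arm the acceptance
  checks exercise).
* The identity stage-2 regression of the extended Brown-Forsythe test has
  no power against spread patterns orthogonal to the exposure columns
  (for example SD proportional to $|x|$ for a centered symmetric $x$);
  add explicit squared-exposure columns for such alternatives.
* JLSp's components use the classical location p-value; under
  heteroskedastic non-null mean structure its location component inherits
  classical-OLS fragility. Use the sandwich location test directly when
  the mean effect itself is the target under heteroskedasticity.
* The scan treats features independently; no shrinkage across features,
  no surrogate-variable or cell-composition estimation (covariates
  computed upstream enter as ordinary columns).
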