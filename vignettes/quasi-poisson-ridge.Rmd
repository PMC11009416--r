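---
title: "Ridge shrinkage for overdispersed quasi-Poisson regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ridge shrinkage for overdispersed quasi-Poisson regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpridge)
```

## The model

Count responses in epidemiology and the social sciences are routinely more
variable than a Poisson model allows. The quasi-Poisson model keeps the
log-linear mean structure but frees the variance:

$$\mathrm{E}(y_i) = \mu_i = \exp(x_i'\beta), \qquad
  \mathrm{Var}(y_i) = \gamma \mu_i,$$

with a dispersion factor $\gamma \ge 1$. Only these two moments are
specified — there is no likelihood — so estimation maximises the
quasi-log-likelihood $\frac{1}{\gamma}\sum_i (y_i \log\mu_i - \mu_i)$ via
iteratively reweighted least squares (IWLS). Because $\gamma$ multiplies
the whole objective it cancels from the coefficient update; `fit_qle()`
therefore stores the weight matrix as $\hat W = \mathrm{diag}(\hat\mu)$,
the cross-product as $F = X'\hat W X$, and carries the Pearson estimate

$$\hat\gamma = \frac{1}{n - p - 1} \sum_i
  \frac{(y_i - \hat\mu_i)^2}{\hat\mu_i}$$

as a separate scalar, which makes the estimator's covariance literally
$\hat\gamma F^{-1}$ and its scalar mean squared error
$\hat\gamma \sum_j 1/\lambda_j$, with $\lambda_j$ the eigenvalues of $F$.
The Pearson form is the standard quasi-likelihood convention (it is what
`glm(..., family = quasipoisson)` reports, and the test suite uses that fit
as an independent oracle).

## Why ridge

When regressors are nearly collinear, the smallest eigenvalues of $F$
approach zero and $\sum_j 1/\lambda_j$ explodes: the quasi-likelihood
estimator (QLE) remains consistent but its variance is useless in finite
samples. The ridge estimator trades a little bias for a lot of variance:

$$\hat\beta_k = (F + kI)^{-1} F\, \hat\beta_{QLE}, \qquad k \ge 0.$$

All of its exact finite-sample theory is diagonal in the canonical frame
$F = T \Lambda T'$, $\alpha = T'\beta$ (`eigen_decompose()`):

$$\mathrm{MSE}(\hat\beta_k)
  = \underbrace{\hat\gamma\sum_j \frac{\lambda_j}{(\lambda_j+k)^2}}_{M_1(k),
  \text{ variance}}
  + \underbrace{k^2 \sum_j \frac{\alpha_j^2}{(\lambda_j+k)^2}}_{M_2(k),
  \text{ squared bias}}.$$

$M_1$ is strictly decreasing and $M_2$ strictly increasing in $k$, and the
derivative of their sum is negative for all
$k < \hat\gamma / \max_j \alpha_j^2$, so some $k > 0$ always beats $k = 0$.
The package checks both statements numerically on random eigen-systems
rather than symbolically; `mse_derivative()` exposes the closed-form
derivatives so the property tests can compare them to finite differences.
(The printed sufficient condition in the source literature for this class
of estimator contains an obvious sign typo; the corrected bound above is
what the tests verify.)

Two open choices were settled as follows and matter when comparing to other
implementations:

* **The intercept is penalised** along with the slopes — the estimator uses
  the full $(p+1)$-dimensional identity. An unpenalised-intercept variant
  would change every number downstream; the literal full-identity form is
  the definition implemented.
* **Bias evaluation point.** The bias formula needs a coefficient vector.
  For data fits the moments are evaluated at $\hat\beta_{QLE}$ (the only
  vector available); inside simulations the Monte-Carlo MSE is computed
  against the true $\beta$ directly, so no plug-in is involved there.

## The sixteen biasing-parameter rules

`ridge_k()` implements sixteen closed-form rules `k1`–`k16`, all functions
of $(\hat\alpha_j, \hat\lambda_j, \hat\gamma, p+1)$; `fit_qprre()` runs the
whole pipeline and `all_rules_table()` tabulates every rule against the QLE
on one dataset. Conventions fixed here:

* medians over an even number of terms are the mean of the two central
  values (tested against a sort-based oracle);
* $\hat\alpha^2_{min}$ in `k5` means $\min_j \hat\alpha_j^2$;
* `k11` uses the polynomial form $\sum_j r_j(2 + r_j^2)$,
  $r_j = \hat\gamma/\hat\alpha_j^2$, as its defining formula. This grows
  like $r_j^3$ and routinely produces enormous $k$ — essentially full
  shrinkage, with scalar MSE near $\beta'\beta$ — which is consistent with
  how the rule behaves in published comparisons. The square-root variant
  $\sum_j r_j(1 + \sqrt{1+r_j^2})$ familiar from the ridge literature is
  available behind `k11_sqrt = TRUE` but is never the default.
* rules dividing by individual $\hat\alpha_j^2$ (`k3`, `k10`, `k11`,
  `k13`, `k14`) refuse exactly-zero components with an error naming the
  rule.

## The synthetic-data generator

The Monte-Carlo engine is first-class, tested code, not a fixture. Its
defaults are the study conditions the package is designed around:

* **Regressors** (`gen_design()`):
  $x_{ij} = (1-\rho^2)^{1/2} z_{ij} + \rho z_{i,p+1}$ with iid standard
  normal $z$ — the classical shared-component construction. Every column
  has mean 0 and variance 1 and every pair correlates at $\rho^2$, so
  $\rho \in \{0.80, 0.90, 0.95, 0.99\}$ spans moderate to near-degenerate
  collinearity. An adjacent-column variant (`literal = TRUE`), which
  couples only neighbouring columns at correlation
  $\rho\sqrt{1-\rho}/(1-\rho+\rho^2)$ and has non-unit variance, is kept
  for comparison because it appears verbatim in parts of this literature;
  it is not the default precisely because it does not deliver the claimed
  $\rho^2$ correlation.
* **Coefficients** (`gen_beta()`): the normalisation
  $\sum_{j=1}^{p+1}\beta_j^2 = 1$ (intercept included) with equal
  components $1/\sqrt{p+1}$ — the most common convention in ridge
  simulation studies. The "eigenvector of the largest eigenvalue"
  alternative is available via `scheme = "eigen"`.
* **Counts** (`gen_response()`): "quasi-Poisson with $\mathrm{Var} =
  \gamma\mu$" does not pin down a distribution, so a sampler had to be
  chosen: Poisson at $\gamma = 1$, and negative binomial with mean $\mu_i$
  and size $\mu_i/(\gamma-1)$ for $\gamma > 1$, which matches the first two
  moments exactly. Under-dispersion is rejected. Other samplers with the
  same two moments (e.g. rescaled Poisson) would differ in higher moments;
  results that depend on tail behaviour, not just on mean and variance, are
  therefore sampler-specific.

What passing simulation tests show — and do not show — about real data:
the generator produces standardized, jointly normal regressors,
exchangeable correlation, and exactly moment-matched counts. Real designs
have skewed regressors on wildly different scales, unequal pairwise
correlations, and zero inflation or heavier tails; the qualitative findings
(ridge dominates the QLE under collinearity, the gap grows with $\rho$ and
shrinks with $n$) transfer, the numeric MSE levels do not.

## The Monte-Carlo engine

`run_cell()` draws a fresh $(X, y)$ per replication, fits every requested
estimator, and averages $(\hat\beta - \beta)'(\hat\beta - \beta)$ over
replications — the standard Monte-Carlo estimate of scalar MSE against the
true coefficients. Replications where IWLS diverges (rare, but real at
$\gamma = 6$, $\rho = 0.99$, $n = 25$) are dropped and counted per
estimator rather than imputed, so a wildly divergent iterate cannot
contaminate a cell average; the `failures` column makes the censoring
visible. Each replication reseeds deterministically from the cell seed, and
each grid cell derives its seed from the master seed by a fixed integer
hash, so grids are reproducible byte-for-byte and cells can be recomputed
in isolation. The full published-style grid
($n$ up to 200, $p \in \{3,6,12\}$, $\gamma \in \{2,4,6\}$, four $\rho$
levels, 2000 replications) is supported by the engine; the package's own
test and acceptance runs use a reduced design — $p = 3$, $\gamma = 2$,
$\rho \in \{0.90, 0.99\}$, $n \in \{50, 150\}$, 200 replications — which is
ample to establish the ordering and trend claims it asserts.

## Diagnostics

* `condition_index()` — $\sqrt{\lambda_{max}/\lambda_{min}}$ of $X'X$ on
  the raw, intercept-augmented design, no centering or scaling; values
  above 30 flag severe collinearity. Orientation is max over min, so the
  index is always $\ge 1$.
* `hat_diagonals()` — the model never defines a hat matrix by itself, so
  the standard weighted ridge hat matrix
  $W^{1/2}X(X'WX + kI)^{-1}X'W^{1/2}$ is used; it reduces to the familiar
  projection at $W = I$, $k = 0$, where its trace is $p+1$.
* `press()` — mean of squared Pearson residuals
  $\chi_i = (y_i - \hat\mu_i)/\sqrt{\hat\gamma\hat\mu_i}$ inflated by
  $(1-h_{ii})^{-2}$, with ridge fitted means and ridge leverages for a
  ridge fit. The same code path serves $k = 0$.
* `kfold_cv()` — seeded shuffle into folds (default 5), refit per training
  fold, squared error of held-out means on the response scale. Fold count
  and loss are configurable because no single convention is canonical;
  published CV numbers for this estimator family are not reproducible
  without knowing the fold assignment, and are not treated as benchmarks
  here.

## Numerical choices

* IWLS starts from least squares on $\log(y + 0.5)$, stops when the
  largest relative coefficient change drops below $10^{-8}$, caps at 100
  iterations, and solves each weighted system by Cholesky. Non-convergence
  raises a typed condition (`qpridge_no_convergence`) carrying the last
  iterate.
* Fitted means are floored at $10^{-10}$ so working responses and Pearson
  residuals stay finite when a linear predictor dives.
* Eigenvector columns are sign-fixed (largest-magnitude entry positive) and
  eigenvalues sorted descending, purely for reproducibility; every reported
  quantity is invariant to both choices, and a test flips signs to prove
  it.
* Exact identities (ridge at $k=0$ equals the QLE; scalar MSE equals
  trace of the matrix MSE; canonical and matrix shrinkage routes agree) are
  asserted at $10^{-10}$, everything stochastic at tolerances derived from
  its Monte-Carlo standard error.

## A worked example

```{r example}
set.seed(42)
X <- gen_design(n = 100, p = 3, rho = 0.95)
y <- gen_response(cbind(1, X), gen_beta(3), gamma = 2)
d <- count_dataset(X, y)

condition_index(d)            # collinearity severity of this draw
fit <- fit_qprre(d, rule = "k7")
fit
head(all_rules_table(d)[, c("estimator", "k", "mse")], 8)
```

## Limitations

* No offsets, exposure terms, user weights, or links other than log; no
  negative-binomial or Conway–Maxwell alternatives.
* The bundled theory is finite-sample-exact only conditional on $F$ and
  $\hat\gamma$; it does not account for the variability of $\hat\gamma$
  itself.
* Published numeric MSE tables for this estimator family depend on
  generator details (coefficient direction, sampler) that are not
  recoverable from their descriptions; this package reproduces their
  qualitative structure — dominance and monotone trends — not their cell
  values.
* `k11`'s literal polynomial form means it is effectively a full-shrinkage
  estimator; users wanting the milder classical behaviour must opt into
  `k11_sqrt = TRUE`.
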