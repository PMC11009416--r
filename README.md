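# qpridge

Ridge-shrinkage estimation for overdispersed count regression.

Count data whose variance exceeds its mean — hospital admissions, migration
counts, insurance claims — are modelled by the quasi-Poisson regression
model: a log-linear mean `E(y_i) = μ_i = exp(x_i'β)` with variance
`Var(y_i) = γ μ_i` and no further distributional assumptions. The
quasi-likelihood estimator (QLE) of `β` is computed by iteratively
reweighted least squares; its covariance is `γ̂ F⁻¹` with
`F = X' diag(μ̂) X`. When regressors are collinear the smallest eigenvalues
of `F` collapse and the QLE's scalar mean squared error
`γ̂ Σ_j 1/λ_j` explodes.

`qpridge` implements the ridge (biasing-parameter) remedy for this model:

    β̂_k = (F + kI)⁻¹ F β̂_QLE,   k ≥ 0,

with its exact finite-sample bias, covariance, and mean squared error in
the canonical frame `F = T Λ T'`, `α = T'β`:

    MSE(β̂_k) = γ̂ Σ_j λ_j/(λ_j+k)²  +  k² Σ_j α_j²/(λ_j+k)²
              = M₁(k) [variance]    +  M₂(k) [squared bias].

Sixteen closed-form rules `k1`–`k16` (Hoerl–Kennard-type and aggregation
variants) choose `k` from the data, a Monte-Carlo engine compares
estimators over grids of sample size, dispersion and collinearity, and
diagnostics cover the condition index, Pearson-residual PRESS, and k-fold
cross-validation. The package is aimed at biostatisticians and
epidemiologists fitting overdispersed count models on correlated
predictors, and at methodologists benchmarking ridge-parameter rules.

## A worked example

```r
library(qpridge)
set.seed(42)
X <- gen_design(n = 100, p = 3, rho = 0.95)   # pairwise corr rho^2 = 0.9025
y <- gen_response(cbind(1, X), gen_beta(3), gamma = 2)
d <- count_dataset(X, y)

condition_index(d)
#> [1] 5.370435

fit <- fit_qprre(d, rule = "k7")
fit
#> Quasi-Poisson ridge fit: rule = k7 , k = 25.6332
#> Scalar MSE = 0.0723413 (variance 0.06489 + squared bias 0.007451 )
#> (Intercept)          x1          x2          x3
#>   0.3555681   0.5434111   0.4387093   0.5850776

head(all_rules_table(d)[, c("estimator", "k", "mse")], 8)
#>   estimator           k        mse
#> 1       QLE    0.000000 0.21112687
#> 2        k1    2.613531 0.17726103
#> 3        k2   10.454125 0.11819555
#> 4        k3 1001.551246 0.08050517
#> 5        k4   14.167141 0.10195679
#> 6        k5   66.017498 0.04140638
#> 7        k6   31.639285 0.06341029
#> 8        k7   25.633202 0.07234125
```

The `mse` column is the analytic scalar MSE at each rule's `k`: every rule
here improves on the unshrunk QLE (0.211), with the largest gains from the
heavier-shrinking rules — the variance term falls much faster than the
squared bias grows. `fit$k` is the chosen biasing parameter; `fit$beta_k`
the shrunk coefficients; `fit$bias`, `fit$cov`, `fit$mmse` the exact
finite-sample moments at that `k`.

A command-line interface is installed as `exec/qpridge`:

```sh
qpridge fixtures --n 200 --p 3 --gamma 2 --rho 0.9 --seed 1 --out data.csv
qpridge fit data.csv --response y --rule k7
qpridge fit data.csv --response y --all-rules
qpridge simulate --n 50,150 --p 3 --gamma 2 --rho 0.9,0.99 --reps 200 --seed 42 --out mse.csv
qpridge diagnose data.csv --response y --rule k7 --folds 5 --seed 1
```

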