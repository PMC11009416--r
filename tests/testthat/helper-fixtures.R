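# Shared fixture builders: every dataset used in the tests is generated in
# code from the package's own simulation generators.

make_sim_dataset <- function(n = 60, p = 3, gamma = 2, rho = 0.9, seed = 1) {
  set.seed(seed)
  X <- gen_design(n, p, rho)
  beta <- gen_beta(p)
  y <- gen_response(cbind(1, X), beta, gamma)
  list(data = count_dataset(X, y), beta = beta)
}

# A random well-conditioned eigen-system (lambdas, alpha, gamma) for theory
# checks that do not need a dataset behind them.
make_eigen_system <- function(q = 4, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(q * q), q)
  F <- crossprod(A) + diag(q) * 0.1
  beta <- rnorm(q)
  list(eig = eigen_decompose(F, beta), F = F, beta = beta,
       gamma = runif(1, 0.5, 5))
}

# Reference values on the worked two-coordinate example
# alpha = (1, 2), lambda = (4, 1), gamma = 2 for all sixteen k-rules,
# computed by hand from the printed formulas.
hand_k_values <- function() {
  c(k1 = 0.4, k2 = 0.8, k3 = 2, k4 = 0.35,
    # k5: 2 min(a2)=2; terms 2/(2+0.5)=0.8, 2/(2+2)=0.5; median 0.65
    k5 = 0.65,
    # k6: (2/2)*(1/(2+0.5) + 1/(8+2)) = 0.4 + 0.1 = 0.5
    k6 = 0.5,
    # k7: terms 2/2.5=0.8, 2/10=0.2; median 0.5
    k7 = 0.5,
    # k8: (1/2)*max(2/(2+2), 2/(8+2)) = 0.25
    k8 = 0.25,
    # k9: sqrt(0.8 * 0.2)
    k9 = sqrt(0.16),
    # k10: min(2*4/1, 2*1/4) = 0.5
    k10 = 0.5,
    # k11: r = (2, 0.5); sum r(2 + r^2) = 2*6 + 0.5*2.25 = 13.125
    k11 = 13.125,
    # k12: 4*2/(2+4) + 1*2/(2+4) = 8/6 + 2/6 = 5/3
    k12 = 5 / 3,
    k13 = 0.25, k14 = 1.25,
    # k15: 4/(1+8) + 1/(1+8) = 5/9
    k15 = 5 / 9,
    # k16: 2 * (0.8 + 0.2) = 2
    k16 = 2)
}
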