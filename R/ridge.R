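#' Canonical (eigenvector) form of a quasi-Poisson fit
#'
#' Diagonalises the weighted cross-product matrix \eqn{F = X'\hat W X} as
#' \eqn{F = T \Lambda T'} and rotates the coefficient vector into the
#' canonical coordinates \eqn{\hat\alpha = T'\hat\beta}. Every ridge-parameter
#' rule and every closed-form MSE expression in this package is diagonal in
#' these coordinates.
#'
#' Eigenvalues are returned in descending order. For determinism the sign of
#' each eigenvector is fixed so that its largest-magnitude entry is positive;
#' all downstream quantities are invariant to this choice.
#'
#' @param F symmetric positive semi-definite matrix.
#' @param beta coefficient vector to rotate (usually the QLE).
#' @return An object of class `eigen_system`: list with `lambdas`, the
#'   orthogonal matrix `T` (eigenvectors in columns) and `alpha`.
#' @export
eigen_decompose <- function(F, beta) {
  F <- as.matrix(F)
  if (max(abs(F - t(F))) > 1e-8 * max(1, max(abs(F)))) {
    stop("F must be symmetric", call. = FALSE)
  }
  beta <- as.numeric(beta)
  if (length(beta) != ncol(F)) stop("beta has wrong length", call. = FALSE)
  es <- eigen((F + t(F)) / 2, symmetric = TRUE)
  Tm <- es$vectors
  for (j in seq_len(ncol(Tm))) {
    i <- which.max(abs(Tm[, j]))
    if (Tm[i, j] < 0) Tm[, j] <- -Tm[, j]
  }
  structure(
    list(lambdas = es$values, T = Tm, alpha = drop(crossprod(Tm, beta))),
    class = "eigen_system"
  )
}

#' Ridge coefficients for the quasi-Poisson model
#'
#' The quasi-Poisson ridge estimator shrinks the quasi-likelihood estimate
#' towards zero:
#' \deqn{\hat\beta_k = (F + kI)^{-1} F \hat\beta_{QLE}.}
#' In canonical coordinates each component is multiplied by
#' \eqn{\lambda_j / (\lambda_j + k)}, so `k = 0` returns the QLE unchanged
#' and \eqn{k \to \infty} shrinks every coefficient to zero. The intercept
#' is penalised along with the slopes (all `p + 1` coefficients).
#'
#' @param F weighted cross-product matrix \eqn{X'\hat W X}.
#' @param beta_qle quasi-likelihood coefficient vector.
#' @param k non-negative biasing (ridge) parameter.
#' @return The shrunk coefficient vector.
#' @export
ridge_coefficients <- function(F, beta_qle, k) {
  if (length(k) != 1 || !is.finite(k) || k < 0) {
    stop("k must be a single non-negative number", call. = FALSE)
  }
  F <- as.matrix(F)
  drop(solve(F + diag(k, nrow(F)), F %*% as.numeric(beta_qle)))
}

#' Exact moments of the ridge estimator at a given k
#'
#' Closed-form bias, covariance, matrix MSE and scalar MSE of the
#' quasi-Poisson ridge estimator evaluated at a coefficient vector `beta`
#' (the QLE for data fits; the true coefficients inside simulations). With
#' \eqn{\Lambda_k = \mathrm{diag}(\lambda_j + k)} and
#' \eqn{\alpha = T'\beta}:
#' \deqn{\mathrm{Bias} = -k\, T \Lambda_k^{-1} \alpha, \qquad
#'   \mathrm{Cov} = \gamma\, T \Lambda_k^{-1} \Lambda \Lambda_k^{-1} T',}
#' \deqn{\mathrm{MMSE} = \mathrm{Cov} + \mathrm{Bias}\,\mathrm{Bias}', \qquad
#'   \mathrm{MSE} = \underbrace{\gamma \sum_j
#'   \frac{\lambda_j}{(\lambda_j + k)^2}}_{M_1(k)} +
#'   \underbrace{k^2 \sum_j \frac{\alpha_j^2}{(\lambda_j + k)^2}}_{M_2(k)}.}
#' \eqn{M_1} is the variance term (decreasing in `k`), \eqn{M_2} the squared
#' bias (increasing in `k`); their sum equals the trace of the matrix MSE.
#'
#' @param eig an [eigen_decompose()] result; its `alpha` must be the
#'   rotation of `beta`.
#' @param gamma positive dispersion.
#' @param k non-negative ridge parameter.
#' @param beta optional coefficient vector at which to evaluate the bias; if
#'   omitted, the `alpha` stored in `eig` is used.
#' @return List with `bias`, `cov`, `mmse`, `M1`, `M2` and `mse`
#'   (`= M1 + M2`).
#' @export
ridge_moments <- function(eig, gamma, k, beta = NULL) {
  stopifnot(inherits(eig, "eigen_system"))
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  lam <- eig$lambdas
  Tm <- eig$T
  alpha <- if (is.null(beta)) eig$alpha else drop(crossprod(Tm, beta))
  d <- 1 / (lam + k)
  bias <- drop(Tm %*% (-k * d * alpha))
  covm <- Tm %*% (t(Tm) * (gamma * lam * d^2))
  M1 <- gamma * sum(lam * d^2)
  M2 <- k^2 * sum(alpha^2 * d^2)
  list(bias = bias, cov = covm, mmse = covm + tcrossprod(bias),
       M1 = M1, M2 = M2, mse = M1 + M2)
}

#' Derivative of the ridge scalar MSE in k
#'
#' Returns the derivatives of the variance term, the squared-bias term and
#' their sum:
#' \deqn{M_1'(k) = -2\gamma \sum_j \frac{\lambda_j}{(\lambda_j + k)^3}, \quad
#'   M_2'(k) = 2k \sum_j \frac{\alpha_j^2 \lambda_j}{(\lambda_j + k)^3},}
#' \deqn{\frac{d\,\mathrm{MSE}}{dk} = -2 \sum_j
#'   \frac{\lambda_j (\gamma - k \alpha_j^2)}{(\lambda_j + k)^3}.}
#' Because the total derivative is strictly negative for
#' \eqn{0 \le k < \gamma / \max_j \alpha_j^2}, some `k > 0` always improves
#' on the unshrunk estimator — the shrinkage analogue of the classical
#' ridge-existence theorem, which this package checks numerically.
#'
#' @inheritParams ridge_moments
#' @return List with `M1_prime`, `M2_prime` and `total`.
#' @export
mse_derivative <- function(eig, gamma, k) {
  stopifnot(inherits(eig, "eigen_system"))
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  lam <- eig$lambdas
  a2 <- eig$alpha^2
  d3 <- (lam + k)^-3
  list(M1_prime = -2 * gamma * sum(lam * d3),
       M2_prime = 2 * k * sum(a2 * lam * d3),
       total = -2 * sum(lam * (gamma - k * a2) * d3))
}
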