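#' Quasi-log-likelihood of the quasi-Poisson model
#'
#' Evaluates the quasi-Poisson objective
#' \deqn{l(y, \mu; \gamma) = \frac{1}{\gamma} \sum_i (y_i \log \mu_i - \mu_i),}
#' the log-link quasi-likelihood whose score equations define the
#' quasi-likelihood estimator. The dispersion \eqn{\gamma} only rescales the
#' objective, so the maximiser in \eqn{\beta} does not depend on it.
#'
#' @param y count vector.
#' @param mu positive fitted-mean vector, same length as `y`.
#' @param gamma positive dispersion parameter.
#' @return The scalar quasi-log-likelihood.
#' @export
#' @examples
#' quasi_loglik(1, 1, 1)  # -1
quasi_loglik <- function(y, mu, gamma = 1) {
  if (length(y) != length(mu)) stop("lengths of y and mu differ", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be strictly positive", call. = FALSE)
  if (gamma <= 0) stop("gamma must be strictly positive", call. = FALSE)
  sum(y * log(mu) - mu) / gamma
}

#' Pearson estimate of the quasi-Poisson dispersion
#'
#' Estimates the overdispersion factor \eqn{\gamma} in
#' \eqn{\mathrm{Var}(Y) = \gamma \mu} by the Pearson chi-square statistic
#' divided by its residual degrees of freedom,
#' \deqn{\hat\gamma = \frac{1}{n - p - 1} \sum_i \frac{(y_i - \hat\mu_i)^2}
#'   {\hat\mu_i},}
#' the standard moment estimator in quasi-likelihood practice (and the one
#' `stats::glm` with `family = quasipoisson` reports).
#'
#' @param y count vector.
#' @param mu fitted means.
#' @param p number of non-intercept regressors (so the model has `p + 1`
#'   coefficients).
#' @return The non-negative dispersion estimate.
#' @export
estimate_dispersion <- function(y, mu, p) {
  if (length(y) != length(mu)) stop("lengths of y and mu differ", call. = FALSE)
  n <- length(y)
  if (n <= p + 1) {
    stop("no residual degrees of freedom: n = ", n, ", p + 1 = ", p + 1,
         call. = FALSE)
  }
  sum((y - mu)^2 / mu) / (n - p - 1)
}

# One shared lower clamp for fitted means: keeps log(mu), 1/mu and the IWLS
# weights finite when a linear predictor runs off to -Inf.
.MU_FLOOR <- 1e-10

#' Fit a quasi-Poisson regression by IWLS
#'
#' Computes the quasi-likelihood estimator (QLE) of the log-link
#' quasi-Poisson model by iteratively reweighted least squares. At each
#' iteration the coefficients solve
#' \deqn{\beta^{(t+1)} = (X'W^{(t)}X)^{-1} X'W^{(t)} m^{(t)},}
#' with weights \eqn{w_i = \hat\mu_i} and working response
#' \eqn{m_i = \log\hat\mu_i + (y_i - \hat\mu_i)/\hat\mu_i}. The dispersion
#' \eqn{\gamma} cancels from the update, so it is estimated once at
#' convergence via [estimate_dispersion()] and carried as a separate scalar;
#' the weighted cross-product matrix is stored as \eqn{F = X'\hat W X} with
#' \eqn{\hat W = \mathrm{diag}(\hat\mu)}, making the covariance of the QLE
#' exactly \eqn{\hat\gamma F^{-1}}.
#'
#' Starting values come from least squares on \eqn{\log(y + 0.5)};
#' convergence is declared when the largest relative coefficient change
#' falls below `tol`.
#'
#' @param data a [count_dataset()].
#' @param tol convergence tolerance on the maximum relative coefficient
#'   change (default `1e-8`).
#' @param max_iter maximum IWLS iterations (default 100).
#' @return An object of class `qle_fit`: coefficients `beta`, fitted means
#'   `mu`, linear predictors `eta`, weighted cross-product `F`, IWLS weights
#'   `W_diag`, Pearson dispersion `gamma_hat`, iteration count `n_iter`,
#'   logical `converged`, and the tolerance used.
#' @export
#' @examples
#' d <- count_dataset(matrix(rnorm(30), 30, 1), rpois(30, 3))
#' fit <- fit_qle(d)
#' coef(fit)
fit_qle <- function(data, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(data, "count_dataset"))
  X <- data$X
  y <- data$y
  q <- ncol(X)          # p + 1 coefficients

  beta <- qr.solve(X, log(y + 0.5))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- pmax(exp(eta), .MU_FLOOR)
    if (any(!is.finite(mu))) {
      stop("IWLS diverged: non-finite fitted means at iteration ", iter,
         call. = FALSE)
    }
    m <- log(mu) + (y - mu) / mu
    Xw <- X * mu                      # rows scaled by w_i = mu_i
    Fmat <- crossprod(X, Xw)
    ch <- tryCatch(chol(Fmat), error = function(e) NULL)
    if (is.null(ch)) {
      stop("weighted cross-product matrix became singular at iteration ",
           iter, call. = FALSE)
    }
    beta_new <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(Xw, m))))
    delta <- max(abs(beta_new - beta) / pmax(abs(beta), 1e-8))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  eta <- drop(X %*% beta)
  mu <- pmax(exp(eta), .MU_FLOOR)
  Fmat <- crossprod(X, X * mu)
  Fmat <- (Fmat + t(Fmat)) / 2
  gamma_hat <- estimate_dispersion(y, mu, data$p)

  fit <- structure(
    list(beta = stats::setNames(beta, colnames(X)),
         mu = mu, eta = eta, F = Fmat, W_diag = mu,
         gamma_hat = gamma_hat, n_iter = iter, converged = converged,
         tol = tol, data = data),
    class = "qle_fit"
  )
  if (!converged) {
    cond <- structure(
      class = c("qpridge_no_convergence", "error", "condition"),
      list(message = paste0("IWLS did not converge in ", max_iter,
                            " iterations (last max rel. change above tol)"),
           call = sys.call(-1), fit = fit)
    )
    stop(cond)
  }
  fit
}

#' @export
coef.qle_fit <- function(object, ...) object$beta

#' @export
print.qle_fit <- function(x, ...) {
  cat("Quasi-Poisson fit (quasi-likelihood / IWLS)\n")
  cat("Converged in", x$n_iter, "iterations; dispersion gamma_hat =",
      format(x$gamma_hat, digits = 6), "\n")
  print(x$beta)
  invisible(x)
}

#' Covariance and scalar MSE of the quasi-likelihood estimator
#'
#' For a quasi-Poisson fit with weighted cross-product matrix \eqn{F} and
#' dispersion \eqn{\gamma}, the asymptotic covariance of the QLE is
#' \eqn{\gamma F^{-1}} and its scalar mean squared error is the trace,
#' \deqn{\mathrm{MSE} = \gamma \sum_j 1/\lambda_j,}
#' where \eqn{\lambda_j} are the eigenvalues of \eqn{F}. Small eigenvalues —
#' the signature of multicollinearity — blow this quantity up, which is the
#' motivation for ridge shrinkage.
#'
#' @param F symmetric positive-definite matrix \eqn{X'\hat W X}.
#' @param gamma positive dispersion.
#' @return A list with `cov` (matrix \eqn{\gamma F^{-1}}) and `mse`
#'   (scalar trace).
#' @export
qle_cov_mse <- function(F, gamma) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  F <- as.matrix(F)
  if (max(abs(F - t(F))) > 1e-8 * max(1, max(abs(F)))) {
    stop("F must be symmetric", call. = FALSE)
  }
  ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("F is singular or indefinite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  covm <- gamma * chol2inv(chol(F))
  list(cov = covm, mse = gamma * sum(1 / ev))
}
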