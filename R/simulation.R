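#' Generate correlated standard-normal regressors
#'
#' Draws an `n x p` regressor matrix by the shared-component construction
#' \deqn{x_{ij} = (1 - \rho^2)^{1/2} z_{ij} + \rho\, z_{i,p+1},}
#' with all \eqn{z} independent standard normal. Each column then has mean 0
#' and variance 1 and every pair of columns has correlation \eqn{\rho^2} —
#' the standard device for manufacturing a controllable degree of
#' multicollinearity in ridge-regression simulation studies.
#'
#' `literal = TRUE` switches to the adjacent-column variant
#' \eqn{x_{ij} = (1 - \rho)^{1/2} z_{ij} + \rho\, z_{i,j+1}}, which couples
#' only neighbouring columns and does not have unit variance; it is provided
#' for comparison only.
#'
#' @param n number of rows.
#' @param p number of regressors.
#' @param rho correlation control in `[0, 1)`; pairwise column correlation
#'   is `rho^2` under the default scheme.
#' @param literal use the adjacent-column variant (default `FALSE`).
#' @return An `n x p` numeric matrix (no intercept column).
#' @export
gen_design <- function(n, p, rho, literal = FALSE) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  Z <- matrix(stats::rnorm(n * (p + 1L)), n, p + 1L)
  X <- if (literal) {
    sqrt(1 - rho) * Z[, 1:p, drop = FALSE] +
      rho * Z[, 2:(p + 1L), drop = FALSE]
  } else {
    sqrt(1 - rho^2) * Z[, 1:p, drop = FALSE] + rho * Z[, p + 1L]
  }
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' True coefficient vector for simulations
#'
#' Returns the unit-norm coefficient vector used throughout the Monte-Carlo
#' study: all `p + 1` components (intercept included) equal to
#' \eqn{1/\sqrt{p+1}}, so that \eqn{\sum_j \beta_j^2 = 1} exactly. With
#' `scheme = "eigen"` the coefficients are instead the (sign-fixed)
#' eigenvector of the largest eigenvalue of a supplied cross-product matrix
#' — the classical "least-favourable direction" convention.
#'
#' @param p number of non-intercept regressors.
#' @param scheme `"equal"` (default) or `"eigen"`.
#' @param F cross-product matrix, required for `scheme = "eigen"`.
#' @return Numeric vector of length `p + 1` with unit Euclidean norm.
#' @export
gen_beta <- function(p, scheme = c("equal", "eigen"), F = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "equal") {
    rep(1 / sqrt(p + 1), p + 1L)
  } else {
    if (is.null(F)) stop("scheme 'eigen' needs the matrix F", call. = FALSE)
    v <- eigen((F + t(F)) / 2, symmetric = TRUE)$vectors[, 1L]
    if (v[which.max(abs(v))] < 0) v <- -v
    v
  }
}

#' Draw overdispersed quasi-Poisson counts
#'
#' Simulates counts with mean \eqn{\mu_i = \exp(x_i'\beta)} and variance
#' \eqn{\gamma \mu_i}. The quasi-Poisson model fixes only these first two
#' moments, so a concrete sampler must be chosen: for `gamma = 1` the draws
#' are Poisson; for `gamma > 1` they are negative binomial with mean
#' \eqn{\mu_i} and size \eqn{\theta_i = \mu_i / (\gamma - 1)}, which gives
#' \eqn{\mathrm{Var} = \mu_i + \mu_i^2/\theta_i = \gamma\mu_i} exactly.
#' Under-dispersion (`gamma < 1`) is not supported.
#'
#' @param X design matrix including the intercept column.
#' @param beta coefficient vector of length `ncol(X)`.
#' @param gamma dispersion, `>= 1`.
#' @return Integer-valued count vector of length `nrow(X)`.
#' @export
gen_response <- function(X, beta, gamma) {
  if (gamma < 1) stop("gamma must be >= 1 (no under-dispersion)",
                      call. = FALSE)
  mu <- exp(drop(as.matrix(X) %*% as.numeric(beta)))
  n <- length(mu)
  if (gamma == 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (gamma - 1))
  }
}

#' Simulation configuration
#'
#' Collects the factors of one Monte-Carlo cell: sample size `n`, number of
#' regressors `p`, true dispersion `gamma`, multicollinearity level `rho`,
#' number of replications `reps`, RNG `seed` and the estimators to compare
#' (`"QLE"`, rule names, or named list entries that are functions
#' `function(data, qle) -> coefficient vector` for custom estimators).
#'
#' @param n,p,gamma,rho,reps,seed scalars; see above.
#' @param estimators character vector / list of estimators.
#' @param beta_scheme passed to [gen_beta()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, p, gamma, rho, reps = 2000L, seed = 1L,
                       estimators = c("QLE", k_rules()),
                       beta_scheme = "equal") {
  stopifnot(n > p + 1, reps >= 1, gamma >= 1, rho >= 0, rho < 1)
  structure(list(n = as.integer(n), p = as.integer(p), gamma = gamma,
                 rho = rho, reps = as.integer(reps), seed = as.integer(seed),
                 estimators = estimators, beta_scheme = beta_scheme),
            class = "sim_config")
}

#' Run one Monte-Carlo cell
#'
#' For each replication: draw a correlated design ([gen_design()]), counts
#' ([gen_response()]) at the unit-norm true coefficients ([gen_beta()]),
#' fit every requested estimator, and accumulate the squared estimation
#' error \eqn{(\hat\beta - \beta)'(\hat\beta - \beta)}. The reported MSE for
#' an estimator is the average of that quantity over its successful
#' replications,
#' \deqn{\widehat{\mathrm{MSE}}(\hat\beta) = \frac{1}{V} \sum_{v=1}^{V}
#'   (\hat\beta_v - \beta)'(\hat\beta_v - \beta).}
#' Replications where IWLS fails to converge (or a rule cannot be evaluated)
#' are dropped for the affected estimators and counted in `failures`.
#' Results are deterministic given `config$seed` and do not depend on the
#' order in which estimators are listed.
#'
#' @param config a [sim_config()].
#' @return A `sim_result`: list with `config`, named vector `mse`, named
#'   integer vector `failures`, and `beta_true`.
#' @export
run_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  est <- config$estimators
  nm <- if (is.null(names(est))) vapply(est, function(e)
    if (is.character(e)) e else "custom", "") else names(est)
  if (is.null(names(est))) names(est) <- nm
  beta_true <- gen_beta(config$p, scheme = config$beta_scheme)

  sse <- stats::setNames(numeric(length(est)), nm)
  ok <- stats::setNames(integer(length(est)), nm)
  fail <- stats::setNames(integer(length(est)), nm)

  for (v in seq_len(config$reps)) {
    set.seed((config$seed + v * 10007L) %% .Machine$integer.max)
    X <- gen_design(config$n, config$p, config$rho)
    y <- gen_response(cbind(1, X), beta_true, config$gamma)
    data <- tryCatch(count_dataset(X, y), error = function(e) NULL)
    qle <- if (is.null(data)) NULL else
      tryCatch(fit_qle(data), error = function(e) NULL)
    eig <- if (is.null(qle)) NULL else eigen_decompose(qle$F, qle$beta)

    for (j in seq_along(est)) {
      e <- est[[j]]
      bhat <- tryCatch({
        if (is.function(e)) {
          e(data, qle)
        } else if (identical(e, "QLE")) {
          if (is.null(qle)) stop("no fit") else qle$beta
        } else {
          if (is.null(qle)) stop("no fit")
          k <- ridge_k(e, eig$alpha, eig$lambdas, qle$gamma_hat)
          ridge_coefficients(qle$F, qle$beta, k)
        }
      }, error = function(err) NULL)
      if (is.null(bhat) || any(!is.finite(bhat))) {
        fail[j] <- fail[j] + 1L
      } else {
        sse[j] <- sse[j] + sum((bhat - beta_true)^2)
        ok[j] <- ok[j] + 1L
      }
    }
  }

  mse <- ifelse(ok > 0, sse / ok, NA_real_)
  structure(list(config = config, mse = mse, failures = fail,
                 beta_true = beta_true),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo cell: n=%d p=%d gamma=%g rho=%g reps=%d\n",
              cfg$n, cfg$p, cfg$gamma, cfg$rho, cfg$reps))
  print(round(x$mse, 3))
  invisible(x)
}

#' Run a grid of Monte-Carlo cells
#'
#' Maps [run_cell()] over the cross-product of the supplied factor levels
#' and returns (optionally writes) a long table with one row per
#' (cell, estimator). Each cell gets its own seed derived deterministically
#' from `seed` and the cell index, so a rerun with the same master seed
#' reproduces the table exactly and cells can be recomputed independently.
#'
#' @param n,p,gamma,rho vectors of factor levels to cross.
#' @param reps replications per cell.
#' @param seed master seed.
#' @param estimators as in [sim_config()].
#' @param out optional path; when given, the table is written there as CSV.
#' @return A data frame with columns `n`, `p`, `gamma`, `rho`, `reps`,
#'   `estimator`, `mse`, `failures`.
#' @export
run_grid <- function(n, p, gamma, rho, reps = 2000L, seed = 1L,
                     estimators = c("QLE", k_rules()), out = NULL) {
  cells <- expand.grid(n = n, p = p, gamma = gamma, rho = rho,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell_seed <- (as.double(seed) * 69621 + i * 30269) %% 2147483647
    cfg <- sim_config(cells$n[i], cells$p[i], cells$gamma[i], cells$rho[i],
                      reps = reps, seed = as.integer(cell_seed),
                      estimators = estimators)
    res <- run_cell(cfg)
    rows[[i]] <- data.frame(
      n = cfg$n, p = cfg$p, gamma = cfg$gamma, rho = cfg$rho,
      reps = cfg$reps, estimator = names(res$mse),
      mse = unname(res$mse), failures = unname(res$failures)
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
  }
  tab
}
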