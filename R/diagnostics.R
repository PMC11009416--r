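#' Condition index of a design matrix
#'
#' Computes \eqn{\sqrt{\lambda_{max}/\lambda_{min}}} of \eqn{X'X} on the
#' intercept-augmented raw design (no centering or scaling). Values above 30
#' conventionally signal severe multicollinearity. A singular cross-product
#' yields `Inf` with a warning rather than an error, because a degenerate
#' design is precisely what the diagnostic is meant to expose.
#'
#' @param X design matrix including the intercept column (a
#'   [count_dataset()] may be passed instead).
#' @return A scalar `>= 1` (possibly `Inf`).
#' @export
condition_index <- function(X) {
  if (inherits(X, "count_dataset")) X <- X$X
  ev <- eigen(crossprod(as.matrix(X)), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= max(ev) * .Machine$double.eps) {
    warning("cross-product matrix is numerically singular; condition index ",
            "is infinite (rank-deficient design)")
    return(Inf)
  }
  sqrt(max(ev) / min(ev))
}

#' Leverages of the (ridge-) weighted hat matrix
#'
#' Diagonal of \eqn{H_k = W^{1/2} X (X'WX + kI)^{-1} X' W^{1/2}}, the hat
#' matrix of the weighted (quasi-Poisson) fit with optional ridge penalty.
#' At `k = 0` this is the projection onto the weighted column space, so the
#' leverages sum to `p + 1`; as `k` grows every leverage shrinks to zero.
#'
#' @param X design matrix including the intercept column.
#' @param W_diag positive IWLS weight vector (fitted means for the
#'   quasi-Poisson model).
#' @param k non-negative ridge parameter.
#' @return Vector of leverages `h_ii`.
#' @export
hat_diagonals <- function(X, W_diag, k = 0) {
  X <- as.matrix(X)
  if (any(W_diag <= 0)) stop("weights must be positive", call. = FALSE)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  Xs <- X * sqrt(W_diag)
  A <- crossprod(Xs) + diag(k, ncol(X))
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
    stop("X'WX + kI is singular (rank-deficient design at k = 0)",
         call. = FALSE))
  rowSums((Xs %*% Ainv) * Xs)
}

#' PRESS criterion from Pearson residuals
#'
#' Leverage-inflated prediction criterion for a quasi-Poisson (ridge) fit:
#' \deqn{\mathrm{PRESS}(k) = \frac{1}{n} \sum_i
#'   \frac{\chi_i^2}{(1 - h_{ii})^2}, \qquad
#'   \chi_i = \frac{y_i - \hat\mu_i}{\sqrt{\hat\gamma \hat\mu_i}},}
#' where \eqn{\hat\mu_i} are the fitted means of the supplied fit (ridge
#' means for a `ridge_fit`) and \eqn{h_{ii}} the leverages of
#' [hat_diagonals()] at the fit's `k`. The dispersion \eqn{\hat\gamma} is
#' always the Pearson estimate from the underlying quasi-likelihood fit.
#'
#' @param data the [count_dataset()] the fit was computed on.
#' @param fit a `qle_fit` or `ridge_fit`.
#' @return A non-negative scalar.
#' @export
press <- function(data, fit) {
  stopifnot(inherits(data, "count_dataset"))
  if (inherits(fit, "ridge_fit")) {
    k <- fit$k
    mu <- pmax(exp(drop(data$X %*% fit$beta_k)), .MU_FLOOR)
    gamma <- fit$qle$gamma_hat
    w <- fit$qle$W_diag
  } else if (inherits(fit, "qle_fit")) {
    k <- 0
    mu <- fit$mu
    gamma <- fit$gamma_hat
    w <- fit$W_diag
  } else {
    stop("fit must be a qle_fit or ridge_fit", call. = FALSE)
  }
  h <- hat_diagonals(data$X, w, k)
  if (any(h >= 1)) {
    stop("a leverage h_ii >= 1 (observation fitted exactly); PRESS undefined",
         call. = FALSE)
  }
  chi2 <- (data$y - mu)^2 / (gamma * mu)
  mean(chi2 / (1 - h)^2)
}

#' K-fold cross-validation for quasi-Poisson (ridge) fits
#'
#' Shuffles the rows into `folds` folds (deterministically given `seed`),
#' fits the chosen estimator on each training set, predicts the held-out
#' means, and returns the mean squared prediction error on the response
#' scale, \eqn{\frac{1}{n}\sum_i (y_i - \hat\mu_{-i})^2}. Folds whose fit
#' fails to converge are skipped with a warning; if every fold fails, an
#' error is raised.
#'
#' @param data a [count_dataset()].
#' @param rule ridge rule name, or `NULL` with `k` for a fixed parameter;
#'   `rule = NULL, k = 0` cross-validates the plain QLE.
#' @param k fixed ridge parameter (see `rule`).
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @return Mean squared prediction error over all scored observations.
#' @export
kfold_cv <- function(data, rule = NULL, k = NULL, folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "count_dataset"), folds >= 2)
  n <- data$n
  old <- .Random.seed_guard(seed)
  on.exit(old())
  idx <- sample.int(n)
  fold_id <- rep(seq_len(folds), length.out = n)[order(idx)]

  Xraw <- data$X[, -1L, drop = FALSE]
  se <- numeric(0)
  failed <- 0L
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (sum(!test) <= data$p + 1) {
      stop("training folds too small: need n_train > p + 1", call. = FALSE)
    }
    fit <- tryCatch({
      train <- count_dataset(Xraw[!test, , drop = FALSE], data$y[!test])
      if (is.null(rule) && (is.null(k) || k == 0)) {
        fit_qle(train)
      } else {
        fit_qprre(train, rule = rule, k = k)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      warning("fold ", f, " failed to converge; skipped")
      next
    }
    beta <- if (inherits(fit, "ridge_fit")) fit$beta_k else fit$beta
    mu_hat <- exp(drop(cbind(1, Xraw[test, , drop = FALSE]) %*% beta))
    se <- c(se, (data$y[test] - mu_hat)^2)
  }
  if (failed == folds) stop("all CV folds failed to converge", call. = FALSE)
  mean(se)
}

# Run code under a fixed seed and restore the caller's RNG state after.
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has) assign(".Random.seed", saved, envir = globalenv())
  }
}

#' Full diagnostics report for one dataset and estimator
#'
#' Convenience wrapper assembling the multicollinearity and predictive
#' diagnostics in one list: condition index of the design, leverages, PRESS
#' and k-fold CV for the requested estimator.
#'
#' @inheritParams kfold_cv
#' @return A list with `condition_index`, `hat_diag`, `press`, `cv`, and the
#'   fitted object under `fit`.
#' @export
diagnose <- function(data, rule = NULL, k = NULL, folds = 5L, seed = 1L) {
  fit <- if (is.null(rule) && (is.null(k) || k == 0))
    fit_qle(data) else fit_qprre(data, rule = rule, k = k)
  kk <- if (inherits(fit, "ridge_fit")) fit$k else 0
  w <- if (inherits(fit, "ridge_fit")) fit$qle$W_diag else fit$W_diag
  list(condition_index = condition_index(data),
       hat_diag = hat_diagonals(data$X, w, kk),
       press = press(data, fit),
       cv = kfold_cv(data, rule = rule, k = k, folds = folds, seed = seed),
       fit = fit)
}
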