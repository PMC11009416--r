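#' Construct a count-data regression dataset
#'
#' Bundles a design matrix and a non-negative integer count response into a
#' validated container used by every fitting routine in the package. An
#' intercept column of ones is prepended to `X`, so with `p` supplied
#' regressors the stored design has `p + 1` columns.
#'
#' @param X numeric matrix (or data frame) of regressors, `n` rows and `p`
#'   columns, without an intercept column.
#' @param y non-negative integer response vector of length `n`.
#' @param names optional character vector of regressor labels; defaults to
#'   the column names of `X` or `x1..xp`.
#'
#' @return An object of class `count_dataset`: a list with elements
#'   `X` (the `n x (p+1)` intercept-augmented design), `y`, `n`, `p`
#'   (number of non-intercept regressors) and `names`.
#'
#' @details `n > p + 1` is required so that the dispersion parameter is
#'   estimable. Exact rank deficiency of the augmented design is an error;
#'   near-deficiency (severe multicollinearity) is deliberately accepted —
#'   quantifying it is the job of [condition_index()] and the ridge
#'   estimator itself.
#'
#' @seealso [fit_qle()], [fit_qprre()], [load_dataset()]
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' y <- rpois(20, exp(0.5 + X[, 1]))
#' d <- count_dataset(X, y)
#' d$p
count_dataset <- function(X, y, names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) {
    stop("regressor matrix contains non-finite values", call. = FALSE)
  }
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) {
    stop("length of 'y' (", length(y), ") does not match nrow(X) (", n, ")",
         call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    bad <- which(!is.finite(y) | y < 0 | y != round(y))[1L]
    stop("response must be non-negative integers; offending value ", y[bad],
         " at row ", bad, call. = FALSE)
  }
  if (n <= p + 1) {
    stop("need n > p + 1 (got n = ", n, ", p = ", p, ")", call. = FALSE)
  }
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- sprintf("x%d", seq_len(p))
  }
  Xa <- cbind(rep(1, n), X)
  colnames(Xa) <- c("(Intercept)", names)
  if (qr(Xa)$rank < p + 1) {
    stop("design matrix (with intercept) is rank deficient", call. = FALSE)
  }
  structure(
    list(X = Xa, y = y, n = n, p = p, names = names),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("Count dataset: n =", x$n, ", p =", x$p, "regressors (+ intercept)\n")
  cat("Response: mean", format(mean(x$y), digits = 4),
      ", variance", format(stats::var(x$y), digits = 4), "\n")
  invisible(x)
}

#' Read a count dataset from CSV
#'
#' Reads a comma-separated file with a header row, takes the named column as
#' the count response and every remaining column as a regressor, and returns
#' a validated [count_dataset()] (intercept added automatically).
#'
#' @param path path to a CSV file (UTF-8, `.` decimal separator).
#' @param response name of the response column.
#' @return A `count_dataset`.
#' @export
load_dataset <- function(path, response) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")", call. = FALSE)
  }
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      stop("column '", nm, "' is not numeric", call. = FALSE)
    }
  }
  y <- df[[response]]
  if (any(y != round(y) | y < 0, na.rm = TRUE)) {
    bad <- which(y != round(y) | y < 0)[1L]
    stop("response column '", response, "' has a non-count value ", y[bad],
         " at row ", bad, call. = FALSE)
  }
  X <- as.matrix(df[setdiff(names(df), response)])
  count_dataset(X, y)
}
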