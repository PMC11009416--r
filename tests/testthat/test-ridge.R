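test_that("eigen decomposition is a faithful, deterministic canonical form", {
  # diagonal F: eigenvalues are the sorted diagonal
  eig <- eigen_decompose(diag(c(2, 7, 5)), c(1, 1, 1))
  expect_equal(eig$lambdas, c(7, 5, 2))
  expect_true(all(abs(eig$T) %in% c(0, 1)))
  for (s in 1:10) {
    sys <- make_eigen_system(5, seed = s)
    eig <- sys$eig
    expect_lt(max(abs(eig$T %*% diag(eig$lambdas) %*% t(eig$T) - sys$F)),
              1e-10 * max(abs(sys$F)))
    expect_lt(max(abs(crossprod(eig$T) - diag(5))), 1e-10)
    expect_equal(sum(eig$alpha^2), sum(sys$beta^2), tolerance = 1e-10)
    # sign convention: largest-magnitude entry of each column positive
    for (j in 1:5) expect_gt(eig$T[which.max(abs(eig$T[, j])), j], 0)
  }
  expect_error(eigen_decompose(matrix(c(1, 2, 0, 1), 2), c(1, 1)),
               "symmetric")
})

test_that("ridge coefficients shrink correctly and reduce to QLE at k = 0", {
  F <- diag(c(4, 1))
  b <- c(1, 1)
  expect_equal(ridge_coefficients(F, b, 0), b)
  expect_equal(ridge_coefficients(F, b, 1), c(0.8, 0.5))
  expect_lt(sqrt(sum(ridge_coefficients(F, b, 1e12)^2)), 1e-9)
  expect_error(ridge_coefficients(F, b, -0.1), "non-negative")
  # canonical route agrees with the matrix route
  for (s in 1:10) {
    sys <- make_eigen_system(4, seed = 30 + s)
    k <- runif(1, 0, 5)
    via_matrix <- ridge_coefficients(sys$F, sys$beta, k)
    eig <- sys$eig
    via_canon <- drop(eig$T %*% (eig$lambdas / (eig$lambdas + k) * eig$alpha))
    expect_equal(via_matrix, via_canon, tolerance = 1e-10)
  }
})

test_that("ridge moments match their canonical closed forms", {
  # hand example: lambda = (4, 1), alpha = (1, 1), gamma = 2, k = 1
  eig <- eigen_decompose(diag(c(4, 1)), c(1, 1))
  mom <- ridge_moments(eig, gamma = 2, k = 1)
  expect_equal(mom$M1, 2 * (4 / 25 + 1 / 4), tolerance = 1e-12)  # 0.82
  expect_equal(mom$M2, 1 / 25 + 1 / 4, tolerance = 1e-12)        # 0.29
  expect_equal(mom$mse, 1.11, tolerance = 1e-12)
  # k = 0 reduces to the unshrunk theory
  mom0 <- ridge_moments(eig, gamma = 2, k = 0)
  expect_equal(mom0$bias, c(0, 0))
  expect_equal(mom0$mse, 2 * (1 / 4 + 1))
  # trace identity and PSD covariance on random systems
  for (s in 1:10) {
    sys <- make_eigen_system(5, seed = 60 + s)
    k <- runif(1, 0, 10)
    mom <- ridge_moments(sys$eig, sys$gamma, k)
    expect_equal(mom$mse, sum(diag(mom$mmse)), tolerance = 1e-10)
    expect_equal(mom$mmse, mom$cov + tcrossprod(mom$bias), tolerance = 1e-12)
    expect_gte(min(eigen(mom$cov, symmetric = TRUE)$values), -1e-12)
  }
})

test_that("moments are invariant to the eigenvector sign convention", {
  sys <- make_eigen_system(4, seed = 5)
  eig <- sys$eig
  flipped <- eig
  flipped$T[, 2] <- -flipped$T[, 2]
  flipped$alpha <- drop(crossprod(flipped$T, sys$beta))
  m1 <- ridge_moments(eig, 2, 0.7)
  m2 <- ridge_moments(flipped, 2, 0.7)
  expect_equal(m1$mse, m2$mse, tolerance = 1e-12)
  expect_equal(m1$bias, m2$bias, tolerance = 1e-12)
  expect_equal(m1$cov, m2$cov, tolerance = 1e-12)
})

test_that("MSE derivative matches a finite-difference oracle", {
  eig <- eigen_decompose(diag(c(4, 1)), c(1, 1))
  h <- 1e-5
  for (k in c(0.5, 2, 7)) {
    d <- mse_derivative(eig, gamma = 2, k = k)
    fd <- (ridge_moments(eig, 2, k + h)$mse -
             ridge_moments(eig, 2, k - h)$mse) / (2 * h)
    expect_equal(d$total, fd, tolerance = 1e-6)
    expect_equal(d$total, d$M1_prime + d$M2_prime, tolerance = 1e-12)
  }
  d0 <- mse_derivative(eig, gamma = 2, k = 0)
  expect_equal(d0$M2_prime, 0)
  expect_equal(d0$M1_prime, -2 * 2 * (4 / 64 + 1))
})

test_that("variance decreases, bias increases, and some k > 0 beats k = 0", {
  kgrid_rel <- c(1e-4, 1e-3, 0.01, 0.1, 0.5, 1, 2, 5, 10)
  for (s in 1:100) {
    sys <- make_eigen_system(sample(3:6, 1), seed = 200 + s)
    eig <- sys$eig
    kk <- kgrid_rel * max(eig$lambdas)
    M1 <- vapply(kk, function(k) ridge_moments(eig, sys$gamma, k)$M1, 0)
    M2 <- vapply(kk, function(k) ridge_moments(eig, sys$gamma, k)$M2, 0)
    mse <- M1 + M2
    expect_true(all(diff(M1) < 0))
    expect_true(all(diff(M2) > 0))
    mse0 <- sys$gamma * sum(1 / eig$lambdas)
    expect_lt(min(mse), mse0)
    # derivative is negative below gamma / max alpha_j^2
    ksafe <- 0.9 * sys$gamma / max(eig$alpha^2)
    expect_lt(mse_derivative(eig, sys$gamma, ksafe)$total, 0)
  }
})

test_that("scalar MSE tends to beta'beta under full shrinkage", {
  sys <- make_eigen_system(4, seed = 77)
  mom <- ridge_moments(sys$eig, sys$gamma, 1e12)
  expect_equal(mom$mse, sum(sys$beta^2), tolerance = 1e-6)
  expect_lt(mom$M1, 1e-9)
})
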