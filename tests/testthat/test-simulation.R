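test_that("design generator has the claimed second moments", {
  set.seed(1)
  # rho = 0: exact reproduction of the first p columns of Z
  set.seed(99); X0 <- gen_design(20, 3, 0)
  set.seed(99); Z <- matrix(rnorm(20 * 4), 20, 4)
  expect_equal(unname(X0), Z[, 1:3])
  # large-n moment checks
  set.seed(2)
  X <- gen_design(50000, 4, 0.9)
  cors <- cor(X)[upper.tri(diag(4))]
  expect_true(all(abs(cors - 0.81) < 0.01))
  expect_true(all(abs(apply(X, 2, var) - 1) < 0.02))
  expect_true(all(abs(colMeans(X)) < 0.02))
  expect_error(gen_design(10, 2, 1), "rho")
})

test_that("literal adjacent-column variant couples only neighbours", {
  set.seed(5)
  X <- gen_design(50000, 3, 0.9, literal = TRUE)
  C <- cor(X)
  # adjacent columns share one z: corr = rho sqrt(1-rho) / (1-rho+rho^2)
  rho <- 0.9
  expect_equal(C[1, 2], rho * sqrt(1 - rho) / (1 - rho + rho^2),
               tolerance = 0.05)
  expect_lt(abs(C[1, 3]), 0.02)  # non-adjacent are independent
})

test_that("true coefficients have unit norm in both schemes", {
  expect_equal(gen_beta(3), rep(0.5, 4))
  expect_equal(gen_beta(1), rep(1 / sqrt(2), 2))
  for (p in c(2, 5, 12)) {
    expect_equal(sum(gen_beta(p)^2), 1, tolerance = 1e-12)
  }
  F <- crossprod(matrix(rnorm(25), 5))
  be <- gen_beta(4, scheme = "eigen", F = F)
  expect_equal(sum(be^2), 1, tolerance = 1e-10)
  expect_error(gen_beta(3, scheme = "eigen"), "needs the matrix")
})

test_that("response generator matches the first two quasi-Poisson moments", {
  X <- matrix(0, 1e5, 1)          # mu = exp(log 5) = 5 for every row
  beta <- c(log(5), 0)
  set.seed(3)
  y1 <- gen_response(cbind(1, X), beta, gamma = 1)
  expect_true(all(y1 >= 0 & y1 == round(y1)))
  expect_gt(var(y1) / mean(y1), 0.97)
  expect_lt(var(y1) / mean(y1), 1.03)
  set.seed(4)
  y4 <- gen_response(cbind(1, X), beta, gamma = 4)
  expect_gt(var(y4) / mean(y4), 3.8)
  expect_lt(var(y4) / mean(y4), 4.2)
  expect_error(gen_response(cbind(1, X), beta, gamma = 0.5), "gamma")
})

test_that("run_cell implements the replication-average MSE definition", {
  p <- 3
  beta_true <- gen_beta(p)
  u <- c(1, 0, 0, 0)
  cfg <- sim_config(n = 30, p = p, gamma = 2, rho = 0.5, reps = 25, seed = 7,
                    estimators = list(
                      oracle = function(data, qle) beta_true,
                      offset = function(data, qle) beta_true + u))
  res <- run_cell(cfg)
  expect_equal(unname(res$mse["oracle"]), 0)
  expect_equal(unname(res$mse["offset"]), sum(u^2), tolerance = 1e-12)
  expect_equal(unname(res$failures), c(0L, 0L))
})

test_that("run_cell is deterministic and drops failing replications", {
  cfg <- sim_config(n = 30, p = 3, gamma = 2, rho = 0.9, reps = 20, seed = 42,
                    estimators = c("QLE", "k1", "k7"))
  r1 <- run_cell(cfg)
  r2 <- run_cell(cfg)
  expect_identical(r1$mse, r2$mse)
  # an estimator that always fails is reported as missing, not zero
  cfg2 <- sim_config(n = 30, p = 3, gamma = 2, rho = 0.5, reps = 5, seed = 1,
                     estimators = list(bad = function(data, qle) stop("no")))
  res2 <- run_cell(cfg2)
  expect_true(is.na(res2$mse["bad"]))
  expect_equal(unname(res2$failures["bad"]), 5L)
})

test_that("run_grid crosses factors, writes CSV, and reruns identically", {
  est <- c("QLE", "k7")
  out1 <- file.path(tempdir(), "grid1.csv")
  out2 <- file.path(tempdir(), "grid2.csv")
  tab <- run_grid(n = c(30, 40), p = 3, gamma = 2, rho = c(0.5, 0.9),
                  reps = 5, seed = 9, estimators = est, out = out1)
  expect_equal(nrow(tab), 4 * length(est))
  expect_named(tab, c("n", "p", "gamma", "rho", "reps", "estimator",
                      "mse", "failures"))
  run_grid(n = c(30, 40), p = 3, gamma = 2, rho = c(0.5, 0.9),
           reps = 5, seed = 9, estimators = est, out = out2)
  expect_identical(readLines(out1), readLines(out2))
  # a single-cell grid matches run_cell at the derived seed
  tab1 <- run_grid(n = 30, p = 3, gamma = 2, rho = 0.5, reps = 5, seed = 9,
                   estimators = est)
  cell_seed <- as.integer((9 * 69621 + 1 * 30269) %% 2147483647)
  res <- run_cell(sim_config(30, 3, 2, 0.5, reps = 5, seed = cell_seed,
                             estimators = est))
  expect_equal(tab1$mse, unname(res$mse), tolerance = 1e-12)
})

test_that("QLE error shrinks with sample size (parameter recovery)", {
  cfg <- sim_config(n = 2000, p = 3, gamma = 2, rho = 0.8, reps = 10,
                    seed = 5, estimators = "QLE")
  res <- run_cell(cfg)
  expect_lt(unname(res$mse["QLE"]), 0.5)
})
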