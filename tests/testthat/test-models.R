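test_that("noiseless linear data is recovered exactly", {
  set.seed(1)
  X <- matrix(rnorm(300 * 4), 300, 4,
              dimnames = list(NULL, paste0("F", 1:4)))
  beta <- c(2, -1, 0.5, 3)
  y <- 1.5 + drop(X %*% beta)
  m <- fit_log_linear(X, y, seed = 1)
  expect_equal(unname(m$coefficients), c(1.5, beta), tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-8)
  expect_equal(m$cv_r2, 1, tolerance = 1e-8)
})

test_that("cv_r2 tracks the population R2 when noise matches signal", {
  set.seed(2)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("F", 1:3)))
  signal <- drop(X %*% c(1, 1, 1))
  y <- signal + rnorm(n, 0, sd(signal))   # population R2 = 0.5
  m <- fit_log_linear(X, y, seed = 3)
  expect_gt(m$cv_r2, 0.4)
  expect_lt(m$cv_r2, 0.6)
})

test_that("rank deficiency raises a collinearity error naming the column", {
  set.seed(3)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  X <- cbind(X, Cdup = X[, "C"])
  y <- rnorm(100)
  expect_error(fit_log_linear(X, y), "collinearity.*Cdup")
})

test_that("cross-validation partitions every gene exactly once", {
  f <- make_folds(12, 10, seed = 4)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_identical(f, make_folds(12, 10, seed = 4))

  set.seed(5)
  X <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(NULL, c("A", "B")))
  y <- drop(X %*% c(1, 1)) + rnorm(12, 0, 0.1)
  m <- fit_svr(X, y, folds = 10, seed = 4)
  expect_length(m$predictions, 12)
  expect_equal(nrow(m$per_fold), 10)
  expect_true(all(is.finite(m$predictions)))
})

test_that("SVR is deterministic under a fixed seed", {
  set.seed(6)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, paste0("F", 1:3)))
  y <- drop(X %*% c(1, -1, 2)) + rnorm(200, 0, 0.5)
  m1 <- fit_svr(X, y, seed = 9)
  m2 <- fit_svr(X, y, seed = 9)
  expect_identical(m1$predictions, m2$predictions)
  expect_identical(m1$pcc, m2$pcc)
})

test_that("SVR beats the linear model on a monotone nonlinear response", {
  set.seed(7)
  x <- matrix(rnorm(800), 800, 1, dimnames = list(NULL, "F1"))
  y <- exp(2 * x[, 1])
  svr <- fit_svr(x, y, seed = 2)
  ll <- fit_log_linear(x, y, seed = 2)
  expect_gt(svr$pcc, ll$pcc)
})

test_that("linear truth gives SVR no advantage", {
  set.seed(8)
  n <- 600
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("F", 1:4)))
  y <- drop(X %*% rep(1, 4)) + rnorm(n)
  ll <- fit_log_linear(X, y, seed = 5)
  svr <- fit_svr(X, y, seed = 5)
  expect_gte(ll$cv_r2, svr$cv_r2 - 0.05)
})

test_that("a pure-noise feature cannot buy accuracy", {
  set.seed(9)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("F", 1:3)))
  y <- drop(X %*% rep(1, 3)) + rnorm(n)
  base <- fit_log_linear(X, y, seed = 6)$cv_r2
  Xn <- cbind(X, NOISE = rnorm(n))
  expect_lt(fit_log_linear(Xn, y, seed = 6)$cv_r2, base + 0.02)
})

test_that("evaluate_predictions follows the squared-correlation definition", {
  y <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  expect_equal(evaluate_predictions(y, y), list(pcc = 1, r2 = 1))
  ev <- evaluate_predictions(-y, y)
  expect_equal(ev$pcc, -1)
  expect_equal(ev$r2, 1)
  set.seed(10)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(evaluate_predictions(a, b)$pcc), 0.05)
  expect_error(evaluate_predictions(rep(1, 5), y), "constant")
  expect_error(evaluate_predictions(y[1:4], y), "length")
})

test_that("stability_rmse arithmetic", {
  expect_equal(stability_rmse(data.frame(train_r2 = c(0.7, 0.7),
                                         test_r2 = c(0.7, 0.7))), 0)
  expect_equal(stability_rmse(data.frame(train_r2 = c(0.8, 0.8),
                                         test_r2 = c(0.6, 0.6))), 0.2)
  expect_equal(stability_rmse(data.frame(train_r2 = 0.9, test_r2 = 0.75)),
               0.15)
})

test_that("degenerate model inputs are rejected", {
  set.seed(11)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(fit_svr(X, rep(1, 30)), "constant")
  expect_error(fit_log_linear(X, c(rnorm(29), NA)), "missing")
  expect_error(fit_log_linear(X[1:3, ], rnorm(3)), "n_genes")
})
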