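test_that("fit_pls recovers a noiseless two-factor relation", {
  with_seed(11, {
    T2 <- matrix(rnorm(40), 20, 2)
    P2 <- matrix(rnorm(12), 6, 2)
    X <- T2 %*% t(P2)
    y <- drop(T2 %*% c(1.5, -2))
  })
  fit <- fit_pls(X, y, 2)
  expect_lt(max(abs(predict(fit, X) - y)), 1e-8)
})

test_that("PLS at maximal factor count equals least squares on tall X", {
  for (seed in 1:5) {
    with_seed(seed, {
      X <- matrix(rnorm(60), 15, 4)
      y <- rnorm(15)
    })
    fit <- fit_pls(X, y, 4)
    ols <- drop(cbind(1, X) %*%
                  solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y)))
    expect_lt(max(abs(predict(fit, X) - ols)), 1e-6)
  }
})

test_that("single-column PLS is simple linear regression", {
  with_seed(3, {
    x <- rnorm(12)
    y <- 2 + 3 * x + rnorm(12)
  })
  fit <- fit_pls(matrix(x), y, 1)
  b <- cov(x, y) / var(x)  # closed-form simple-regression slope
  expect_equal(fit$coefficients, b, tolerance = 1e-10)
  expect_equal(predict(fit, matrix(x)), mean(y) + b * (x - mean(x)),
               tolerance = 1e-10)
})

test_that("fit_pls validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rnorm(10), 3), "n_factors")
  expect_error(fit_pls(X, rep(1, 10), 1), "zero variance")
})

test_that("prediction is the centred affine map", {
  with_seed(4, {
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
  })
  fit <- fit_pls(X, y, 2)
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), fit$y_mean,
               tolerance = 1e-12)
  p2 <- predict(fit, X[c(1, 1), ])
  expect_equal(p2[1], p2[2])
  expect_error(predict(fit, X[, 1:2]), "columns")
})

test_that("loocv_predict leaves each sample out", {
  # noiseless linear relation: interpolating folds give zero SECV
  with_seed(5, {
    X <- matrix(rnorm(36), 12, 3)
    y <- drop(X %*% c(1, -1, 2)) + 4
  })
  rec <- loocv_predict(X, y, 3)
  expect_lt(secv(rec), 1e-8)
  expect_equal(rec$measured, y)

  # n = 3, single column, F = 1: three explicit two-point regressions
  x <- c(0, 1, 3); y3 <- c(1, 2, 7)
  rec3 <- loocv_predict(matrix(x), y3, 1)
  byhand <- vapply(1:3, function(j) {
    b <- cov(x[-j], y3[-j]) / var(x[-j])
    mean(y3[-j]) + b * (x[j] - mean(x[-j]))
  }, numeric(1))
  expect_equal(rec3$predicted, byhand, tolerance = 1e-10)

  # order invariance: permuting samples permutes predictions
  with_seed(6, {
    X <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
    perm <- sample(10)
  })
  r1 <- loocv_predict(X, y, 2)
  r2 <- loocv_predict(X[perm, ], y[perm], 2)
  expect_equal(r2$predicted, r1$predicted[perm], tolerance = 1e-8)

  expect_error(loocv_predict(X, y, 9), "n_factors")
})

test_that("secv and r_pcv implement the evaluation statistics", {
  expect_equal(secv(c(1, 2), c(1, 2)), 0)
  expect_equal(secv(c(0, 0), c(1, -1)), 1)
  expect_equal(secv(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)), sqrt(0.025))
  expect_error(secv(prediction_record(1:3, 1:2)), "equal length")

  m <- c(1, 3, 5, 6)
  expect_equal(r_pcv(m, 2 * m + 1), 1)
  expect_equal(r_pcv(m, -m), -1)
  expect_error(r_pcv(m, rep(2, 4)), "zero variance")
  with_seed(7, {
    for (i in 1:20) {
      r <- r_pcv(rnorm(10), rnorm(10))
      expect_gte(r, -1); expect_lte(r, 1)
    }
  })
})

test_that("select_factors minimises SECV with parsimony tie-breaking", {
  with_seed(8, {
    T2 <- matrix(rnorm(60), 30, 2)
    X <- T2 %*% t(matrix(rnorm(16), 8, 2))
    y <- drop(T2 %*% c(2, -1))
  })
  sel <- select_factors(X, y, 1:5)
  expect_equal(sel$n_factors, 2)  # SECV ~0 from 2 on; ties break downward
  expect_lt(sel$secv, 1e-6)

  # grid order must not matter
  sel2 <- select_factors(X, y, c(4, 2, 5, 1, 3))
  expect_equal(sel2$n_factors, sel$n_factors)

  expect_equal(select_factors(X, y, 3)$n_factors, 3)
  expect_error(select_factors(X, y, 40:50), "no feasible")
})

test_that("LOOCV PLS at maximal factors matches leave-one-out OLS", {
  for (seed in 1:5) {
    with_seed(seed + 100, {
      X <- matrix(rnorm(48), 16, 3)
      y <- rnorm(16)
    })
    rec <- loocv_predict(X, y, 3)
    expect_lt(max(abs(rec$predicted - loo_ols_predict(X, y))), 1e-6)
  }
})
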