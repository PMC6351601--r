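# Ridge-regularized linear decoder against closed-form oracles.

test_that("noiseless full-rank data recovers the true weights at lambda 0", {
  set.seed(1)
  X <- matrix(rnorm(200 * 12), 200)
  W_true <- matrix(rnorm(12 * 5), 12)
  Y <- X %*% W_true
  d <- fit_linear(X, Y, 0)
  expect_lt(max(abs(d$weights - W_true)) / max(abs(W_true)), 1e-6)
  expect_lt(max(abs(d$bias)), 1e-8)
})

test_that("huge penalties shrink weights to zero and predict column means", {
  set.seed(2)
  X <- matrix(rnorm(100 * 6), 100)
  Y <- matrix(rnorm(100 * 3), 100)
  d <- fit_linear(X, Y, 1e12)
  expect_lt(max(abs(d$weights)), 1e-6)
  P <- predict_linear(d, X)
  expect_lt(max(abs(sweep(P, 2, colMeans(Y)))), 1e-4)
})

test_that("ridge solution matches an independent normal-equations oracle", {
  set.seed(3)
  X <- matrix(rnorm(80 * 10), 80)
  Y <- matrix(rnorm(80 * 4), 80)
  lambda <- 1
  d <- fit_linear(X, Y, lambda)
  # independent oracle: explicit normal equations on centered unit-variance
  # features and z-scored targets, undone on the original scales
  xm <- colMeans(X)
  xs <- apply(X, 2, sd)
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- colMeans(Y)
  ys <- apply(Y, 2, sd)
  Yz <- sweep(sweep(Y, 2, ym), 2, ys, "/")
  A <- t(Xc) %*% Xc + lambda * diag(ncol(X))
  Wz_oracle <- solve(A) %*% (t(Xc) %*% Yz)
  W_oracle <- sweep(Wz_oracle / xs, 2, ys, "*")
  expect_lt(max(abs(d$weights - W_oracle)), 1e-8)
  b_oracle <- ym - as.numeric(xm %*% W_oracle)
  expect_lt(max(abs(d$bias - b_oracle)), 1e-8)
})

test_that("training MSE is non-increasing as the penalty decreases", {
  set.seed(4)
  X <- matrix(rnorm(150 * 8), 150)
  Y <- X %*% matrix(rnorm(8 * 3), 8) + matrix(rnorm(150 * 3), 150) * 0.3
  mses <- vapply(c(100, 10, 1, 0.1, 0), function(l) {
    d <- fit_linear(X, Y, l)
    mean((predict_linear(d, X) - Y)^2)
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-10))
})

test_that("degenerate designs and feature mismatches are rejected", {
  Y <- matrix(rnorm(20), 10)
  expect_error(fit_linear(matrix(0, 10, 3), Y, 0), "degenerate|singular")
  d <- fit_linear(matrix(rnorm(40), 10), Y, 1)
  expect_error(predict_linear(d, matrix(rnorm(30), 10)), "mismatch")
})

test_that("prediction reproduces fit-time training predictions", {
  set.seed(5)
  X <- matrix(rnorm(60 * 7), 60)
  Y <- matrix(rnorm(60 * 2), 60)
  d <- fit_linear(X, Y, 0.5)
  # refit oracle: identical data and penalty give identical predictions
  d2 <- fit_linear(X, Y, 0.5)
  expect_identical(predict_linear(d, X), predict_linear(d2, X))
  # zero input predicts the bias row
  expect_equal(predict_linear(d, matrix(0, 3, 7)),
               matrix(d$bias, 3, 2, byrow = TRUE), tolerance = 1e-12)
})
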