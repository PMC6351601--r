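# Deep decoder: combined loss, architecture construction, gradients,
# training behavior and reproducibility.

test_that("combined loss at the anchors: perfect and inverted predictions", {
  set.seed(1)
  y <- matrix(rnorm(6 * 10), 6)
  expect_equal(combined_loss(y, y), -1)
  expect_equal(combined_loss(y, -y), mean(rowMeans((2 * y)^2)) + 1)
  # zero-variance samples contribute correlation 0 (loss reduces to MSE)
  yc <- matrix(1, 2, 10)
  yh <- matrix(rnorm(20), 2)
  expect_equal(combined_loss(yc, yh), mean(rowMeans((yc - yh)^2)))
})

test_that("combined loss matches an independently coded formula oracle", {
  set.seed(2)
  y <- matrix(rnorm(8 * 16), 8)
  y_hat <- matrix(rnorm(8 * 16), 8)
  oracle <- mean(vapply(1:8, function(i) {
    mean((y[i, ] - y_hat[i, ])^2) - cor(y[i, ], y_hat[i, ])
  }, numeric(1)))
  expect_lt(abs(combined_loss(y, y_hat) - oracle), 1e-10)
})

test_that("analytic gradients agree with finite differences everywhere", {
  set.seed(3)
  y <- matrix(rnorm(5 * 8), 5)
  y_hat <- matrix(rnorm(5 * 8), 5)
  g <- neurovoc:::combined_loss_grad(y, y_hat)
  for (idx in list(c(1, 1), c(3, 5), c(5, 8))) {
    yp <- y_hat; yp[idx[1], idx[2]] <- yp[idx[1], idx[2]] + 1e-6
    num <- (combined_loss(y, yp) - combined_loss(y, y_hat)) / 1e-6
    expect_lt(abs(num - g[idx[1], idx[2]]), 1e-5)
  }
  # whole-model gradient check (FCN+LCN, tanh output, dropout off)
  arch <- architecture_spec("FCN+LCN", fcn_widths = 7, grid_filters = 3,
                            summation_width = 6, output_dim = 5,
                            output_nonlinearity = "tanh")
  m <- build_model(arch, c(4, 3, 2), dropout = 0, seed = 2)
  X <- matrix(rnorm(6 * 24), 6)
  Y <- matrix(rnorm(6 * 5), 6)
  fwd <- neurovoc:::model_forward(m, X, training = TRUE, train_bn = TRUE)
  L0 <- combined_loss(Y, fwd$out)
  gr <- neurovoc:::model_backward(fwd$model, fwd,
                                  neurovoc:::combined_loss_grad(Y, fwd$out))
  m2 <- fwd$model
  bump <- function(mod) {
    f2 <- neurovoc:::model_forward(mod, X, training = TRUE, train_bn = FALSE)
    (combined_loss(Y, f2$out) - L0) / 1e-6
  }
  mp <- m2; mp$paths[[1]][[1]]$W[3, 2] <- mp$paths[[1]][[1]]$W[3, 2] + 1e-6
  expect_lt(abs(bump(mp) - gr$path_grads[[1]][[1]]$W[3, 2]), 1e-4)
  mp <- m2; mp$paths[[2]][[1]]$K[2, 1, 2, 5] <-
    mp$paths[[2]][[1]]$K[2, 1, 2, 5] + 1e-6
  expect_lt(abs(bump(mp) - gr$path_grads[[2]][[1]]$K[2, 1, 2, 5]), 1e-4)
  mp <- m2; mp$summation[[1]]$W[4, 3] <- mp$summation[[1]]$W[4, 3] + 1e-6
  expect_lt(abs(bump(mp) - gr$sum_grads[[1]]$W[4, 3]), 1e-4)
})

test_that("parameter counts: FCN analytic, LCN = CNN x positions", {
  arch <- architecture_spec("FCN", fcn_widths = c(10, 8), output_dim = 4,
                            summation_width = 6)
  m <- build_model(arch, c(4, 3, 2))
  d_in <- 24
  expected <- (d_in * 10 + 10) + 2 * 10 + (10 * 8 + 8) + 2 * 8 +
    (8 * 6 + 6) + 2 * 6 + (6 * 4 + 4)
  expect_equal(model_param_count(m), expected)
  aL <- architecture_spec("LCN", grid_filters = 4, grid_kernel = c(3, 3),
                          output_dim = 4, summation_width = 6)
  aC <- architecture_spec("CNN", grid_filters = 4, grid_kernel = c(3, 3),
                          output_dim = 4, summation_width = 6)
  mL <- build_model(aL, c(5, 4, 2))
  mC <- build_model(aC, c(5, 4, 2))
  lcn <- mL$paths[[1]][[1]]; cnn <- mC$paths[[1]][[1]]
  n_pos <- 5 * 4
  expect_equal(length(lcn$K) + length(lcn$b),
               n_pos * (length(cnn$K) + length(cnn$b)))
  # combined extractor widths concatenate
  aFL <- architecture_spec("FCN+LCN", fcn_widths = 16, grid_filters = 4,
                           output_dim = 4, summation_width = 6)
  mFL <- build_model(aFL, c(5, 4, 2))
  expect_equal(attr(mFL$paths[[1]], "d_out") + attr(mFL$paths[[2]], "d_out"),
               16 + 5 * 4 * 4)
  expect_error(build_model(architecture_spec("CNN", grid_kernel = c(9, 9)),
                           c(5, 4, 2)), "receptive field")
})

test_that("a solvable linear task trains to a strongly negative loss", {
  set.seed(99)
  X <- matrix(rnorm(500 * 20), 500)
  Y <- scale(X %*% matrix(rnorm(20 * 8), 20))
  arch <- architecture_spec("FCN", fcn_widths = 32, summation_width = 16,
                            output_dim = 8)
  m <- build_model(arch, c(5, 4, 1), dropout = 0, seed = 4)
  cfg <- training_config(batch_size = 64, lr = 5e-3, epochs = 200, seed = 7)
  m <- train_model(m, X, Y, cfg)
  expect_lte(tail(m$history$train_loss, 1), -0.9)
  # loss decreases monotonically over the first epochs (one slip allowed)
  d5 <- diff(m$history$train_loss[1:6])
  expect_lte(sum(d5 > 0), 1)
})

test_that("training is exactly reproducible and evaluation deterministic", {
  set.seed(11)
  X <- matrix(rnorm(300 * 20), 300)
  Y <- scale(X %*% matrix(rnorm(20 * 8), 20))
  arch <- architecture_spec("FCN", fcn_widths = 16, summation_width = 8,
                            output_dim = 8)
  cfg <- training_config(batch_size = 64, lr = 3e-3, epochs = 8, seed = 5)
  m1 <- train_model(build_model(arch, c(5, 4, 1), seed = 4), X, Y, cfg)
  m2 <- train_model(build_model(arch, c(5, 4, 1), seed = 4), X, Y, cfg)
  expect_identical(m1$history, m2$history)
  p1 <- reconstruct(m1, X)
  expect_identical(p1, reconstruct(m1, X))
  expect_equal(ncol(p1), 8L)
  # tanh-output model stays strictly inside (-1, 1)
  archt <- architecture_spec("FCN", fcn_widths = 16, summation_width = 8,
                             output_dim = 8, output_nonlinearity = "tanh")
  mt <- train_model(build_model(archt, c(5, 4, 1), seed = 4), X,
                    tanh(Y), cfg)
  pt <- reconstruct(mt, X)
  expect_true(all(pt > -1 & pt < 1))
})

test_that("the learning rate halves after a four-epoch validation plateau", {
  set.seed(12)
  X <- matrix(rnorm(400 * 20), 400)
  Y <- scale(X %*% matrix(rnorm(20 * 8), 20))
  arch <- architecture_spec("FCN", fcn_widths = 16, summation_width = 8,
                            output_dim = 8)
  m <- build_model(arch, c(5, 4, 1), dropout = 0, seed = 5)
  # a vanishing learning rate freezes the model: the validation loss cannot
  # improve, so the plateau rule must fire on schedule
  cfg <- training_config(batch_size = 512, lr = 1e-13, epochs = 10, seed = 3)
  m <- train_model(m, X, Y, cfg)
  expect_equal(m$history$lr[1:5], rep(1e-13, 5))
  expect_equal(m$history$lr[6], 5e-14)
  expect_equal(m$history$lr[10], 2.5e-14)
})

test_that("invalid training configurations are rejected", {
  expect_error(training_config(lr = -1))
  expect_error(training_config(dropout = 1.2))
  expect_error(architecture_spec("MLP"), "arg")
})
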