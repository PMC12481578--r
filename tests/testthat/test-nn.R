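# Numerical verification of the reverse-mode engine: for every layer kind,
# analytic parameter and input gradients are compared against central finite
# differences on a tiny network.

num_grad <- function(f, p, eps = 1e-5) {
  g <- array(0, dim(p) %||% length(p))
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p[i] + eps
    p2 <- p; p2[i] <- p[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}

check_gradients <- function(layers, input_dim, n = 4, seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * input_dim), n)
  m <- nn_build(nn_model(layers), input_dim, seed = seed)
  y <- matrix(rnorm(n * prod(m$output_shape)), n)
  lossf <- function(mm) sum((nn_forward(mm, x)$out - y)^2)
  fw <- nn_forward(m, x)
  bw <- nn_backward(m, fw$caches, 2 * (fw$out - y))
  worst <- 0
  for (i in seq_along(m$layers)) {
    for (nm in names(m$layers[[i]]$params)) {
      f <- function(pv) {
        mm <- m
        mm$layers[[i]]$params[[nm]] <- pv
        lossf(mm)
      }
      ng <- num_grad(f, m$layers[[i]]$params[[nm]])
      worst <- max(worst, max(abs(ng - bw$grads[[i]][[nm]])) /
                     max(1, max(abs(ng))))
    }
  }
  fx <- function(xv) {
    dim(xv) <- dim(x)
    sum((nn_forward(m, xv)$out - y)^2)
  }
  ngx <- num_grad(fx, as.vector(x))
  worst <- max(worst, max(abs(ngx - as.vector(bw$dx))) / max(1, max(abs(ngx))))
  worst
}

test_that("dense-stack gradients match finite differences", {
  err <- check_gradients(list(layer_dense(7, "tanh"), layer_dense(3, "sigmoid"),
                              layer_dense(1, "gelu")), 11)
  expect_lt(err, 1e-6)
})

test_that("convolutional gradients match finite differences", {
  err <- check_gradients(list(layer_reshape_conv(), layer_conv1d(3, 5, "tanh"),
                              layer_avgpool(2), layer_flatten(),
                              layer_dense(1)), 40)
  expect_lt(err, 1e-6)
})

test_that("custom SERS layer gradients match finite differences", {
  err <- check_gradients(list(layer_reshape_conv(),
                              layer_multiscale(c(4, 7, 10), 3),
                              layer_region_scaling(rbind(c(3, 10), c(20, 30))),
                              layer_paired_conv(2, 5), layer_avgpool(3),
                              layer_flatten(), layer_dense(1)), 60)
  expect_lt(err, 1e-6)
  err3pl <- check_gradients(list(layer_dense(1, "tanh"),
                                 layer_three_pl(10, 0.3, 1.2)), 11)
  expect_lt(err3pl, 1e-6)
})

test_that("transformer gradients match finite differences", {
  err <- check_gradients(list(layer_reshape_conv(), layer_patch_embed(10, 8),
                              layer_transformer_block(3, 12, 0),
                              layer_meanpool_tokens(), layer_dense(1)),
                         50, n = 3)
  expect_lt(err, 1e-5)
})

test_that("training reduces loss and is reproducible under a fixed seed", {
  set.seed(1)
  X <- matrix(rnorm(150 * 20), 150)
  y <- as.numeric(X %*% rnorm(20))
  m <- nn_build(nn_model(list(layer_dense(16, "relu"), layer_dense(1))), 20,
                seed = 2)
  fit <- nn_fit(m, X, y, loss = "mse", lr = 0.01, epochs = 60,
                batch_size = 32, seed = 5)
  expect_lt(tail(fit$history$train_loss, 1), 0.1 * fit$history$train_loss[1])
  fit2 <- nn_fit(m, X, y, loss = "mse", lr = 0.01, epochs = 60,
                 batch_size = 32, seed = 5)
  expect_identical(fit$history$train_loss, fit2$history$train_loss)
})

test_that("early stopping restores the checkpointed best weights", {
  set.seed(2)
  X <- matrix(rnorm(60 * 10), 60)
  y <- as.numeric(X %*% rnorm(10))
  m <- nn_build(nn_model(list(layer_dense(8, "relu"), layer_dense(1))), 10,
                seed = 1)
  fit <- nn_fit(m, X[1:40, ], y[1:40], x_val = X[41:60, ], y_val = y[41:60],
                loss = "mse", lr = 0.05, epochs = 100, batch_size = 16,
                patience = 10, seed = 3)
  val_now <- mean((nn_predict(fit$model, X[41:60, ]) - y[41:60])^2)
  expect_equal(val_now, fit$best_val, tolerance = 1e-10)
  expect_lte(nrow(fit$history), 100)
})

test_that("dropout perturbs only training-mode forward passes", {
  m <- nn_build(nn_model(list(layer_dropout(0.5), layer_dense(1))), 6,
                seed = 1)
  x <- matrix(1, 5, 6)
  p1 <- nn_forward(m, x, training = FALSE)$out
  p2 <- nn_forward(m, x, training = FALSE)$out
  expect_identical(p1, p2)
  set.seed(1)
  t1 <- nn_forward(m, x, training = TRUE)$out
  expect_false(isTRUE(all.equal(t1, p1)))
})
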