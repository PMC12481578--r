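test_that("the three-parameter logistic has its calibration-curve shape", {
  expect_equal(three_pl(0.7, upper = 10, midpoint = 0.7, steepness = 2), 5)
  expect_equal(three_pl(-1e3, upper = 8), 0, tolerance = 1e-12)
  expect_equal(three_pl(1e3, upper = 8), 8, tolerance = 1e-12)
  z <- seq(-5, 5, by = 0.1)
  v <- three_pl(z, upper = 10, midpoint = 1, steepness = 0.8)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 10))
  expect_error(three_pl(0, upper = -1), "upper")
})

test_that("the 3PL output layer never exceeds its asymptote during training", {
  set.seed(4)
  X <- matrix(rnorm(80 * 12), 80)
  y <- runif(80, 0, 9)
  m <- nn_build(nn_model(list(layer_dense(6, "relu"), layer_dense(1),
                              layer_three_pl(upper_init = 10))), 12, seed = 1)
  opt <- opt_create(m, "adam", 0.01)
  for (step in 1:30) {
    fw <- nn_forward(m, X, training = TRUE)
    upper <- m$layers[[3]]$params$upper
    expect_true(all(fw$out > 0 & fw$out < upper))
    lo <- nn_loss(fw$out, y, "mae")
    bw <- nn_backward(m, fw$caches, lo$grad)
    st <- opt_step(opt, m, bw$grads)
    opt <- st$opt
    m <- st$model
  }
})

test_that("region scaling is the documented piecewise multiplication", {
  x <- rep(1, 50)
  reg <- rbind(c(1, 10), c(21, 30))
  out <- region_scaling(x, reg, c(2, 3))
  expect_equal(out, c(rep(2, 10), rep(1, 10), rep(3, 10), rep(1, 20)))
  expect_equal(region_scaling(x, reg, c(1, 1)), x)
  expect_equal(region_scaling(x, rbind(c(1, 50)), 0), rep(0, 50))
  expect_error(region_scaling(x, rbind(c(1, 10), c(5, 20)), c(1, 1)),
               "non-overlapping")
  expect_error(region_scaling(x, rbind(c(0, 10)), 1), "within")
})

test_that("region scaling and multiscale layers are exactly linear", {
  set.seed(5)
  x1 <- array(rnorm(2 * 60 * 1), c(2, 60, 1))
  x2 <- array(rnorm(2 * 60 * 1), c(2, 60, 1))
  lay <- layer_multiscale(c(4, 7, 10), 3)
  f <- function(z) nn_apply_layer(lay, z, seed = 9)
  expect_equal(f(x1 + 2 * x2), f(x1) + 2 * f(x2) - f(0 * x1), tolerance = 1e-12)
  reg <- layer_region_scaling(rbind(c(5, 20)), scale_init = 1.7)
  g <- function(z) nn_apply_layer(reg, z, seed = 9)
  expect_equal(g(x1 + 2 * x2), g(x1) + 2 * g(x2), tolerance = 1e-12)
})

test_that("multiscale output is length-preserving with 24 channels", {
  x <- array(rnorm(3 * 120), c(3, 120, 1))
  out <- nn_apply_layer(layer_multiscale(), x, seed = 1)
  expect_equal(dim(out), c(3, 120, 24))
  # zero input with zero bias gives zero output
  out0 <- nn_apply_layer(layer_multiscale(), 0 * x, seed = 1)
  expect_equal(max(abs(out0)), 0)
  expect_error(nn_apply_layer(layer_multiscale(), array(0, c(2, 30, 1))),
               "largest kernel")
})

test_that("multiscale impulse responses match a direct correlation oracle", {
  L <- 60
  x <- array(0, c(1, L, 1))
  t0 <- 31
  x[1, t0, 1] <- 1
  lay <- layer_multiscale(c(4, 7, 10), 2)
  built <- with_seed(1, nn_layer_init(lay, c(L, 1L)))
  out <- nn_layer_forward(built, x)$out
  kernels <- c(4, 7, 10)
  for (bi in seq_along(kernels)) {
    W <- built$params[[paste0("W", bi)]]
    b <- built$params[[paste0("b", bi)]]
    for (f in 1:2) {
      impulse <- numeric(L)
      impulse[t0] <- 1
      oracle <- direct_xcorr_oracle(impulse, W[, f], b[f])
      expect_equal(out[1, , (bi - 1) * 2 + f], oracle, tolerance = 1e-12)
    }
  }
})

test_that("paired conv concatenates tanh and rectified branches", {
  x <- array(rnorm(2 * 30), c(2, 30, 1))
  lay <- with_seed(2, nn_layer_init(layer_paired_conv(3, 5), c(30L, 1L)))
  out <- nn_layer_forward(lay, x)$out
  expect_equal(dim(out), c(2, 30, 6))
  z <- conv_forward(x, lay$params$W, lay$params$b, 5)$z
  expect_equal(out[, , 1:3], tanh(z))
  expect_equal(out[, , 4:6], pmax(z, 0))
})

test_that("model kinds assemble with their documented output behavior", {
  m3 <- build_model("cnn_3pl", 120, upper_init = 10, seed = 1)
  p <- predict_quant(m3, matrix(rnorm(6 * 120), 6))
  expect_true(all(p > 0 & p < 10))
  ml <- build_model("cnn_linear", 120, seed = 1)
  expect_length(predict_quant(ml, matrix(rnorm(3 * 120), 3)), 3)
  mv <- build_model("vit", 125, seed = 1)
  expect_equal(mv$net$layers[[2]]$cfg$n_patches, 5)
  expect_length(predict_quant(mv, matrix(rnorm(2 * 125), 2)), 2)
})

test_that("patch counts follow the zero-padding rule", {
  expect_equal(vit_patch_count(925), 37)
  expect_equal(vit_patch_count(937), 38)
  expect_equal(vit_patch_count(842), 34)
})

test_that("identity scaling leaves the scale-adjusting CNN unchanged", {
  reg <- rbind(c(10, 40), c(80, 110))
  with_reg <- build_model("scnn", 120, regions = reg, seed = 7)
  without <- build_model("scnn", 120, regions = NULL, seed = 7)
  # align trained weights: copy every non-region layer's parameters
  ridx <- which(vapply(with_reg$net$layers, function(l)
    l$kind == "region_scaling", logical(1)))
  keep <- setdiff(seq_along(with_reg$net$layers), ridx)
  for (i in seq_along(keep))
    without$net$layers[[i]]$params <- with_reg$net$layers[[keep[i]]]$params
  expect_equal(with_reg$net$layers[[ridx]]$params$s, c(1, 1))
  x <- matrix(rnorm(4 * 120), 4)
  expect_equal(predict_quant(with_reg, x), predict_quant(without, x),
               tolerance = 1e-12)
})

test_that("proposed scaling regions avoid all reference peaks", {
  refs <- fixture_study_refs_small()
  reg <- propose_scaling_regions(refs, quantile_threshold = 0.6,
                                 min_width = 5)
  expect_true(nrow(reg) >= 1)
  thr <- apply(refs, 1, stats::quantile, probs = 0.6)
  for (r in seq_len(nrow(reg)))
    for (i in seq_len(nrow(refs)))
      expect_true(all(refs[i, reg[r, 1]:reg[r, 2]] <= thr[i] + 1e-12))
})
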