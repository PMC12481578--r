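make_pair_inputs <- function(n_clean = 20, n_bg = 4, p = 40, seed = 8) {
  set.seed(seed)
  list(clean = matrix(runif(n_clean * p), n_clean),
       bg = matrix(runif(n_bg * p, 0, 0.5), n_bg))
}

test_that("noisy pair construction splits and normalizes as documented", {
  # the 80:20 rule on 364 pairs gives 291 train / 73 test
  set.seed(1)
  big <- build_noisy_pairs(matrix(runif(364 * 10), 364),
                           matrix(runif(5 * 10), 5), seed = 3)
  expect_equal(nrow(big$x_train), 291)
  expect_equal(nrow(big$x_test), 73)
  pin <- make_pair_inputs()
  pairs <- build_noisy_pairs(pin$clean, pin$bg, seed = 2)
  expect_true(all(pairs$x_train >= 0 & pairs$x_train <= 1))
  expect_true(all(pairs$y_train >= 0 & pairs$y_train <= 1))
  # same seed reproduces the pairing exactly
  pairs2 <- build_noisy_pairs(pin$clean, pin$bg, seed = 2)
  expect_identical(pairs$background_of, pairs2$background_of)
  expect_identical(pairs$x_train, pairs2$x_train)
  # a single background is used for every pair
  single <- build_noisy_pairs(pin$clean, pin$bg[1, , drop = FALSE], seed = 4)
  expect_true(all(single$background_of == 1))
  expect_error(build_noisy_pairs(pin$clean, pin$bg[0, , drop = FALSE]),
               "empty")
  expect_error(build_noisy_pairs(pin$clean, matrix(0, 2, 39)), "grids differ")
})

test_that("the trained denoiser beats the identity baseline on held-out pairs", {
  set.seed(11)
  p <- 40
  grid_t <- seq(0, 1, length.out = p)
  clean <- t(replicate(60, exp(-(grid_t - runif(1, 0.2, 0.8))^2 / 0.005)))
  bg <- t(replicate(5, 0.8 * exp(-(grid_t - 0.5)^2 / 0.05)))
  pairs <- build_noisy_pairs(clean, bg, seed = 5)
  cfg <- dae_config(input_dim = p, encoder_widths = c(32, 8), epochs = 60)
  dae <- train_dae(pairs, cfg, seed = 6)
  identity_mse <- mean((pairs$x_test - pairs$y_test)^2)
  expect_lt(dae$test_mse, identity_mse)
  # training loss decreases
  expect_lt(tail(dae$history$train_loss, 1), dae$history$train_loss[1])
  # deterministic under the seed
  dae2 <- train_dae(pairs, cfg, seed = 6)
  expect_identical(dae$test_mse, dae2$test_mse)
  # an untrained model is no better than the trained one
  dae0 <- train_dae(pairs, dae_config(input_dim = p,
                                      encoder_widths = c(32, 8),
                                      epochs = 0), seed = 6)
  expect_gte(dae0$test_mse, dae$test_mse)
  # denoised outputs respect the sigmoid range contract
  out <- denoise(dae, pairs$x_test)
  expect_true(all(out >= 0 & out <= 1))
  expect_error(train_dae(pairs, dae_config(input_dim = p + 1)),
               "does not match")
  expect_error(denoise(dae, matrix(0.1, 2, p + 3)), "input_dim")
})

test_that("denoise enforces container states and dimensions", {
  set.seed(3)
  p <- 30
  pairs <- build_noisy_pairs(matrix(runif(20 * p), 20),
                             matrix(runif(2 * p), 2), seed = 1)
  dae <- train_dae(pairs, dae_config(input_dim = p,
                                     encoder_widths = c(16, 4),
                                     epochs = 5), seed = 2)
  s_raw <- spectrum(seq_len(p), runif(p), state = "raw")
  expect_error(denoise(dae, s_raw), "normalized")
  s_norm <- spectrum(seq_len(p), minmax_normalize(runif(p)),
                     state = "normalized")
  out <- denoise(dae, s_norm)
  expect_identical(out$state, "denoised")
  expect_true(all(out$intensities >= 0 & out$intensities <= 1))
  # applying the denoiser to its own output is well-defined (idempotence
  # is not claimed, only closure)
  out2 <- denoise(dae, out)
  expect_identical(out2$state, "denoised")
})
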