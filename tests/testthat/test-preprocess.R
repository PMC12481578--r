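test_that("ALS baseline matches a dense penalized-least-squares oracle", {
  set.seed(1)
  y <- cumsum(rnorm(50)) + 5
  r <- als_baseline(y)
  expect_lt(max(abs(r$baseline - dense_als_oracle(y))), 1e-8)
  expect_equal(r$corrected, y - r$baseline)
  # non-default parameters too
  p2 <- als_params(lam = 50, p = 0.3, n_iter = 4)
  r2 <- als_baseline(y, p2)
  expect_lt(max(abs(r2$baseline - dense_als_oracle(y, 50, 0.3, 4))), 1e-8)
})

test_that("ALS reproduces constant and linear inputs exactly", {
  cc <- als_baseline(rep(3.3, 30))
  expect_lt(max(abs(cc$baseline - 3.3)), 1e-6)
  expect_lt(max(abs(cc$corrected)), 1e-6)
  ramp <- seq(-2, 7, length.out = 40)
  rr <- als_baseline(ramp)
  expect_lt(max(abs(rr$corrected)), 1e-6)
})

test_that("ALS is shift-invariant and leaves positive peaks above baseline", {
  set.seed(2)
  y <- rnorm(60, sd = 0.05) +
    2 * exp(-(seq_len(60) - 30)^2 / 8)  # single positive peak, flat base
  r <- als_baseline(y)
  expect_gt(r$corrected[30], 1)  # peak apex survives correction
  shift <- als_baseline(y + 11)
  expect_lt(max(abs(shift$baseline - r$baseline - 11)), 1e-6)
  expect_error(als_baseline(c(1, NA, 3)), "finite")
  expect_error(als_baseline(c(1, 2)), "length")
})

test_that("min-max normalization maps to [0, 1] and flags constants", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  set.seed(3)
  y <- rnorm(30)
  ny <- minmax_normalize(y)
  expect_equal(range(ny), c(0, 1))
  expect_warning(z <- minmax_normalize(rep(2, 5)), "constant")
  expect_equal(z, rep(0, 5))
})

test_that("Savitzky-Golay derivative matches a sliding polyfit oracle", {
  p <- sg_params(window = 11, polyorder = 3, deriv_order = 2)
  set.seed(4)
  y <- cumsum(rnorm(60))
  d <- sg_derivative(y, p)
  expect_length(d, length(y))
  oracle <- polyfit_sg_oracle(y, 11, 3, 2)
  interior <- !is.na(oracle)
  expect_lt(max(abs(d[interior] - oracle[interior])), 1e-8)
})

test_that("Savitzky-Golay derivative has the analytic values on polynomials", {
  ramp <- 2.5 * (1:100)
  expect_lt(max(abs(sg_derivative(ramp, sg_params())[17:84])), 1e-10)
  a <- 0.3
  quad <- a * (1:100)^2
  d <- sg_derivative(quad, sg_params())
  expect_equal(d[17:84], rep(2 * a, 68), tolerance = 1e-8)
  expect_error(sg_params(window = 10), "odd")
  expect_error(sg_params(window = 5, polyorder = 5), "polyorder")
  expect_error(sg_derivative(1:5, sg_params()), "window")
})

test_that("noise overlay is plain addition of baselined spectra", {
  g <- seq(1, 50)
  clean <- spectrum(g, runif(50), state = "baselined")
  zero <- spectrum(g, rep(0, 50), state = "baselined")
  bg <- spectrum(g, runif(50), state = "baselined")
  expect_equal(overlay_noise(clean, zero)$intensities, clean$intensities)
  expect_equal(overlay_noise(zero, bg)$intensities, bg$intensities)
  over <- overlay_noise(clean, bg)
  expect_equal(over$intensities - bg$intensities, clean$intensities)
  expect_equal(overlay_noise(clean, bg, gain = 0.5)$intensities,
               clean$intensities + 0.5 * bg$intensities)
  raw <- spectrum(g, runif(50), state = "raw")
  expect_error(overlay_noise(raw, bg), "baselined")
  short <- spectrum(g[1:49], runif(49), state = "baselined")
  expect_error(overlay_noise(clean, short), "grids differ")
})

test_that("dataset preprocessing applies crop -> ALS -> normalize in order", {
  man <- sample_manifest(c("a", "b"), c(1, 2), c(0, 1), c(2, 0), "water",
                         c(3, 3), "repeat")
  ds <- make_dataset(man, response_model(), seed = 9)
  out <- preprocess_dataset(ds)
  expect_identical(out$state, "normalized")
  expect_equal(ncol(out$intensities), 842)
  expect_true(all(out$intensities >= 0 & out$intensities <= 1))
  expect_true(all(abs(apply(out$intensities, 1, max) - 1) < 1e-12))
  base_only <- preprocess_dataset(ds, normalize = FALSE)
  expect_identical(base_only$state, "baselined")
})
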