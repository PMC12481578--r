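test_that("reference spectra are normalized, distinct and self-similar", {
  lib <- default_band_library()
  refs <- reference_matrix(lib, sers_grid())
  for (a in c("serotonin", "dopamine", "epinephrine")) {
    expect_equal(cosine_similarity(refs[a, ], refs[a, ]), 1)
    expect_equal(range(refs[a, ]), c(0, 1))
  }
  pairs <- combn(c("serotonin", "dopamine", "epinephrine"), 2)
  for (j in seq_len(ncol(pairs)))
    expect_lt(cosine_similarity(refs[pairs[1, j], ], refs[pairs[2, j], ]),
              0.9)
  expect_error(make_reference("caffeine", lib), "unknown analyte")
  empty <- lib
  empty$serotonin <- empty$serotonin[0, ]
  expect_error(make_reference("serotonin", empty), "empty")
})

test_that("every analyte library holds at least four in-grid bands", {
  lib <- default_band_library()
  g <- range(sers_grid())
  for (b in lib) {
    expect_gte(nrow(b), 4)
    expect_true(all(b$center > g[1] & b$center < g[2]))
    expect_true(all(b$amplitude > 0))
  }
})

test_that("mixtures obey the response model contracts", {
  lib <- default_band_library()
  quiet <- response_model(noise_sigma = 0, scale_jitter_sigma = 0,
                          baseline_coeffs = 0)
  s0 <- make_mixture(0, 0, 0, "water", quiet, lib, seed = 1)
  expect_equal(max(abs(s0$intensities)), 0)
  expect_identical(s0$state, "raw")
  s1 <- make_mixture(1, 2, 3, "urine", seed = 42)
  s2 <- make_mixture(1, 2, 3, "urine", seed = 42)
  expect_identical(s1$intensities, s2$intensities)
  expect_error(make_mixture(-1, 0, 0, "water"), ">= 0")
})

test_that("the saturating response is locally linear far below half-saturation", {
  m <- response_model()
  a1 <- response_amplitude(0.01, "serotonin", m)
  a2 <- response_amplitude(0.02, "serotonin", m)
  expect_equal(a2 / a1, 2, tolerance = 0.01)
  # monotone and bounded by a_max
  cs <- seq(0, 50, by = 0.5)
  amps <- response_amplitude(cs, "dopamine", m)
  expect_true(all(diff(amps) > 0))
  expect_true(all(amps < m$a_max[["dopamine"]]))
})

test_that("urine spectra are water spectra plus the background template", {
  lib <- default_band_library()
  quiet <- response_model(noise_sigma = 0, scale_jitter_sigma = 0)
  su <- make_mixture(1, 2, 3, "urine", quiet, lib, seed = 5)
  sw <- make_mixture(1, 2, 3, "water", quiet, lib, seed = 5)
  bg <- reference_matrix(lib, sers_grid())["urine_background", ]
  expect_lt(max(abs(su$intensities - sw$intensities - bg)), 1e-12)
})

test_that("dataset generation reproduces the study design counts", {
  ds <- make_dataset(study_manifest("urine"),
                     response_model(noise_sigma = 0), seed = 3,
                     grid = sers_grid())
  expect_equal(n_spectra(ds), 318)
  expect_true(all(is.finite(ds$intensities)))
  one <- make_dataset(sample_manifest("z", 1, 1, 4, "water", 7, "repeat"),
                      seed = 2)
  expect_equal(n_spectra(one), 7)
  expect_true(all(one$targets == 4))
})

test_that("the design confounds serotonin absence with other signals", {
  man <- study_manifest("urine")
  absent <- man[man$ht5_uM == 0, ]
  # every serotonin-free sample carries another neurotransmitter or is the
  # pure background sample
  expect_true(all(absent$epi_uM + absent$da_uM > 0 | absent$sample_id == "U"))
  expect_setequal(absent$sample_id, c("A", "B", "F", "U"))
  # and one sample is pure serotonin, so the signal is learnable
  pure <- man[man$ht5_uM > 0 & man$epi_uM + man$da_uM == 0, ]
  expect_true("C" %in% pure$sample_id)
})
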