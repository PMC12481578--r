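test_that("spectrum objects enforce their invariants", {
  expect_error(spectrum(1:3, 1:2), "equal length")
  expect_error(spectrum(c(1, 3, 2), 1:3), "strictly increasing")
  expect_error(spectrum(1:3, c(0, 0.5, 1.2), state = "normalized"),
               "\\[0, 1\\]")
  s <- spectrum(1:5, rnorm(5))
  expect_s3_class(s, "sers_spectrum")
  expect_identical(s$state, "raw")
})

test_that("the instrument grid crops to exactly the analysis window", {
  g <- sers_grid()
  expect_length(g, 937)
  expect_equal(diff(range(diff(g))), 0, tolerance = 1e-9)
  s <- spectrum(g, seq_along(g))
  cropped <- crop_range(s, 300, 2000)
  expect_length(cropped$wavenumbers, 842)
  expect_equal(min(cropped$wavenumbers), 300)
  expect_equal(max(cropped$wavenumbers), 2000)
})

test_that("crop_range is idempotent, handles edges and rejects empty windows", {
  s <- spectrum(seq(100, 200, by = 10), rnorm(11))
  expect_equal(crop_range(s, 100, 200), s)
  one <- crop_range(s, 145, 155)
  expect_length(one$wavenumbers, 1)
  expect_equal(one$wavenumbers, 150)
  c1 <- crop_range(s, 120, 180)
  expect_equal(crop_range(c1, 120, 180), c1)
  expect_error(crop_range(s, 101, 104), "no grid points")
  expect_error(crop_range(s, 180, 120), "lo must be <")
})

test_that("delimited spectrum tables round-trip and report parse errors", {
  sp <- fixture_random_spectra(n = 3, p = 25, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, path)
  back <- read_spectra(path)
  expect_named(back, names(sp))
  for (i in seq_along(sp)) {
    expect_equal(back[[i]]$wavenumbers, sp[[i]]$wavenumbers)
    expect_equal(back[[i]]$intensities, sp[[i]]$intensities)
  }
  # matrix container round-trip
  path2 <- withr::local_tempfile(fileext = ".rds")
  write_spectra(sp, path2, format = "matrix_container")
  back2 <- read_spectra(path2, format = "matrix_container")
  expect_equal(back2[[2]]$intensities, sp[[2]]$intensities)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,a", "1,0.5", "2,oops", "3,0.7"), bad)
  expect_error(read_spectra(bad), "row 3.*column.*a")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,a", "1,0.5", "1,0.6"), dup)
  expect_error(read_spectra(dup), "duplicate wavenumbers")
})

test_that("unsorted input grids are sorted on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,a", "3,30", "1,10", "2,20"), path)
  s <- read_spectra(path)[[1]]
  expect_equal(s$wavenumbers, 1:3)
  expect_equal(s$intensities, c(10, 20, 30))
})

test_that("the study-design manifest has the documented structure", {
  m <- study_manifest("both")
  expect_equal(sum(m$n_spectra), 682)
  expect_equal(sum(m$n_spectra[m$medium == "urine"]), 318)
  expect_equal(sum(m$n_spectra[m$medium == "water"]), 364)
  urine <- study_manifest("urine")
  expect_setequal(urine$sample_id[urine$split_role == "held_out_test"],
                  c("D", "E"))
  expect_identical(urine$sample_id[urine$split_role == "held_out_validation"],
                   "F")
  # all water rows are repeats (the held-out samples have no water spectra)
  expect_true(all(study_manifest("water")$split_role == "repeat"))
})

make_blank_ds <- function(manifest) {
  n <- sum(manifest$n_spectra)
  labelled_dataset(matrix(0, n, 4), 1:4,
                   rep(manifest$ht5_uM, manifest$n_spectra),
                   rep(manifest$sample_id, manifest$n_spectra),
                   rep(manifest$medium, manifest$n_spectra))
}

test_that("split rules reproduce the urine protocol counts", {
  man <- study_manifest("urine")
  ds <- split_dataset(make_blank_ds(man), man, 0.1, seed = 7)
  counts <- table(ds$split)
  expect_equal(unname(counts[c("train", "validation", "test")]),
               c(218L, 46L, 54L), ignore_attr = TRUE)
  # held-out samples route deterministically
  expect_true(all(ds$split[ds$sample_id %in% c("D", "E")] == "test"))
  expect_true(all(ds$split[ds$sample_id == "F"] == "validation"))
  expect_false(any(ds$sample_id[ds$split == "test"] %in%
                     setdiff(man$sample_id, c("D", "E"))))
  # determinism
  ds2 <- split_dataset(make_blank_ds(man), man, 0.1, seed = 7)
  expect_identical(ds$split, ds2$split)
})

test_that("splits partition and conserve counts for random manifests", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    roles <- sample(c("repeat", "held_out_validation", "held_out_test"), k,
                    replace = TRUE, prob = c(0.7, 0.15, 0.15))
    roles[1] <- "repeat"  # ensure at least one repeat sample
    man <- sample_manifest(paste0("s", 1:k), runif(k, 0, 9), runif(k, 0, 9),
                           runif(k, 0, 9), "urine", sample(1:30, k), roles)
    ds <- split_dataset(make_blank_ds(man), man, 0.1, seed = rep)
    expect_false(anyNA(ds$split))
    expect_equal(length(ds$split), sum(man$n_spectra))
    n_rep <- sum(man$n_spectra[man$split_role == "repeat"])
    expect_equal(sum(ds$split == "validation"),
                 sum(man$n_spectra[man$split_role == "held_out_validation"]) +
                   ceiling(0.1 * n_rep))
  }
})

test_that("single repeat sample of 10 spectra splits 9/1/0", {
  man <- sample_manifest("x", 1, 1, 1, "urine", 10, "repeat")
  ds <- split_dataset(make_blank_ds(man), man, 0.1, seed = 1)
  expect_equal(sum(ds$split == "train"), 9)
  expect_equal(sum(ds$split == "validation"), 1)
  expect_equal(sum(ds$split == "test"), 0)
})

test_that("unknown sample ids are a manifest-mismatch error", {
  man <- sample_manifest("x", 1, 1, 1, "urine", 2, "repeat")
  ds <- labelled_dataset(matrix(0, 2, 4), 1:4, c(1, 1), c("x", "y"),
                         c("urine", "urine"))
  expect_error(split_dataset(ds, man), "absent from manifest.*y")
})
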