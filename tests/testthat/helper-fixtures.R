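# Shared fixtures, built lazily once per test run and cached. The heavy
# end-to-end products (simulated study dataset, trained denoiser, trained
# quantifier ensembles) are shared by the acceptance tests so each is built
# a single time.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# Random small spectra on a toy grid, for I/O round-trips.
fixture_random_spectra <- function(n = 3, p = 40, seed = 1) {
  set.seed(seed)
  grid <- seq(300, 1000, length.out = p)
  sp <- lapply(seq_len(n), function(i) spectrum(grid, stats::runif(p)))
  names(sp) <- paste0("s", seq_len(n))
  sp
}

# Noiseless, saturation-free recovery fixture: raw (unnormalized) linear
# spectra over a dense design of 28 concentration combinations spanning the
# 0-9 uM cube (a 3-D response surface needs many combinations to pin the
# map down), plus two held-out interior combinations for testing.
linear_manifest <- function() {
  set.seed(77)
  n_tr <- 28
  epi <- round(stats::runif(n_tr, 0, 9), 1)
  da <- round(stats::runif(n_tr, 0, 9), 1)
  ht5 <- round(c(seq(0, 9, length.out = 14),
                 stats::runif(n_tr - 14, 0, 9)), 1)
  ids <- c(sprintf("s%02d", seq_len(n_tr)), "T1", "T2")
  sample_manifest(ids, c(epi, 2, 4), c(da, 3, 1), c(ht5, 6, 2.5), "water",
                  rep(6, n_tr + 2),
                  c(rep("repeat", n_tr), "held_out_test", "held_out_test"))
}

fixture_linear <- function() fx_get("linear", function() {
  man <- linear_manifest()
  model <- response_model(mode = "linear", scale_jitter_sigma = 0,
                          noise_sigma = 0, baseline_coeffs = 0)
  ds <- make_dataset(man, model, seed = 11)
  ds <- preprocess_dataset(ds, als = NULL, crop = c(300, 2000),
                           normalize = FALSE)
  split_dataset(ds, man, 0.1, seed = 7)
})

# Full confounded study-design fixture: simulate both media, baseline
# correct, train the denoiser on water + background, denoise the urine
# spectra and crop to the analysis window.
fixture_study <- function() fx_get("study", function() {
  man <- study_manifest("both")
  ds <- make_dataset(man, response_model(), seed = 101)
  full_base <- preprocess_dataset(ds, als = als_params(), crop = NULL,
                                  normalize = FALSE)
  full_norm <- full_base
  full_norm$intensities <- t(apply(full_base$intensities, 1,
                                   minmax_normalize))
  full_norm$state <- "normalized"
  water <- ds_subset(full_base, which(full_base$medium == "water"))
  bg <- ds_subset(full_base, which(full_base$sample_id == "U" &
                                     full_base$medium == "urine"))
  pairs <- build_noisy_pairs(water$intensities, bg$intensities, seed = 202)
  dae <- train_dae(pairs, dae_config(input_dim = 937, epochs = 48),
                   seed = 303)
  urine <- ds_subset(full_norm, which(full_norm$medium == "urine"))
  den <- denoise(dae, urine)
  crop_ds <- function(d) {
    keep <- d$wavenumbers >= 300 - 1e-6 & d$wavenumbers <= 2000 + 1e-6
    d$intensities <- d$intensities[, keep, drop = FALSE]
    d$wavenumbers <- d$wavenumbers[keep]
    d
  }
  uraw <- crop_ds(urine)
  uden <- crop_ds(den)
  uraw <- split_dataset(uraw, man[man$medium == "urine", ], seed = 404)
  uden$split <- uraw$split
  list(manifest = man, dae = dae, pairs = pairs, raw = uraw, denoised = uden,
       references = reference_matrix(default_band_library(), sers_grid()))
})

# Tiny easily-learnable dataset: one peak whose height encodes the target.
make_easy_ds <- function(n, p = 64, seed = 1) {
  set.seed(seed)
  targets <- stats::runif(n, 0, 9)
  profile <- exp(-(seq_len(p) - 20)^2 / 10)
  x <- outer(targets / 9, profile) + matrix(stats::rnorm(n * p, 0, 0.001), n)
  labelled_dataset(x, seq_len(p), targets, rep("s", n), rep("water", n))
}

# Reference spectra on a reduced grid, for cheap layer/region tests.
fixture_study_refs_small <- function() fx_get("refs_small", function() {
  g <- seq(300, 2000, length.out = 300)
  reference_matrix(default_band_library(), g)[1:3, ]
})

# Scaled-down quantifier ensembles (5 members, 64 epochs) on the raw and
# denoised urine spectra of the study fixture.
fixture_ensembles <- function() fx_get("ensembles", function() {
  st <- fixture_study()
  pr <- train_protocol(ensemble_size = 5, epochs = 64, batch_size = 64,
                       early_stop_patience = 64)
  list(
    denoised = train_ensemble("cnn_3pl", ds_subset(st$denoised, "train"),
                              ds_subset(st$denoised, "validation"), pr,
                              seed = 505),
    raw = train_ensemble("cnn_3pl", ds_subset(st$raw, "train"),
                         ds_subset(st$raw, "validation"), pr, seed = 505))
})
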