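#' Band libraries for synthetic SERS spectra
#'
#' A band library holds, per compound, a table of Raman bands (center cm^-1,
#' FWHM cm^-1, relative amplitude, line shape). The default library covers
#' the three neurotransmitters and a urine background template. Band
#' positions are plausible, documented placements — not literature
#' assignments — designed so that each analyte has at least one unique band,
#' the analytes share overlapping bands (epinephrine and dopamine share a
#' catechol-like band at 1269 cm^-1; serotonin and dopamine have
#' near-coincident ring bands at 759/769 cm^-1), and clean unit-concentration
#' spectra are pairwise distinguishable (cosine < 0.9). The urine template
#' mixes a sharp urea-like band near 1003 cm^-1 with broad humps, emulating
#' unresolved biological background.
#'
#' @return Named list of band `data.frame`s with class `sers_band_library`.
#' @export
default_band_library <- function() {
  lib <- list(
    serotonin = data.frame(
      center = c(759, 934, 1134, 1310, 1425, 1547),
      width = c(18, 22, 20, 24, 20, 26),
      amplitude = c(1.0, 0.45, 0.6, 0.5, 0.35, 0.7),
      shape = "lorentzian"),
    dopamine = data.frame(
      center = c(594, 769, 1151, 1269, 1332, 1485),
      width = c(20, 18, 22, 20, 18, 24),
      amplitude = c(0.5, 1.0, 0.55, 0.6, 0.8, 0.45),
      shape = "lorentzian"),
    epinephrine = data.frame(
      center = c(640, 815, 1044, 1269, 1391, 1582),
      width = c(22, 18, 20, 20, 22, 24),
      amplitude = c(0.55, 1.0, 0.5, 0.45, 0.65, 0.6),
      shape = "lorentzian"),
    urine_background = data.frame(
      center = c(525, 680, 1003, 1160, 1440, 1650),
      width = c(120, 90, 30, 110, 140, 120),
      amplitude = c(0.5, 0.45, 0.9, 0.6, 0.8, 0.55),
      shape = c("gaussian", "gaussian", "lorentzian", "gaussian",
                "gaussian", "gaussian"))
  )
  class(lib) <- "sers_band_library"
  lib
}

band_profile <- function(grid, center, width, amplitude, shape) {
  hw <- width / 2
  lor <- amplitude * hw^2 / ((grid - center)^2 + hw^2)
  if (shape == "lorentzian") return(lor)
  gau <- amplitude * exp(-4 * log(2) * (grid - center)^2 / width^2)
  switch(shape,
         gaussian = gau,
         pseudo_voigt = 0.5 * lor + 0.5 * gau,
         stop2("unknown band shape: ", shape))
}

#' Clean reference spectrum of one compound
#'
#' Sums the compound's bands on the instrument grid and min-max normalizes,
#' giving the noise-free unit-concentration spectrum used both as the
#' generator's signal template and as the reference for context matching.
#'
#' @param analyte Name of a library entry.
#' @param lib A band library (default [default_band_library()]).
#' @param grid Wavenumber grid.
#' @return A `sers_spectrum` with state `normalized`.
#' @export
make_reference <- function(analyte, lib = default_band_library(),
                           grid = sers_grid()) {
  if (!analyte %in% names(lib))
    stop2("unknown analyte: ", analyte)
  bands <- lib[[analyte]]
  if (is.null(bands) || nrow(bands) == 0)
    stop2("band library entry for ", analyte, " is empty")
  y <- rowSums(vapply(seq_len(nrow(bands)), function(i)
    band_profile(grid, bands$center[i], bands$width[i], bands$amplitude[i],
                 as.character(bands$shape[i])), numeric(length(grid))))
  spectrum(grid, minmax_normalize(y), state = "normalized")
}

#' Concentration-response model for the generator
#'
#' Describes how analyte concentration maps to spectral amplitude and which
#' nuisance processes corrupt a measurement. The saturating response
#' `amplitude(c) = a_max * c / (k_half + c)` is monotone and bounded by
#' `a_max` — the assay behavior that motivates a logistic calibration output
#' layer in the quantifier. `mode = "linear"` uses the low-concentration
#' tangent `(a_max / k_half) * c` instead, for saturation-free fixtures.
#'
#' Nuisance defaults: per-measurement multiplicative scale jitter is
#' lognormal with sigma 0.1 (drawn independently for the analyte signal and
#' the background, so the signal-to-background ratio varies between
#' measurements and survives per-spectrum normalization); additive Gaussian
#' noise has sd 0.01, i.e. 1% of the unit maximum clean amplitude; a mild
#' low-order polynomial baseline drift is included for the baseline
#' corrector to remove. These levels degrade raw-spectrum quantification
#' while leaving denoised quantification feasible.
#'
#' @param a_max Named amplitude ceilings per analyte.
#' @param k_half Half-saturation concentration, uM.
#' @param mode `"saturating"` or `"linear"`.
#' @param scale_jitter_sigma Lognormal sigma of multiplicative jitter.
#' @param noise_sigma Additive Gaussian noise sd (intensity units).
#' @param baseline_coeffs Polynomial drift coefficients in the unit-scaled
#'   grid coordinate (constant, linear, quadratic, ...).
#' @param background_gain Amplitude of the urine background template added
#'   to urine-medium measurements.
#' @export
response_model <- function(a_max = c(serotonin = 1, dopamine = 1,
                                     epinephrine = 0.9),
                           k_half = 4,
                           mode = c("saturating", "linear"),
                           scale_jitter_sigma = 0.1,
                           noise_sigma = 0.01,
                           baseline_coeffs = c(0.05, 0.08, -0.04),
                           background_gain = 1) {
  mode <- match.arg(mode)
  stopifnot(k_half > 0, scale_jitter_sigma >= 0, noise_sigma >= 0,
            background_gain >= 0)
  structure(list(a_max = a_max, k_half = k_half, mode = mode,
                 scale_jitter_sigma = scale_jitter_sigma,
                 noise_sigma = noise_sigma,
                 baseline_coeffs = baseline_coeffs,
                 background_gain = background_gain),
            class = "sers_response_model")
}

#' Saturating amplitude response
#'
#' @param conc Concentration, uM, >= 0.
#' @param analyte Analyte name (for its `a_max`).
#' @param model A [response_model()].
#' @return Spectral amplitude of the analyte at that concentration.
#' @export
response_amplitude <- function(conc, analyte, model) {
  if (any(conc < 0)) stop2("concentration must be >= 0")
  a <- model$a_max[[analyte]]
  if (is.null(a)) stop2("response model has no a_max for ", analyte)
  if (model$mode == "linear") (a / model$k_half) * conc
  else a * conc / (model$k_half + conc)
}

#' Simulate one SERS mixture measurement
#'
#' Builds `jitter_sig * sum_a amplitude(c_a) * reference_a` plus (for urine
#' medium) an independently jittered urine background template, plus
#' polynomial baseline drift and additive Gaussian noise. The clean signal
#' component is nonnegative by construction; the returned spectrum has state
#' `raw`.
#'
#' @param conc_epi,conc_da,conc_5ht Concentrations, uM, >= 0.
#' @param medium `"water"` or `"urine"`.
#' @param model A [response_model()].
#' @param lib A band library.
#' @param seed Integer seed; the same seed reproduces the measurement
#'   exactly.
#' @param grid Wavenumber grid.
#' @return A `sers_spectrum` with state `raw`.
#' @export
make_mixture <- function(conc_epi, conc_da, conc_5ht,
                         medium = c("water", "urine"),
                         model = response_model(),
                         lib = default_band_library(), seed = 1,
                         grid = sers_grid()) {
  medium <- match.arg(medium)
  if (any(c(conc_epi, conc_da, conc_5ht) < 0))
    stop2("concentrations must be >= 0")
  refs <- reference_matrix(lib, grid)
  conc <- c(epinephrine = conc_epi, dopamine = conc_da, serotonin = conc_5ht)
  clean <- numeric(length(grid))
  for (a in names(conc))
    clean <- clean + response_amplitude(conc[[a]], a, model) * refs[a, ]
  with_seed(seed, {
    j_sig <- exp(stats::rnorm(1, 0, model$scale_jitter_sigma))
    y <- j_sig * clean
    if (medium == "urine") {
      j_bg <- exp(stats::rnorm(1, 0, model$scale_jitter_sigma))
      y <- y + j_bg * model$background_gain * refs["urine_background", ]
    }
    t01 <- (grid - min(grid)) / diff(range(grid))
    drift <- numeric(length(grid))
    for (k in seq_along(model$baseline_coeffs))
      drift <- drift + model$baseline_coeffs[k] * t01^(k - 1)
    y <- y + drift
    if (model$noise_sigma > 0)
      y <- y + stats::rnorm(length(grid), 0, model$noise_sigma)
    spectrum(grid, y, state = "raw")
  })
}

# Cache of normalized reference spectra, analytes + background in rows.
reference_matrix <- function(lib, grid) {
  nms <- names(lib)
  m <- do.call(rbind, lapply(nms, function(a)
    make_reference(a, lib, grid)$intensities))
  rownames(m) <- nms
  m
}

#' Simulate a full labelled dataset from a manifest
#'
#' Generates exactly `n_spectra` measurements per manifest row with that
#' row's concentrations and medium. Targets are the serotonin
#' concentrations; per-spectrum seeds are derived from `seed` by counter so
#' the dataset is reproducible and individual spectra are independent.
#'
#' @param manifest A `sers_manifest`.
#' @param model A [response_model()].
#' @param lib A band library.
#' @param seed Integer master seed.
#' @param grid Wavenumber grid.
#' @return A `sers_dataset` with state `raw`.
#' @export
make_dataset <- function(manifest, model = response_model(),
                         lib = default_band_library(), seed = 1,
                         grid = sers_grid()) {
  manifest <- validate_manifest(manifest)
  total <- sum(manifest$n_spectra)
  X <- matrix(NA_real_, total, length(grid))
  targets <- numeric(total)
  sample_id <- character(total)
  medium <- character(total)
  conc <- matrix(NA_real_, total, 3)
  row <- 0L
  counter <- 0L
  for (i in seq_len(nrow(manifest))) {
    for (k in seq_len(manifest$n_spectra[i])) {
      row <- row + 1L
      counter <- counter + 1L
      s <- make_mixture(manifest$epi_uM[i], manifest$da_uM[i],
                        manifest$ht5_uM[i], manifest$medium[i], model, lib,
                        seed = derive_seed(seed, "mixture", counter),
                        grid = grid)
      X[row, ] <- s$intensities
      targets[row] <- manifest$ht5_uM[i]
      sample_id[row] <- manifest$sample_id[i]
      medium[row] <- manifest$medium[i]
      conc[row, ] <- c(manifest$epi_uM[i], manifest$da_uM[i],
                       manifest$ht5_uM[i])
    }
  }
  labelled_dataset(X, grid, targets, sample_id, medium, state = "raw",
                   concentrations = conc)
}
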