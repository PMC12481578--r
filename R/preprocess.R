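#' ALS baseline parameters
#'
#' Parameters of asymmetric least-squares baseline estimation: the
#' second-difference smoothness weight `lam` (lambda), the asymmetry `p`
#' giving residuals above the baseline a small weight, and the number of
#' reweighting iterations `n_iter`. The defaults (1000, 0.1, 10) are the
#' prespecified values used for every spectrum in the pipeline.
#'
#' @param lam Smoothness weight, > 0.
#' @param p Asymmetry, in (0, 1); values < 0.5 let positive peaks float above
#'   the baseline.
#' @param n_iter Reweighting iterations, >= 1.
#' @export
als_params <- function(lam = 1000, p = 0.1, n_iter = 10) {
  stopifnot(lam > 0, p > 0, p < 1, n_iter >= 1)
  list(lam = lam, p = p, n_iter = as.integer(n_iter))
}

#' Asymmetric least-squares baseline correction
#'
#' Estimates a slowly varying baseline `z` by iteratively reweighted
#' penalized least squares: `z` minimizes
#' `sum_i w_i (y_i - z_i)^2 + lam * sum (diff(z, differences = 2))^2`,
#' starting from unit weights and updating `w_i = p` where `y_i > z_i` and
#' `1 - p` otherwise, for `n_iter` iterations. With `p` well below 0.5 the
#' baseline hugs the lower envelope of the spectrum, so positive Raman peaks
#' survive in `corrected = y - baseline`.
#'
#' The solve uses a sparse banded system (`Matrix`), so cost is linear in
#' spectrum length. Adding a constant to `y` shifts the baseline by the same
#' constant (second differences of a constant vanish).
#'
#' @param y Intensity vector, length >= 3, finite.
#' @param params An [als_params()] list.
#' @return List with `baseline` and `corrected` vectors.
#' @export
als_baseline <- function(y, params = als_params()) {
  assert_finite_vector(y, "y")
  m <- length(y)
  if (m < 3) stop2("als_baseline needs length(y) >= 3")
  D <- Matrix::diff(Matrix::Diagonal(m), differences = 2)
  P <- params$lam * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(params$n_iter)) {
    A <- Matrix::Diagonal(m, w) + P
    z <- as.numeric(Matrix::solve(A, w * y))
    w <- ifelse(y > z, params$p, 1 - params$p)
  }
  list(baseline = z, corrected = y - z)
}

#' Min-max normalization to \[0, 1\]
#'
#' Per-spectrum rescaling `(y - min y) / (max y - min y)`. The scope is
#' deliberately per-spectrum: normalization follows per-spectrum baseline
#' correction and uses no cross-spectrum statistics, which also means the
#' absolute intensity scale of a measurement is not preserved. A constant
#' input has no scale to recover; it returns all zeros with a warning rather
#' than failing, so degenerate spectra do not abort batch runs.
#'
#' @param y Intensity vector.
#' @return Vector with min 0 and max 1 (all zeros if `y` is constant).
#' @export
minmax_normalize <- function(y) {
  assert_finite_vector(y, "y")
  rng <- range(y)
  if (diff(rng) == 0) {
    warning("minmax_normalize: constant input, returning zeros")
    return(rep(0, length(y)))
  }
  (y - rng[1]) / diff(rng)
}

#' Savitzky-Golay parameters
#'
#' Defaults follow the reference-standard derivative preprocessing used as a
#' benchmark: second derivative of a fifth-order polynomial fit in a
#' 33-point window.
#'
#' @param window Odd window length in points.
#' @param polyorder Polynomial order, < window.
#' @param deriv_order Derivative order.
#' @export
sg_params <- function(window = 33, polyorder = 5, deriv_order = 2) {
  if (window %% 2 == 0) stop2("sg window must be odd")
  if (polyorder >= window) stop2("sg polyorder must be < window")
  stopifnot(deriv_order >= 0)
  list(window = as.integer(window), polyorder = as.integer(polyorder),
       deriv_order = as.integer(deriv_order))
}

#' Savitzky-Golay derivative filter
#'
#' Least-squares polynomial smoothing differentiation with respect to sample
#' index (unit spacing). Output length equals input length: edge points use
#' the polynomial fit of the first/last full window rather than truncation,
#' so downstream models keep a fixed input dimension.
#'
#' @param y Intensity vector, `length(y) >= window`.
#' @param params An [sg_params()] list.
#' @return Filtered derivative vector, same length as `y`.
#' @export
sg_derivative <- function(y, params = sg_params()) {
  assert_finite_vector(y, "y")
  if (length(y) < params$window)
    stop2("sg_derivative needs length(y) >= window")
  signal::sgolayfilt(y, p = params$polyorder, n = params$window,
                     m = params$deriv_order, ts = 1)
}

#' Overlay a background measurement onto a clean spectrum
#'
#' Constructs the corrupted member of a denoiser training pair by elementwise
#' addition of a baselined background measurement to a baselined clean
#' spectrum (both pre-normalization, the only scale-coherent stage for
#' addition). A configurable background gain is exposed; the default of 1
#' adds the background as measured.
#'
#' @param clean `sers_spectrum` with state `baselined`.
#' @param background `sers_spectrum` with state `baselined`, same grid.
#' @param gain Multiplier applied to the background before addition.
#' @return A `baselined` `sers_spectrum`.
#' @export
overlay_noise <- function(clean, background, gain = 1) {
  stopifnot(inherits(clean, "sers_spectrum"), inherits(background, "sers_spectrum"))
  if (clean$state != "baselined" || background$state != "baselined")
    stop2("overlay_noise requires baselined spectra (got ", clean$state,
          " + ", background$state, ")")
  if (length(clean$wavenumbers) != length(background$wavenumbers) ||
      max(abs(clean$wavenumbers - background$wavenumbers)) > 1e-8)
    stop2("overlay_noise: wavenumber grids differ")
  spectrum(clean$wavenumbers, clean$intensities + gain * background$intensities,
           state = "baselined")
}

#' Standard preprocessing for a dataset
#'
#' Applies the fixed pipeline order to every spectrum in a dataset:
#' crop to the analysis window, ALS baseline correction, then per-spectrum
#' min-max normalization (optional). Returns the dataset with updated
#' intensities, grid and state.
#'
#' @param ds A `sers_dataset` with state `raw`.
#' @param als [als_params()] list, or `NULL` to skip baseline correction.
#' @param crop Length-2 window in cm^-1, or `NULL` to skip cropping.
#' @param normalize Apply [minmax_normalize()] per spectrum.
#' @return The processed `sers_dataset`.
#' @export
preprocess_dataset <- function(ds, als = als_params(), crop = c(300, 2000),
                               normalize = TRUE) {
  stopifnot(inherits(ds, "sers_dataset"))
  wn <- ds$wavenumbers
  X <- ds$intensities
  if (!is.null(crop)) {
    tol <- 1e-8 * max(abs(c(crop, wn)))
    keep <- wn >= crop[1] - tol & wn <= crop[2] + tol
    if (!any(keep)) stop2("preprocess_dataset: empty crop window")
    wn <- wn[keep]
    X <- X[, keep, drop = FALSE]
  }
  state <- ds$state
  if (!is.null(als)) {
    X <- t(apply(X, 1, function(y) als_baseline(y, als)$corrected))
    state <- "baselined"
  }
  if (normalize) {
    X <- t(apply(X, 1, minmax_normalize))
    state <- "normalized"
  }
  labelled_dataset(X, wn, ds$targets, ds$sample_id, ds$medium, state = state,
                   concentrations = ds$concentrations, split = ds$split)
}
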