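#' Spectrum objects
#'
#' A `sers_spectrum` holds a single Raman/SERS measurement: a strictly
#' increasing wavenumber grid (cm^-1), an intensity vector of equal length,
#' and a processing-state flag tracking the pipeline stage the intensities
#' are in.
#'
#' States form the preprocessing order used throughout the package:
#' `raw` -> (crop) -> `baselined` (after ALS correction) -> `normalized`
#' (min-max to \[0, 1\]) -> `denoised` (autoencoder output). `sg_derivative`
#' marks Savitzky-Golay derivative processing used for benchmarking.
#'
#' @param wavenumbers Numeric vector, cm^-1, strictly increasing.
#' @param intensities Numeric vector, same length as `wavenumbers`.
#' @param state Processing state flag.
#' @return An object of class `sers_spectrum`.
#' @export
spectrum <- function(wavenumbers, intensities,
                     state = c("raw", "baselined", "normalized",
                               "sg_derivative", "denoised")) {
  state <- match.arg(state)
  assert_finite_vector(wavenumbers, "wavenumbers")
  if (!is.numeric(intensities)) stop2("intensities must be numeric")
  if (length(wavenumbers) != length(intensities))
    stop2("wavenumbers and intensities must have equal length (",
          length(wavenumbers), " vs ", length(intensities), ")")
  if (is.unsorted(wavenumbers, strictly = TRUE))
    stop2("wavenumbers must be strictly increasing")
  if (state %in% c("normalized", "denoised")) {
    eps <- 1e-9
    if (min(intensities) < -eps || max(intensities) > 1 + eps)
      stop2("state=", state, " requires intensities in [0, 1]")
  }
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities),
                 state = state),
            class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %d points, %.1f-%.1f cm^-1, state=%s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$state))
  invisible(x)
}

#' Instrument wavenumber grid
#'
#' The default acquisition grid used by the synthetic-data generator and all
#' fixtures: 937 uniformly spaced points with spacing 1700/841 cm^-1, laid out
#' so that exactly 842 points fall in the analysis window \[300, 2000\] cm^-1
#' (the first in-window point is exactly 300.0 and the last exactly 2000.0);
#' the remaining 95 points extend below 300 cm^-1, as spectrometers typically
#' record from ~100 cm^-1.
#'
#' @return Numeric vector of length 937.
#' @export
sers_grid <- function() {
  delta <- 1700 / 841
  300 + (-95:841) * delta
}

#' Crop a spectrum to a wavenumber window
#'
#' Keeps grid points with `lo <= wavenumber <= hi` (closed interval, with a
#' tiny relative tolerance so that window edges laid exactly on grid points
#' are retained under floating-point rounding). Order is preserved and the
#' processing state is unchanged. Cropping is idempotent.
#'
#' @param s A `sers_spectrum`.
#' @param lo,hi Window edges in cm^-1, `lo < hi`.
#' @return The cropped `sers_spectrum`.
#' @export
crop_range <- function(s, lo = 300, hi = 2000) {
  stopifnot(inherits(s, "sers_spectrum"))
  if (!(lo < hi)) stop2("crop_range: lo must be < hi")
  tol <- 1e-8 * max(abs(c(lo, hi, s$wavenumbers)))
  keep <- s$wavenumbers >= lo - tol & s$wavenumbers <= hi + tol
  if (!any(keep)) stop2("crop_range: no grid points in [", lo, ", ", hi, "]")
  spectrum(s$wavenumbers[keep], s$intensities[keep], state = s$state)
}

#' Read spectra from disk
#'
#' Two container forms are supported. `delimited_table` is the canonical
#' plain-text form: a header row `wavenumber,<id1>,<id2>,...` followed by one
#' row per grid point; every non-header cell must parse as a number.
#' `matrix_container` is an RDS file holding a list with elements
#' `wavenumbers`, `intensities` (spectra in rows), `ids` and `state`,
#' intended for large intermediate artifacts.
#'
#' Rows are sorted by wavenumber if needed; duplicate wavenumbers are an
#' error.
#'
#' @param path File path.
#' @param format `"delimited_table"` or `"matrix_container"`.
#' @return A list of `sers_spectrum` objects, named by column id.
#' @export
read_spectra <- function(path, format = c("delimited_table", "matrix_container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "matrix_container") {
    obj <- readRDS(path)
    sp <- lapply(seq_len(nrow(obj$intensities)), function(i)
      spectrum(obj$wavenumbers, obj$intensities[i, ], state = obj$state %||% "raw"))
    names(sp) <- obj$ids
    return(sp)
  }
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop2("delimited spectrum table needs a wavenumber column plus >= 1 spectrum")
  num <- matrix(NA_real_, nrow(tab), ncol(tab))
  for (j in seq_len(ncol(tab))) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) & !is.na(tab[[j]]))
    if (length(bad))
      stop2("parse error in ", basename(path), ": non-numeric value ",
            dQuote(tab[[j]][bad[1]]), " at row ", bad[1] + 1L,
            ", column ", dQuote(names(tab)[j]))
    num[, j] <- v
  }
  ord <- order(num[, 1])
  num <- num[ord, , drop = FALSE]
  if (anyDuplicated(num[, 1]))
    stop2("duplicate wavenumbers in ", basename(path))
  sp <- lapply(2:ncol(tab), function(j) spectrum(num[, 1], num[, j], state = "raw"))
  names(sp) <- names(tab)[-1]
  sp
}

#' Write spectra to disk
#'
#' Inverse of [read_spectra()]. All spectra must share one wavenumber grid.
#'
#' @param spectra List of `sers_spectrum`; names become column ids.
#' @param path Output path.
#' @param format See [read_spectra()].
#' @export
write_spectra <- function(spectra, path,
                          format = c("delimited_table", "matrix_container")) {
  format <- match.arg(format)
  stopifnot(length(spectra) >= 1)
  wn <- spectra[[1]]$wavenumbers
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavenumbers, wn)))
      stop2("write_spectra: spectra must share one wavenumber grid")
  ids <- names(spectra) %||% paste0("s", seq_along(spectra))
  if (format == "matrix_container") {
    m <- do.call(rbind, lapply(spectra, function(s) s$intensities))
    saveRDS(list(wavenumbers = wn, intensities = m, ids = ids,
                 state = spectra[[1]]$state), path)
    return(invisible(path))
  }
  tab <- data.frame(wavenumber = wn, check.names = FALSE)
  for (i in seq_along(spectra)) tab[[ids[i]]] <- spectra[[i]]$intensities
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
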