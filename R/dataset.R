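#' Labelled spectral datasets
#'
#' A `sers_dataset` is the matrix-backed container used by every training
#' stage: spectra in rows on a shared wavenumber grid, with parallel vectors
#' of serotonin targets (micromolar), sample ids, media, and (once assigned)
#' split membership. The per-sample added concentrations of all three
#' analytes are carried alongside for bookkeeping and explainability.
#'
#' @param intensities Numeric matrix, one spectrum per row.
#' @param wavenumbers Shared grid, length `ncol(intensities)`.
#' @param targets Serotonin concentration per spectrum, uM.
#' @param sample_id Character vector of sample labels.
#' @param medium Character vector, `"water"`/`"urine"`.
#' @param state Processing state shared by all rows (see [spectrum()]).
#' @param concentrations Optional n x 3 matrix (epi, da, ht5) per spectrum.
#' @param split Optional character vector in
#'   `c("train", "validation", "test")`.
#' @return A `sers_dataset` object.
#' @export
labelled_dataset <- function(intensities, wavenumbers, targets, sample_id,
                             medium, state = "raw", concentrations = NULL,
                             split = NULL) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  if (length(wavenumbers) != ncol(intensities))
    stop2("wavenumbers length must match ncol(intensities)")
  for (nm in c("targets", "sample_id", "medium")) {
    v <- get(nm)
    if (length(v) != n) stop2(nm, " must have one entry per spectrum")
  }
  if (!is.null(split)) {
    if (length(split) != n) stop2("split must have one entry per spectrum")
    if (!all(split %in% c("train", "validation", "test")))
      stop2("split values must be train/validation/test")
  }
  if (!is.null(concentrations)) {
    concentrations <- as.matrix(concentrations)
    stopifnot(nrow(concentrations) == n, ncol(concentrations) == 3)
    colnames(concentrations) <- c("epi_uM", "da_uM", "ht5_uM")
  }
  structure(list(intensities = intensities,
                 wavenumbers = as.numeric(wavenumbers),
                 targets = as.numeric(targets),
                 sample_id = as.character(sample_id),
                 medium = as.character(medium),
                 state = state,
                 concentrations = concentrations,
                 split = split),
            class = "sers_dataset")
}

#' @export
print.sers_dataset <- function(x, ...) {
  cat(sprintf("<sers_dataset> %d spectra x %d points, state=%s\n",
              nrow(x$intensities), ncol(x$intensities), x$state))
  if (!is.null(x$split)) print(table(split = x$split))
  invisible(x)
}

#' Number of spectra in a dataset
#' @param ds A `sers_dataset`.
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Subset a dataset by row index or split label
#'
#' @param ds A `sers_dataset`.
#' @param idx Integer/logical row index, or one of `"train"`,
#'   `"validation"`, `"test"` to take that split.
#' @export
ds_subset <- function(ds, idx) {
  if (is.character(idx) && length(idx) == 1 &&
      idx %in% c("train", "validation", "test")) {
    if (is.null(ds$split)) stop2("dataset has no split assignment")
    idx <- which(ds$split == idx)
  }
  labelled_dataset(ds$intensities[idx, , drop = FALSE], ds$wavenumbers,
                   ds$targets[idx], ds$sample_id[idx], ds$medium[idx],
                   state = ds$state,
                   concentrations = if (!is.null(ds$concentrations))
                     ds$concentrations[idx, , drop = FALSE],
                   split = if (!is.null(ds$split)) ds$split[idx])
}

#' Assign train/validation/test membership from a manifest
#'
#' Spectra from `held_out_test` samples go exclusively to the test set and
#' spectra from `held_out_validation` samples go to the validation set.
#' Spectra from `repeat` samples are shuffled with `seed` and split
#' train:validation, with the validation count taken as
#' `ceiling(val_fraction * n_repeat)` — the rounding rule that, on the
#' built-in urine design (318 spectra, 243 of them repeats), yields the
#' protocol's 218/46/54 train/validation/test partition.
#'
#' @param ds A `sers_dataset`.
#' @param manifest A `sers_manifest` covering every (sample_id, medium) in
#'   `ds`.
#' @param val_fraction Fraction of repeat spectra routed to validation,
#'   in (0, 1).
#' @param seed Integer seed for the repeat-spectrum shuffle.
#' @return `ds` with its `split` field populated.
#' @export
split_dataset <- function(ds, manifest, val_fraction = 0.1, seed = 1) {
  manifest <- validate_manifest(manifest)
  if (!(val_fraction > 0 && val_fraction < 1))
    stop2("val_fraction must be in (0, 1)")
  key <- paste(ds$sample_id, ds$medium)
  mkey <- paste(manifest$sample_id, manifest$medium)
  if (!all(key %in% mkey)) {
    bad <- unique(key[!key %in% mkey])
    stop2("sample ids absent from manifest: ", paste(bad, collapse = ", "))
  }
  role <- manifest$split_role[match(key, mkey)]
  split <- rep(NA_character_, length(role))
  split[role == "held_out_test"] <- "test"
  split[role == "held_out_validation"] <- "validation"
  rep_idx <- which(role == "repeat")
  n_val <- ceiling(val_fraction * length(rep_idx))
  shuffled <- with_seed(derive_seed(seed, "split"), sample(rep_idx))
  split[shuffled[seq_len(n_val)]] <- "validation"
  split[shuffled[-seq_len(n_val)]] <- "train"
  ds$split <- split
  ds
}

# Convert a list of sers_spectrum sharing a grid into a bare matrix.
spectra_matrix <- function(spectra) {
  do.call(rbind, lapply(spectra, function(s) s$intensities))
}
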