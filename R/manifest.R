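#' Sample manifests
#'
#' A manifest row describes one measured sample in one medium: the spiked
#' neurotransmitter concentrations (micromolar), how many repeat spectra were
#' acquired, and the role the sample plays in the train/validation/test
#' protocol. Samples whose measurements may appear in training are `repeat`
#' samples; `held_out_validation` samples contribute all of their spectra to
#' the validation set, and `held_out_test` samples appear exclusively in the
#' test set.
#'
#' @param sample_id Character labels.
#' @param epi_uM,da_uM,ht5_uM Added epinephrine / dopamine / serotonin
#'   concentrations, micromolar, non-negative.
#' @param medium `"water"` or `"urine"`.
#' @param n_spectra Integer counts, >= 0.
#' @param split_role `"repeat"`, `"held_out_validation"` or `"held_out_test"`.
#' @return A `data.frame` with class `sers_manifest`.
#' @export
sample_manifest <- function(sample_id, epi_uM, da_uM, ht5_uM, medium,
                            n_spectra, split_role = "repeat") {
  m <- data.frame(sample_id = as.character(sample_id),
                  epi_uM = as.numeric(epi_uM), da_uM = as.numeric(da_uM),
                  ht5_uM = as.numeric(ht5_uM),
                  medium = as.character(medium),
                  n_spectra = as.integer(n_spectra),
                  split_role = as.character(split_role),
                  stringsAsFactors = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  stopifnot(is.data.frame(m))
  need <- c("sample_id", "epi_uM", "da_uM", "ht5_uM", "medium", "n_spectra",
            "split_role")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop2("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (any(m$epi_uM < 0 | m$da_uM < 0 | m$ht5_uM < 0))
    stop2("manifest concentrations must be >= 0")
  if (!all(m$medium %in% c("water", "urine")))
    stop2("manifest medium must be 'water' or 'urine'")
  if (any(m$n_spectra < 0)) stop2("manifest n_spectra must be >= 0")
  if (!all(m$split_role %in% c("repeat", "held_out_validation", "held_out_test")))
    stop2("invalid split_role in manifest")
  if (anyDuplicated(m[c("sample_id", "medium")]))
    stop2("duplicate (sample_id, medium) rows in manifest")
  class(m) <- unique(c("sers_manifest", class(m)))
  m
}

#' The neurotransmitter study design manifest
#'
#' The built-in fixture manifest of the serotonin quantification study this
#' package models: samples A-M plus a background sample U, each spiked with
#' epinephrine (EPI), dopamine (DA) and serotonin (5-HT) at 0-9 uM and
#' measured repeatedly in water and/or lyophilized-urine medium. Urine rows
#' total 318 spectra and water rows 364 (682 in all). Samples D and E are the
#' held-out test samples, F is the held-out validation sample, and all other
#' samples are repeat samples; sample U is the analyte-free background pool
#' used to train the denoiser.
#'
#' The design is deliberately confounded: every serotonin-free sample (A, B,
#' F, U) carries either another neurotransmitter or pure background, so a
#' quantifier can learn to use dopamine/epinephrine presence as a proxy for
#' serotonin absence — the failure mode the context-explainability stage is
#' designed to expose.
#'
#' @param medium `"both"`, `"urine"` or `"water"`: which rows to return.
#' @return A `sers_manifest` data frame.
#' @export
study_manifest <- function(medium = c("both", "urine", "water")) {
  medium <- match.arg(medium)
  ids <- LETTERS[1:13]
  epi <- c(2, 0, 0, 3, 0, 7, 3, 1, 2, 6, 7, 9, 3)
  da  <- c(0, 2, 0, 0, 8, 3, 2, 1, 8, 9, 3, 6, 3)
  ht5 <- c(0, 0, 2, 7, 3, 0, 7, 9, 3, 1, 2, 4, 3)
  n_water <- c(25, 17, 22, 0, 0, 0, 41, 38, 37, 93, 11, 11, 11)
  n_urine <- c(22, 21, 22, 26, 28, 21, 26, 22, 22, 23, 23, 21, 0)
  role <- rep("repeat", 13)
  role[ids %in% c("D", "E")] <- "held_out_test"
  role[ids == "F"] <- "held_out_validation"
  urine <- sample_manifest(c(ids, "U"), c(epi, 0), c(da, 0), c(ht5, 0),
                           "urine", c(n_urine, 41), c(role, "repeat"))
  water <- sample_manifest(c(ids, "U"), c(epi, 0), c(da, 0), c(ht5, 0),
                           "water", c(n_water, 58), rep("repeat", 14))
  urine <- urine[urine$n_spectra > 0, ]
  water <- water[water$n_spectra > 0, ]
  out <- switch(medium, both = rbind(urine, water), urine = urine, water = water)
  rownames(out) <- NULL
  validate_manifest(out)
}
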