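#' Load and validate a pipeline run configuration
#'
#' The run configuration is a YAML file with optional sections
#' `manifest` (path to a manifest CSV; the built-in study design is used
#' when absent), `bands` (path to a band-library YAML; defaults built in),
#' `response` (generator settings), `preprocess` (`als`, `crop`,
#' `normalize`), `dae` (denoiser settings), `quantify` (`kind`, protocol
#' fields, `upper_init`), `crime` (`k`, `n_samples`, `segment_width`),
#' `benchmark` (`enabled`), `perturbation` (`levels`), plus a master
#' `seed` and an output directory `out_dir`. Every stage derives its own
#' seed from the master seed, so one seed reproduces the whole run.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "sers_run"
  if (!is.null(cfg$manifest) && !file.exists(cfg$manifest))
    stop2("manifest file not found: ", cfg$manifest)
  if (!is.null(cfg$bands) && !file.exists(cfg$bands))
    stop2("band library file not found: ", cfg$bands)
  cfg
}

#' Read a manifest from a delimited file
#'
#' Columns: sample_id, epi_uM, da_uM, ht5_uM, medium, n_spectra,
#' split_role.
#'
#' @param path CSV path.
#' @export
read_manifest <- function(path) {
  validate_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a band library from YAML
#'
#' Top-level keys are compound names; each holds parallel lists
#' `center`, `width`, `amplitude` and `shape`.
#'
#' @param path YAML path.
#' @export
read_band_library <- function(path) {
  raw <- yaml::read_yaml(path)
  lib <- lapply(raw, function(b)
    data.frame(center = as.numeric(b$center), width = as.numeric(b$width),
               amplitude = as.numeric(b$amplitude),
               shape = as.character(b$shape)))
  class(lib) <- "sers_band_library"
  lib
}

log_stage <- function(log_path, stage, seed, t0, extra = NULL) {
  rec <- c(list(stage = stage, seed = seed,
                elapsed_s = round(as.numeric(proc.time()[3] - t0), 2)),
           extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full framework end-to-end
#'
#' Executes simulate -> preprocess -> denoiser training -> denoising ->
#' quantifier ensemble training -> evaluation -> context explainability ->
#' (optional) classical benchmarks and perturbation testing, writing every
#' stage's outputs, a machine-readable `metrics.json`, and a structured
#' `log.jsonl` with stage seeds and timings into the run directory. A
#' stage failure halts the pipeline with a stage-named error; outputs of
#' completed stages are retained.
#'
#' @param config A config list from [run_config()] (or an equivalent list).
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  seed <- config$seed
  metrics <- list(schema_version = 1L, seed = seed)

  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop2("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
    log_stage(log_path, stage, derive_seed(seed, stage), t0)
    res
  }

  manifest <- if (!is.null(config$manifest)) read_manifest(config$manifest)
              else study_manifest("both")
  lib <- if (!is.null(config$bands)) read_band_library(config$bands)
         else default_band_library()
  rm_args <- config$response %||% list()
  model_resp <- do.call(response_model, rm_args)

  # simulate
  ds <- run_stage("simulate", {
    d <- make_dataset(manifest, model_resp, lib,
                      seed = derive_seed(seed, "simulate"))
    write_spectra_matrix(d, file.path(out, "raw_spectra.rds"))
    d
  })

  # preprocess: baseline-correct on the full grid (denoiser input), crop
  # for quantification
  pp <- config$preprocess %||% list()
  crop <- pp$crop %||% c(300, 2000)
  als <- do.call(als_params, pp$als %||% list())
  prep <- run_stage("preprocess", {
    full_norm <- preprocess_dataset(ds, als = als, crop = NULL,
                                    normalize = TRUE)
    full_base <- preprocess_dataset(ds, als = als, crop = NULL,
                                    normalize = FALSE)
    list(full_norm = full_norm, full_base = full_base)
  })

  # denoiser: water-medium spectra as clean pool, background sample as noise
  dae_cfg_args <- config$dae %||% list()
  dae <- run_stage("train_dae", {
    water <- ds_subset(prep$full_base, which(prep$full_base$medium == "water"))
    bg <- ds_subset(prep$full_base, which(prep$full_base$sample_id == "U" &
                                            prep$full_base$medium == "urine"))
    if (n_spectra(bg) == 0)
      bg <- ds_subset(prep$full_base, which(prep$full_base$sample_id == "U"))
    pairs <- build_noisy_pairs(water$intensities, bg$intensities,
                               seed = derive_seed(seed, "pairs"))
    cfg <- do.call(dae_config, c(list(input_dim = ncol(water$intensities)),
                                 dae_cfg_args))
    train_dae(pairs, cfg, seed = derive_seed(seed, "dae"))
  })
  metrics$dae_test_mse <- dae$test_mse

  # denoise the urine spectra, then crop both raw-normalized and denoised
  qcfg <- config$quantify %||% list()
  urine_idx <- which(prep$full_norm$medium == "urine")
  urine_norm <- ds_subset(prep$full_norm, urine_idx)
  denoised <- run_stage("denoise", denoise(dae, urine_norm))
  crop_ds <- function(d) {
    tol <- 1e-8 * max(abs(c(crop, d$wavenumbers)))
    keep <- d$wavenumbers >= crop[1] - tol & d$wavenumbers <= crop[2] + tol
    d$intensities <- d$intensities[, keep, drop = FALSE]
    d$wavenumbers <- d$wavenumbers[keep]
    d
  }
  urine_raw_c <- crop_ds(urine_norm)
  urine_den_c <- crop_ds(denoised)
  urine_manifest <- manifest[manifest$medium == "urine", ]
  urine_raw_c <- split_dataset(urine_raw_c, urine_manifest,
                               seed = derive_seed(seed, "split"))
  urine_den_c$split <- urine_raw_c$split

  # quantifier ensemble on denoised spectra
  protocol <- do.call(train_protocol,
                      qcfg[intersect(names(qcfg),
                                     names(formals(train_protocol)))])
  kind <- qcfg$kind %||% "cnn_3pl"
  ens <- run_stage("train_quant", {
    train_ensemble(kind, ds_subset(urine_den_c, "train"),
                   ds_subset(urine_den_c, "validation"), protocol,
                   seed = derive_seed(seed, "quant"),
                   upper_init = qcfg$upper_init %||% 10)
  })
  test_den <- ds_subset(urine_den_c, "test")
  ev <- run_stage("evaluate", {
    if (!ens$converged) stop2("no ensemble member survived the MAE cutoff")
    evaluate(predict_quant(ens$selected, test_den), test_den$targets)
  })
  metrics$quant_kind <- kind
  metrics$quant_test_mae_uM <- ev$mae
  metrics$quant_test_mse <- ev$mse
  metrics$quant_test_mpe_pct <- ev$mpe
  metrics$ensemble_surviving <- sum(ens$surviving)

  # context explainability on the denoised urine spectra
  ccfg <- config$crime %||% list()
  refs <- reference_matrix(lib, ds$wavenumbers)
  refs_c <- refs[setdiff(rownames(refs), "urine_background"), , drop = FALSE]
  tolc <- 1e-8 * max(abs(c(crop, ds$wavenumbers)))
  keepc <- ds$wavenumbers >= crop[1] - tolc & ds$wavenumbers <= crop[2] + tolc
  cr <- run_stage("explain", {
    crime(ens$selected, urine_den_c, refs_c[, keepc, drop = FALSE],
          k = ccfg$k %||% "auto",
          segment_width = ccfg$segment_width %||% 25,
          n_samples = ccfg$n_samples %||% 200,
          seed = derive_seed(seed, "crime"))
  })
  ctx_tab <- do.call(rbind, lapply(cr$contexts, function(ctx)
    data.frame(context = ctx$context_id, n_members = ctx$n_members,
               top_match = ctx$matches$analyte[1],
               cosine = ctx$matches$cosine[1])))
  utils::write.csv(ctx_tab, file.path(out, "contexts.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(latent1 = cr$latent[, 1],
                              latent2 = cr$latent[, 2],
                              context = cr$labels),
                   file.path(out, "latent.csv"), row.names = FALSE)
  tryCatch(crime_latent_plot(cr, file.path(out, "latent.png")),
           error = function(e) NULL)
  metrics$n_contexts <- length(cr$contexts)
  metrics$context_top_matches <- ctx_tab$top_match

  # optional classical benchmarks
  if (isTRUE((config$benchmark %||% list())$enabled)) {
    bench <- run_stage("benchmark", {
      run_benchmarks(ds_subset(urine_den_c, "train"), test_den,
                     seed = derive_seed(seed, "bench"))
    })
    utils::write.csv(bench, file.path(out, "benchmarks.csv"),
                     row.names = FALSE)
    metrics$benchmark_best_classical_mae <- min(bench$mae, na.rm = TRUE)
  }

  # optional perturbation testing
  pcfg <- config$perturbation %||% list()
  if (!isFALSE(pcfg$enabled %||% TRUE)) {
    pt <- run_stage("perturb", {
      plan <- perturbation_plan(pcfg$levels %||% c(0.05, 0.1, 0.2, 0.3),
                                seed = derive_seed(seed, "perturb"))
      perturbation_test(ens$selected, test_den, plan)
    })
    utils::write.csv(pt, file.path(out, "perturbation.csv"),
                     row.names = FALSE)
    metrics$perturbation_mae <- pt$mae
  }

  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

write_spectra_matrix <- function(ds, path) {
  saveRDS(list(wavenumbers = ds$wavenumbers, intensities = ds$intensities,
               ids = ds$sample_id, state = ds$state, targets = ds$targets,
               medium = ds$medium), path)
}
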