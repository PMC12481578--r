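#' Benchmark hyperparameter grids
#'
#' Candidate grids for the classical model families compared against the
#' neural quantifiers, searched by 3-fold cross-validation. The defaults
#' are modest, documented grids: PLSR component count, random-forest size
#' and feature sampling, RBF-SVM cost and kernel width, and gradient
#' boosting depth/learning rate.
#'
#' @param plsr,rf,svm,xgb Named lists of candidate parameter vectors.
#' @param cv_folds Number of cross-validation folds.
#' @export
benchmark_grid <- function(plsr = list(ncomp = c(2, 5, 10, 15, 20)),
                           rf = list(ntree = c(200, 500),
                                     mtry_frac = c(0.05, 0.2)),
                           svm = list(cost = c(1, 10, 100),
                                      gamma = c(1e-4, 1e-3, 1e-2)),
                           xgb = list(max_depth = c(3, 6),
                                      eta = c(0.1, 0.3),
                                      nrounds = 150),
                           cv_folds = 3) {
  lapply(list(plsr = plsr, rf = rf, svm = svm, xgb = xgb), function(g)
    if (length(g) == 0) stop2("benchmark grids must be non-empty") else g)
  list(plsr = plsr, rf = rf, svm = svm, xgb = xgb,
       cv_folds = as.integer(cv_folds))
}

fit_family <- function(family, pars, x, y, seed) {
  if (stats::sd(y) < 1e-12) {
    # constant target: every family's limit is the intercept-only model
    # (and several fitters reject a zero-variance response outright)
    return(structure(list(mean = mean(y)), class = "const_model"))
  }
  switch(family,
    plsr = {
      # components cannot exceed the effective rank of the centered data
      # (noiseless low-rank spectra would otherwise give singular loadings)
      rk <- qr(scale(x, center = TRUE, scale = FALSE))$rank
      nc <- max(1, min(pars$ncomp, rk, ncol(x) - 1, nrow(x) - 1))
      colnames(x) <- paste0("v", seq_len(ncol(x)))
      mixOmics::pls(x, y, ncomp = nc, mode = "regression")
    },
    rf = {
      mtry <- max(1, floor(pars$mtry_frac * ncol(x)))
      with_seed(seed, randomForest::randomForest(x, y, ntree = pars$ntree,
                                                 mtry = mtry))
    },
    svm = e1071::svm(x, y, cost = pars$cost, gamma = pars$gamma,
                     type = "eps-regression", kernel = "radial"),
    xgb = with_seed(seed, {
      xgboost::xgboost(x, y, nrounds = pars$nrounds,
                       max_depth = pars$max_depth,
                       learning_rate = pars$eta,
                       objective = "reg:squarederror", verbosity = 0,
                       nthreads = 1, seed = seed %% 100000L)
    }),
    stop2("unknown model family: ", family))
}

predict_family <- function(family, fit, x) {
  if (inherits(fit, "const_model")) return(rep(fit$mean, nrow(x)))
  switch(family,
    plsr = {
      colnames(x) <- paste0("v", seq_len(ncol(x)))
      pr <- stats::predict(fit, x)
      as.numeric(pr$predict[, 1, dim(pr$predict)[3]])
    },
    rf = as.numeric(stats::predict(fit, x)),
    svm = as.numeric(stats::predict(fit, x)),
    xgb = as.numeric(stats::predict(fit, x)))
}

expand_pars <- function(grid_family) {
  do.call(expand.grid, c(grid_family, list(stringsAsFactors = FALSE)))
}

#' Classical-model benchmarks with grid-search cross-validation
#'
#' For each family (PLSR, random forest, SVM, XGBoost): every grid point is
#' scored by `cv_folds`-fold cross-validated MAE on the training set, the
#' best configuration is refit on the full training set, and test-set MAE,
#' MSE and MPE are reported. A family whose fit fails on degenerate data is
#' reported as a failure row rather than aborting the table.
#'
#' @param train,test `sers_dataset`s.
#' @param grid A [benchmark_grid()].
#' @param seed Integer seed (fold assignment, stochastic fits).
#' @param families Model families to run (default all four).
#' @return Data frame with one row per family: best parameters (as a
#'   string), test `mae`, `mse`, `mpe`, and `ok`.
#' @export
run_benchmarks <- function(train, test, grid = benchmark_grid(), seed = 1,
                           families = c("plsr", "rf", "svm", "xgb")) {
  xtr <- train$intensities; ytr <- train$targets
  xte <- test$intensities; yte <- test$targets
  n <- nrow(xtr)
  folds <- with_seed(derive_seed(seed, "folds"),
                     sample(rep_len(seq_len(grid$cv_folds), n)))
  rows <- lapply(families, function(family) {
    pars_tab <- expand_pars(grid[[family]])
    res <- tryCatch({
      cv_mae <- vapply(seq_len(nrow(pars_tab)), function(gi) {
        pars <- as.list(pars_tab[gi, , drop = FALSE])
        errs <- vapply(seq_len(grid$cv_folds), function(f) {
          tr <- folds != f
          fit <- fit_family(family, pars, xtr[tr, , drop = FALSE], ytr[tr],
                            derive_seed(seed, family, gi, f))
          mean(abs(predict_family(family, fit, xtr[!tr, , drop = FALSE]) -
                     ytr[!tr]))
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- which.min(cv_mae)
      pars <- as.list(pars_tab[best, , drop = FALSE])
      fit <- fit_family(family, pars, xtr, ytr,
                        derive_seed(seed, family, "final"))
      ev <- evaluate(predict_family(family, fit, xte), yte)
      data.frame(family = family,
                 params = paste(names(pars), unlist(pars), sep = "=",
                                collapse = ","),
                 mae = ev$mae, mse = ev$mse, mpe = ev$mpe, ok = TRUE,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(family = family, params = NA_character_, mae = NA_real_,
                 mse = NA_real_, mpe = NA_real_, ok = FALSE,
                 stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, rows)
}

#' Gaussian perturbation robustness plan
#'
#' Noise levels are fractions of each spectrum's maximum intensity (the
#' reference scale for "X% noise"). `universal` mode perturbs every
#' position; `localized` mode perturbs only the supplied index regions
#' (typically the context-explainability top regions), testing whether the
#' model can compensate from neighboring unperturbed regions.
#'
#' @param noise_levels Fractions in (0, 1].
#' @param mode `"universal"` or `"localized"`.
#' @param regions Two-column (start, end) index matrix for localized mode.
#' @param mae_cutoff Robustness pass threshold, uM.
#' @param seed Integer seed.
#' @export
perturbation_plan <- function(noise_levels = c(0.05, 0.10, 0.20, 0.30),
                              mode = c("universal", "localized"),
                              regions = NULL, mae_cutoff = 0.5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(noise_levels >= 0), all(noise_levels <= 1))
  if (mode == "localized" && is.null(regions))
    stop2("localized perturbation requires regions")
  list(noise_levels = noise_levels, mode = mode, regions = regions,
       mae_cutoff = mae_cutoff, seed = seed)
}

#' Perturbation robustness test
#'
#' Adds Gaussian noise with per-spectrum sd `level * max(intensity)` to the
#' test spectra at each plan level (level 0 leaves the spectra untouched,
#' reproducing the unperturbed MAE exactly) and reports the resulting MAE
#' and pass/fail against the plan's cutoff.
#'
#' @param model A trained `sers_quant`.
#' @param test A `sers_dataset`.
#' @param plan A [perturbation_plan()].
#' @return Data frame (level, mode, mae, pass).
#' @export
perturbation_test <- function(model, test, plan = perturbation_plan()) {
  x <- test$intensities
  scale_per_spec <- apply(x, 1, max)
  rows <- lapply(seq_along(plan$noise_levels), function(li) {
    level <- plan$noise_levels[li]
    xp <- x
    if (level > 0) {
      noise <- with_seed(derive_seed(plan$seed, "perturb", li), {
        nz <- matrix(stats::rnorm(length(x)), nrow(x)) *
          (level * scale_per_spec)
        if (plan$mode == "localized") {
          mask <- matrix(0, nrow(x), ncol(x))
          for (r in seq_len(nrow(plan$regions)))
            mask[, plan$regions[r, 1]:plan$regions[r, 2]] <- 1
          nz * mask
        } else nz
      })
      xp <- x + noise
    }
    mae <- mean(abs(as.numeric(predict_quant(model, xp)) - test$targets))
    data.frame(level = level, mode = plan$mode, mae = mae,
               pass = mae < plan$mae_cutoff)
  })
  do.call(rbind, rows)
}
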