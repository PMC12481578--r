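#' Denoising autoencoder configuration
#'
#' A fully connected encoder-decoder that reconstructs clean, normalized
#' spectra from background-corrupted inputs. The encoder has a 2 x 200 = 400
#' unit ReLU layer followed by compression into a 200-dimensional encoding
#' space (ReLU); the decoder mirrors it (400-unit ReLU, then reconstruction
#' to the full input dimension through a sigmoid, so outputs always lie in
#' \[0, 1\]). Trained with mean squared error and a Nadam optimizer for 128
#' epochs at batch size 32, on an 80:20 train/test split of the noisy/clean
#' pairs.
#'
#' @param input_dim Spectrum length (937 on the default grid).
#' @param encoder_widths Encoder layer widths, last entry = latent size.
#' @param epochs,batch_size,learning_rate Training schedule.
#' @param train_fraction Fraction of pairs used for training.
#' @export
dae_config <- function(input_dim = 937, encoder_widths = c(400, 200),
                       epochs = 128, batch_size = 32, learning_rate = 1e-3,
                       train_fraction = 0.8) {
  stopifnot(input_dim >= 1, length(encoder_widths) >= 1,
            train_fraction > 0, train_fraction < 1)
  list(input_dim = as.integer(input_dim),
       encoder_widths = as.integer(encoder_widths),
       decoder_widths = as.integer(c(rev(encoder_widths)[-1], input_dim)),
       epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, train_fraction = train_fraction)
}

#' Build noisy/clean training pairs
#'
#' Pairs every clean (baselined, pre-normalization) spectrum with itself
#' plus a randomly selected baselined background measurement, then min-max
#' normalizes both members of each pair. Pairs are split train:test with
#' `train_fraction`, taking the test count as the ceiling of the held-out
#' fraction (364 pairs split 80:20 gives 291 train / 73 test).
#'
#' @param clean Matrix of baselined clean spectra (rows).
#' @param backgrounds Matrix of baselined background measurements (rows),
#'   same grid.
#' @param seed Integer seed controlling background selection and the split.
#' @param train_fraction Fraction of pairs assigned to training.
#' @return List with `x_train`, `y_train`, `x_test`, `y_test` (noisy inputs
#'   `x`, clean targets `y`), plus the background assignment.
#' @export
build_noisy_pairs <- function(clean, backgrounds, seed = 1,
                              train_fraction = 0.8) {
  clean <- as.matrix(clean)
  backgrounds <- as.matrix(backgrounds)
  if (nrow(backgrounds) < 1) stop2("background pool is empty")
  if (ncol(clean) != ncol(backgrounds))
    stop2("clean and background grids differ (", ncol(clean), " vs ",
          ncol(backgrounds), ")")
  n <- nrow(clean)
  with_seed(derive_seed(seed, "pairs"), {
    pick <- sample.int(nrow(backgrounds), n, replace = TRUE)
    noisy <- clean + backgrounds[pick, , drop = FALSE]
    x <- t(apply(noisy, 1, minmax_normalize))
    y <- t(apply(clean, 1, minmax_normalize))
    n_test <- ceiling((1 - train_fraction) * n)
    ord <- sample.int(n)
    test_idx <- ord[seq_len(n_test)]
    train_idx <- ord[-seq_len(n_test)]
    list(x_train = x[train_idx, , drop = FALSE],
         y_train = y[train_idx, , drop = FALSE],
         x_test = x[test_idx, , drop = FALSE],
         y_test = y[test_idx, , drop = FALSE],
         background_of = pick, train_idx = train_idx, test_idx = test_idx)
  })
}

#' Train the denoising autoencoder
#'
#' @param pairs Output of [build_noisy_pairs()].
#' @param config A [dae_config()].
#' @param seed Integer seed (weight init + shuffling).
#' @return A `sers_dae` with trained weights, the config, the training
#'   history and `test_mse` (reconstruction MSE of denoised test inputs
#'   against their clean targets).
#' @export
train_dae <- function(pairs, config = dae_config(), seed = 1) {
  d <- ncol(pairs$x_train)
  if (d != config$input_dim)
    stop2("pair dimension ", d, " does not match config input_dim ",
          config$input_dim)
  layers <- c(
    lapply(config$encoder_widths, function(u) layer_dense(u, "relu")),
    lapply(config$decoder_widths[-length(config$decoder_widths)],
           function(u) layer_dense(u, "relu")),
    list(layer_dense(config$input_dim, "sigmoid")))
  model <- nn_build(nn_model(layers), d, seed = derive_seed(seed, "dae-init"))
  fit <- nn_fit(model, pairs$x_train, pairs$y_train, loss = "mse",
                optimizer = "nadam", lr = config$learning_rate,
                epochs = config$epochs, batch_size = config$batch_size,
                seed = derive_seed(seed, "dae-fit"))
  pred <- nn_predict(fit$model, pairs$x_test)
  structure(list(model = fit$model, config = config,
                 history = fit$history,
                 test_mse = mean((pred - pairs$y_test)^2)),
            class = "sers_dae")
}

#' @export
print.sers_dae <- function(x, ...) {
  cat(sprintf("<sers_dae> %d-%s-%d, test MSE %.4f\n", x$config$input_dim,
              paste(x$config$encoder_widths, collapse = "-"),
              x$config$input_dim, x$test_mse))
  invisible(x)
}

#' Denoise normalized spectra
#'
#' Runs spectra through the trained autoencoder. Inputs must be normalized
#' (state `normalized` for a `sers_spectrum`/`sers_dataset`) and match the
#' model's input dimension; outputs are in \[0, 1\] by the sigmoid contract
#' and carry state `denoised`.
#'
#' @param dae A trained `sers_dae`.
#' @param x A `sers_spectrum`, `sers_dataset`, or numeric matrix of
#'   normalized spectra in rows.
#' @return Same container type as `x`, denoised.
#' @export
denoise <- function(dae, x) {
  stopifnot(inherits(dae, "sers_dae"))
  if (inherits(x, "sers_spectrum")) {
    if (!x$state %in% c("normalized", "denoised"))
      stop2("denoise expects a normalized spectrum (got state=", x$state, ")")
    out <- denoise(dae, matrix(x$intensities, 1))
    return(spectrum(x$wavenumbers, as.numeric(out), state = "denoised"))
  }
  if (inherits(x, "sers_dataset")) {
    if (!x$state %in% c("normalized", "denoised"))
      stop2("denoise expects a normalized dataset (got state=", x$state, ")")
    out <- denoise(dae, x$intensities)
    ds <- x
    ds$intensities <- out
    ds$state <- "denoised"
    return(ds)
  }
  x <- as.matrix(x)
  if (ncol(x) != dae$config$input_dim)
    stop2("spectrum length ", ncol(x), " does not match denoiser input_dim ",
          dae$config$input_dim)
  nn_predict(dae$model, x)
}
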