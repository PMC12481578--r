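#' Ensemble training protocol
#'
#' The quantification training protocol: Adam with learning rate 0.001,
#' batch size 64, up to 256 epochs with mean-absolute-error loss, early
#' stopping with a patience of 64 epochs and checkpointing of the weights
#' with the lowest validation loss. Each model kind is trained
#' `ensemble_size` times (100 in the full protocol) from distinct derived
#' seeds; members whose training-set MAE exceeds `drop_threshold` (1 uM)
#' are dropped as outlier models, and the surviving member with the lowest
#' validation MAE is selected as the final model. Ensemble-average
#' predictions over the survivors are also retained.
#'
#' @param ensemble_size Number of independently trained members.
#' @param epochs,batch_size,learning_rate,loss Training schedule.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param drop_threshold Training MAE (uM) above which a member is dropped.
#' @export
train_protocol <- function(ensemble_size = 100, epochs = 256,
                           batch_size = 64, learning_rate = 1e-3,
                           loss = "mae", early_stop_patience = 64,
                           drop_threshold = 1) {
  stopifnot(ensemble_size >= 1, epochs >= 0, drop_threshold >= 0)
  list(ensemble_size = as.integer(ensemble_size),
       epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, loss = loss,
       early_stop_patience = early_stop_patience,
       drop_threshold = drop_threshold)
}

#' Build a quantification model
#'
#' Four architectures share a core 1-D CNN: an initial 25-point kernel
#' convolution (ReLU), average pooling, a paired Tanh-ReLU convolution
#' block, a "half-peak" 13-point ReLU convolution (about half the nominal
#' 25-point peak width), pooling, and a small dense head.
#'
#' * `cnn_linear` — core CNN with a linear output.
#' * `cnn_3pl` — core CNN with the learnable three-parameter-logistic
#'   output activation.
#' * `scnn` — scale-adjusting CNN: the initial convolution is replaced by
#'   the multiscale layer (kernels 8/25/50, 8 filters each) followed by the
#'   local region-scaling layer, then the core blocks and a 3PL output.
#' * `vit` — patch embedding (width 25, matching the CNN's initial kernel;
#'   hidden size 64, dropout 0.1), 6 pre-norm transformer blocks with
#'   6-head self-attention and GELU MLPs, mean token pooling and a linear
#'   regression head.
#'
#' @param kind Architecture name.
#' @param input_dim Spectrum length.
#' @param regions Preregistered (start, end) index regions for the `scnn`
#'   region-scaling layer; defaults to none (identity scaling layer is not
#'   created when `NULL`, use [propose_scaling_regions()] to derive them
#'   from reference spectra).
#' @param upper_init Upper-asymptote initialization of the 3PL output,
#'   above the maximum training concentration.
#' @param seed Integer seed for weight initialization.
#' @return A `sers_quant` model (untrained).
#' @export
build_model <- function(kind = c("cnn_linear", "cnn_3pl", "scnn", "vit"),
                        input_dim, regions = NULL, upper_init = 10,
                        seed = 1) {
  kind <- match.arg(kind)
  core_tail <- list(layer_paired_conv(filters = 8, kernel = 13),
                    layer_conv1d(filters = 8, kernel = 13,
                                 activation = "relu"),
                    layer_avgpool(4), layer_flatten(),
                    layer_dense(32, "relu"))
  layers <- switch(kind,
    cnn_linear = c(list(layer_reshape_conv(),
                        layer_conv1d(8, 25, "relu"), layer_avgpool(4)),
                   core_tail, list(layer_dense(1, "linear"))),
    cnn_3pl = c(list(layer_reshape_conv(),
                     layer_conv1d(8, 25, "relu"), layer_avgpool(4)),
                core_tail, list(layer_dense(1, "linear"),
                                layer_three_pl(upper_init = upper_init))),
    scnn = {
      scale_layers <- list(layer_reshape_conv(), layer_multiscale())
      if (!is.null(regions))
        scale_layers <- c(scale_layers,
                          list(layer_region_scaling(regions)))
      c(scale_layers, list(layer_avgpool(4)), core_tail,
        list(layer_dense(1, "linear"),
             layer_three_pl(upper_init = upper_init)))
    },
    vit = c(list(layer_reshape_conv(), layer_patch_embed(25, 64)),
            replicate(6, layer_transformer_block(heads = 6,
                                                 mlp_hidden = 128,
                                                 dropout = 0.1),
                      simplify = FALSE),
            list(layer_meanpool_tokens(), layer_dense(1, "linear"))))
  net <- nn_build(nn_model(layers), input_dim, seed = seed)
  structure(list(kind = kind, net = net, input_dim = as.integer(input_dim)),
            class = "sers_quant")
}

#' @export
print.sers_quant <- function(x, ...) {
  cat(sprintf("<sers_quant> %s, input_dim=%d%s\n", x$kind, x$input_dim,
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

#' Predict concentrations
#'
#' @param model A `sers_quant`.
#' @param x Numeric matrix of spectra in rows, or a `sers_dataset`.
#' @return Numeric vector of predicted concentrations, uM.
#' @export
predict_quant <- function(model, x) {
  stopifnot(inherits(model, "sers_quant"))
  if (inherits(x, "sers_dataset")) x <- x$intensities
  as.numeric(nn_predict(model$net, as.matrix(x)))
}

#' Train one quantification model
#'
#' @param model An untrained `sers_quant`.
#' @param train,validation `sers_dataset`s.
#' @param protocol A [train_protocol()].
#' @param seed Integer seed.
#' @return The trained `sers_quant`, with `history`, `train_mae` and
#'   `val_mae` fields.
#' @export
train_quant <- function(model, train, validation, protocol = train_protocol(),
                        seed = 1) {
  stopifnot(inherits(model, "sers_quant"))
  fit <- nn_fit(model$net, train$intensities, train$targets,
                x_val = validation$intensities, y_val = validation$targets,
                loss = protocol$loss, optimizer = "adam",
                lr = protocol$learning_rate, epochs = protocol$epochs,
                batch_size = protocol$batch_size,
                patience = protocol$early_stop_patience, seed = seed)
  model$net <- fit$model
  model$history <- fit$history
  model$trained <- TRUE
  model$train_mae <- mean(abs(predict_quant(model, train) - train$targets))
  model$val_mae <- mean(abs(predict_quant(model, validation) -
                              validation$targets))
  model
}

#' Train an ensemble and select the final model
#'
#' Trains `protocol$ensemble_size` models of one kind from distinct derived
#' seeds, drops members whose training MAE exceeds the drop threshold, and
#' selects the surviving member with the lowest validation MAE as the final
#' model. If every member is dropped the result records
#' `converged = FALSE` (a model kind can fail to converge under the
#' training-MAE cutoff) and carries no selected model.
#'
#' @param kind Architecture passed to [build_model()].
#' @param train,validation `sers_dataset`s.
#' @param protocol A [train_protocol()].
#' @param seed Master seed; member seeds are derived from it.
#' @param ... Further arguments to [build_model()] (e.g. `regions`,
#'   `upper_init`).
#' @return A `sers_ensemble`: members, survivor flags, the selected model
#'   (or `NULL`), and a `predict` helper for ensemble-average predictions.
#' @export
train_ensemble <- function(kind, train, validation,
                           protocol = train_protocol(), seed = 1, ...) {
  members <- vector("list", protocol$ensemble_size)
  train_mae <- val_mae <- numeric(protocol$ensemble_size)
  for (i in seq_len(protocol$ensemble_size)) {
    m <- build_model(kind, input_dim = ncol(train$intensities),
                     seed = derive_seed(seed, "member-init", i), ...)
    m <- train_quant(m, train, validation, protocol,
                     seed = derive_seed(seed, "member-fit", i))
    members[[i]] <- m
    train_mae[i] <- m$train_mae
    val_mae[i] <- m$val_mae
  }
  surviving <- train_mae <= protocol$drop_threshold
  selected <- NULL
  if (any(surviving)) {
    sel <- which(surviving)[which.min(val_mae[surviving])]
    selected <- members[[sel]]
  }
  structure(list(kind = kind, members = members, surviving = surviving,
                 train_mae = train_mae, val_mae = val_mae,
                 selected = selected, converged = any(surviving),
                 protocol = protocol),
            class = "sers_ensemble")
}

#' @export
print.sers_ensemble <- function(x, ...) {
  cat(sprintf("<sers_ensemble> %s: %d members, %d surviving%s\n", x$kind,
              length(x$members), sum(x$surviving),
              if (!x$converged) " (no convergence under MAE cutoff)" else ""))
  invisible(x)
}

#' Ensemble-average predictions over surviving members
#'
#' @param ensemble A `sers_ensemble`.
#' @param x Spectra matrix or `sers_dataset`.
#' @export
predict_ensemble <- function(ensemble, x) {
  if (!ensemble$converged)
    stop2("ensemble did not converge: no surviving members")
  preds <- vapply(ensemble$members[ensemble$surviving],
                  function(m) predict_quant(m, x),
                  numeric(if (inherits(x, "sers_dataset")) n_spectra(x)
                          else nrow(as.matrix(x))))
  rowMeans(as.matrix(preds))
}

#' Regression evaluation metrics
#'
#' Mean absolute error (uM), mean squared error (uM^2) and mean percentage
#' error. MPE is the mean of `|pred - truth| / truth * 100` over entries
#' with `truth >= mpe_floor`; it is undefined at zero concentration, so
#' entries below the floor (default 0.5 uM) are excluded, and `NA` is
#' returned if none remain.
#'
#' @param pred,truth Concentration vectors, uM, equal length.
#' @param mpe_floor Minimum truth for inclusion in MPE.
#' @return List with `mae`, `mse`, `mpe`.
#' @export
evaluate <- function(pred, truth, mpe_floor = 0.5) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  keep <- truth >= mpe_floor
  list(mae = mean(abs(pred - truth)),
       mse = mean((pred - truth)^2),
       mpe = if (any(keep))
         mean(abs(pred[keep] - truth[keep]) / truth[keep]) * 100
       else NA_real_)
}
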