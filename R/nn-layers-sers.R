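# Custom SERS-specific layers: the three-parameter-logistic output
# activation, the multiscale parallel-kernel convolution, the local
# region-scaling layer, and the paired Tanh-ReLU convolution block used in
# the core CNN.

#' Three-parameter logistic activation
#'
#' The saturating calibration-curve form
#' `upper / (1 + exp(-steepness * (z - midpoint)))`: output lies in
#' `(0, upper)`, is strictly increasing in `z`, equals `upper / 2` at the
#' midpoint, and approaches 0 / `upper` at the asymptotes. Used as a
#' learnable output activation so the network's final transformation behaves
#' like an assay calibration curve, which saturates near the limits of
#' quantification.
#'
#' @param z Numeric input (any shape).
#' @param upper Upper asymptote, > 0.
#' @param midpoint Input value mapped to `upper / 2`.
#' @param steepness Slope parameter, > 0.
#' @return Numeric, same shape as `z`.
#' @export
#' @examples
#' three_pl(0, upper = 10, midpoint = 0, steepness = 1)  # 5
three_pl <- function(z, upper = 10, midpoint = 0, steepness = 1) {
  stopifnot(upper > 0, steepness > 0)
  upper / (1 + exp(-steepness * (z - midpoint)))
}

#' @rdname three_pl
#' @param upper_init,midpoint_init,steepness_init Initial values of the
#'   learnable parameters. `upper_init` should sit above the maximum
#'   training concentration (default 10 uM for a 0-9 uM design).
#' @export
layer_three_pl <- function(upper_init = 10, midpoint_init = 0,
                           steepness_init = 1) {
  stopifnot(upper_init > 0, steepness_init > 0)
  list(kind = "three_pl", cfg = list(upper_init = upper_init,
                                     midpoint_init = midpoint_init,
                                     steepness_init = steepness_init))
}

#' Multiscale 1-D convolution layer
#'
#' Three parallel length-preserving convolutions with kernel widths 8, 25
#' and 50 (roughly one third of a peak, one half-peak, and a full peak on
#' the instrument grid), 8 filters each, concatenated along the channel
#' axis: a length-L input yields an L x 24 feature map. The convolution is
#' linear (`C_i(X) = W_i * X + b_i`, cross-correlation convention), so the
#' layer is exactly linear in its input for fixed weights.
#'
#' @param kernels Integer kernel widths.
#' @param filters Filters per kernel.
#' @export
layer_multiscale <- function(kernels = c(8, 25, 50), filters = 8) {
  list(kind = "multiscale", cfg = list(kernels = as.integer(kernels),
                                       filters = as.integer(filters)))
}

#' Local region-scaling layer
#'
#' Multiplies preregistered index regions of the spectrum by learnable
#' scalars `s_j` (one per region), leaving positions outside all regions
#' unchanged; output length equals input length. Regions are inclusive
#' 1-based index ranges and must be non-overlapping. Intended to let the
#' model downweight spectral regions assessed as irrelevant from the pure
#' compounds' reference spectra, while adapting to intensity-scale
#' variation.
#'
#' @param regions Two-column matrix/data.frame of (start, end) indices.
#' @param scale_init Initial value of every scaling factor.
#' @export
layer_region_scaling <- function(regions, scale_init = 1) {
  regions <- as.matrix(regions)
  storage.mode(regions) <- "integer"
  list(kind = "region_scaling",
       cfg = list(regions = regions, scale_init = scale_init))
}

#' @rdname layer_multiscale
#' @param filters,kernel Convolution size of the paired block.
#' @details `layer_paired_conv()` is the core-CNN building block: one
#'   convolution whose pre-activation is passed through tanh and ReLU in
#'   parallel, concatenated along channels (2 x filters outputs).
#' @export
layer_paired_conv <- function(filters = 8, kernel = 13) {
  list(kind = "paired_conv", cfg = list(filters = as.integer(filters),
                                        kernel = as.integer(kernel)))
}

#' Apply region scaling to a vector or feature array
#'
#' Functional form of [layer_region_scaling()]: multiplies each inclusive
#' index region `[start_j, end_j]` of `x` by `scales[j]`; positions outside
#' all regions pass through unchanged.
#'
#' @param x Numeric vector (or n x L x C array).
#' @param regions Two-column matrix of (start, end) indices,
#'   non-overlapping, within `length(x)`.
#' @param scales Numeric vector, one scale per region.
#' @export
region_scaling <- function(x, regions, scales) {
  regions <- as.matrix(regions)
  vec <- is.null(dim(x))
  L <- if (vec) length(x) else dim(x)[2]
  validate_regions(regions, L)
  stopifnot(length(scales) == nrow(regions))
  out <- x
  for (r in seq_len(nrow(regions))) {
    idx <- regions[r, 1]:regions[r, 2]
    if (vec) out[idx] <- x[idx] * scales[r]
    else out[, idx, ] <- x[, idx, , drop = FALSE] * scales[r]
  }
  out
}

#' Apply a single layer outside of a model
#'
#' Convenience used for layer-level verification: builds the layer for the
#' given input shape (seeded init), optionally overrides its parameters,
#' and runs one forward pass.
#'
#' @param layer An unbuilt layer object.
#' @param x Input batch.
#' @param params Optional named list overriding initialized parameters.
#' @param seed Seed for initialization.
#' @return The layer output.
#' @export
nn_apply_layer <- function(layer, x, params = NULL, seed = 1) {
  in_shape <- if (is.matrix(x)) ncol(x) else dim(x)[-1]
  with_seed(derive_seed(seed, "layer"), {
    layer <- nn_layer_init(layer, in_shape)
  })
  if (!is.null(params))
    for (nm in names(params)) layer$params[[nm]] <- params[[nm]]
  nn_layer_forward(layer, x, training = FALSE)$out
}

#' Propose scaling regions from reference spectra
#'
#' Identifies index regions where all supplied (normalized) reference
#' spectra fall below a quantile threshold — i.e. regions carrying no
#' analyte signal — and merges consecutive indices into (start, end)
#' ranges. These are the preregistered regions handed to
#' [layer_region_scaling()].
#'
#' @param references Matrix with one reference spectrum per row.
#' @param quantile_threshold Per-reference amplitude quantile below which a
#'   position counts as signal-free.
#' @param min_width Discard regions narrower than this many points.
#' @return Two-column integer matrix of (start, end) regions.
#' @export
propose_scaling_regions <- function(references, quantile_threshold = 0.5,
                                    min_width = 10) {
  references <- as.matrix(references)
  thr <- apply(references, 1, stats::quantile, probs = quantile_threshold)
  low <- colSums(references > thr) == 0
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  cbind(start = starts[keep], end = ends[keep])
}
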