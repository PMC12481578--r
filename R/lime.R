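#' LIME explanation of one spectrum prediction
#'
#' Fits a local weighted ridge surrogate to the quantifier around a single
#' spectrum. The spectrum is partitioned into contiguous fixed-width
#' segments (default width 25 grid points, about half a peak). Perturbed
#' neighbors are generated by switching random subsets of segments "off" —
#' replacing their values with the spectrum's global baseline level (its
#' minimum intensity) — and the model is evaluated on each neighbor. A
#' ridge regression on the on/off indicator vectors, weighted by an
#' exponential kernel in the fraction of switched-off segments, yields one
#' weight per segment (its local contribution to the prediction) plus an
#' intercept. Per-segment perturbation limits record the range of segment
#' mean values observed across the perturbation sample; the context
#' clustering stage consumes both weights and limits.
#'
#' @param model A trained `sers_quant` (or any function mapping a spectra
#'   matrix to predictions).
#' @param x Numeric spectrum vector.
#' @param segment_width Segment width in grid points.
#' @param n_samples Number of perturbed neighbors.
#' @param seed Integer seed.
#' @param kernel_width Exponential kernel width on the off-fraction
#'   distance.
#' @param ridge Ridge penalty of the surrogate.
#' @return A `sers_lime` object: `weights`, `intercept`, `limits`
#'   (2 x n_segments lower/upper), `segment_map` (start, end indices),
#'   `prediction`.
#' @export
lime_explain <- function(model, x, segment_width = 25, n_samples = 500,
                         seed = 1, kernel_width = 0.25, ridge = 1e-3) {
  x <- as.numeric(x)
  p <- length(x)
  starts <- seq(1L, p, by = segment_width)
  ends <- pmin(starts + segment_width - 1L, p)
  ns <- length(starts)
  if (n_samples < ns)
    stop2("lime_explain: n_samples (", n_samples,
          ") must be >= number of segments (", ns, ") for a determined ",
          "surrogate")
  predict_fn <- if (inherits(model, "sers_quant"))
    function(m) predict_quant(model, m) else model
  base_level <- min(x)
  with_seed(derive_seed(seed, "lime"), {
    Z <- matrix(stats::rbinom(n_samples * ns, 1, 0.5), n_samples, ns)
    Z[1, ] <- 1  # include the unperturbed instance
    X <- matrix(rep(x, each = n_samples), n_samples, p)
    for (j in seq_len(ns)) {
      off <- Z[, j] == 0
      if (any(off)) X[off, starts[j]:ends[j]] <- base_level
    }
    pred <- as.numeric(predict_fn(X))
    d <- 1 - rowMeans(Z)  # fraction of segments switched off
    w <- exp(-(d / kernel_width)^2)
    # weighted ridge: (Z'WZ + r I) beta = Z'W y, with intercept column
    Zc <- cbind(1, Z)
    A <- crossprod(Zc * w, Zc)
    diag(A)[-1] <- diag(A)[-1] + ridge
    beta <- solve(A, crossprod(Zc * w, pred))
    seg_means <- vapply(seq_len(ns), function(j)
      mean(x[starts[j]:ends[j]]), numeric(1))
    limits <- rbind(lower = pmin(seg_means, base_level),
                    upper = pmax(seg_means, base_level))
    structure(list(weights = as.numeric(beta[-1]),
                   intercept = beta[1],
                   limits = limits,
                   segment_map = cbind(start = starts, end = ends),
                   prediction = pred[1]),
              class = "sers_lime")
  })
}

#' Flatten a set of LIME explanations into a feature matrix
#'
#' One row per instance: the concatenation of segment weights, lower
#' perturbation limits and upper perturbation limits, each column min-max
#' normalized across the dataset (constant columns map to zero). This is
#' the representation whose latent structure defines prediction contexts.
#'
#' @param explanations List of `sers_lime` sharing one segment map.
#' @return Numeric matrix, n x (3 * n_segments).
#' @export
flatten_explanations <- function(explanations) {
  stopifnot(length(explanations) >= 1)
  sm <- explanations[[1]]$segment_map
  for (e in explanations)
    if (!identical(dim(e$segment_map), dim(sm)) ||
        any(e$segment_map != sm))
      stop2("flatten_explanations: inconsistent segment maps")
  M <- do.call(rbind, lapply(explanations, function(e)
    c(e$weights, e$limits["lower", ], e$limits["upper", ])))
  apply(M, 2, function(col) {
    r <- range(col)
    if (diff(r) == 0) rep(0, length(col)) else (col - r[1]) / diff(r)
  })
}
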