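#' Cosine similarity of two spectra
#'
#' `dot(A, B) / (||A|| ||B||)`: 1 for identical direction, 0 for orthogonal
#' spectra, -1 for completely opposite. Invariant to positive rescaling of
#' either argument.
#'
#' @param a,b Numeric vectors of equal length, nonzero norm.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop2("cosine similarity undefined for zero-norm vectors")
  sum(a * b) / (na * nb)
}

#' Variational autoencoder specification for the context latent space
#'
#' A small fully connected VAE compressing flattened LIME explanations to a
#' two-dimensional latent space (the latent dimension is fixed by the
#' method: contexts are identified by clustering, and inspected, in 2-D).
#'
#' @param hidden Encoder/decoder hidden width.
#' @param beta Weight of the KL divergence term.
#' @param epochs,batch_size,learning_rate Training schedule.
#' @export
vae_spec <- function(hidden = 32, beta = 0.01, epochs = 300,
                     batch_size = 32, learning_rate = 1e-3) {
  stopifnot(hidden >= 2, beta >= 0)
  list(hidden = as.integer(hidden), latent_dim = 2L, beta = beta,
       epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate)
}

#' Fit the VAE and return 2-D latent coordinates
#'
#' Trains the VAE of [vae_spec()] on the flattened explanation matrix
#' (reconstruction MSE plus beta-weighted KL divergence, Adam) and returns
#' the encoder mean for every instance. Deterministic under `seed`. If all
#' rows are identical there is no structure to embed; a warning is emitted
#' and collapsed (all-equal) coordinates are returned.
#'
#' @param x Numeric matrix, n >= 10 rows.
#' @param spec A [vae_spec()].
#' @param seed Integer seed.
#' @return n x 2 matrix of latent means.
#' @export
fit_latent <- function(x, spec = vae_spec(), seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 10) stop2("fit_latent needs at least 10 instances")
  if (all(apply(x, 2, function(col) diff(range(col)) == 0))) {
    warning("fit_latent: all rows identical; returning collapsed coordinates")
    return(matrix(0, n, 2))
  }
  w <- spec$hidden
  enc <- nn_build(nn_model(list(layer_dense(w, "relu"))), d,
                  seed = derive_seed(seed, "vae-enc"))
  mu <- nn_build(nn_model(list(layer_dense(2))), w,
                 seed = derive_seed(seed, "vae-mu"))
  lv <- nn_build(nn_model(list(layer_dense(2))), w,
                 seed = derive_seed(seed, "vae-lv"))
  dec <- nn_build(nn_model(list(layer_dense(w, "relu"), layer_dense(d))), 2,
                  seed = derive_seed(seed, "vae-dec"))
  opts <- list(enc = opt_create(enc, "adam", spec$learning_rate),
               mu = opt_create(mu, "adam", spec$learning_rate),
               lv = opt_create(lv, "adam", spec$learning_rate),
               dec = opt_create(dec, "adam", spec$learning_rate))
  beta <- spec$beta
  with_seed(derive_seed(seed, "vae-fit"), {
    for (ep in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = spec$batch_size)) {
        b <- idx[start:min(start + spec$batch_size - 1L, n)]
        xb <- x[b, , drop = FALSE]
        nb <- nrow(xb)
        fe <- nn_forward(enc, xb, training = TRUE)
        fm <- nn_forward(mu, fe$out)
        fs <- nn_forward(lv, fe$out)
        eps <- matrix(stats::rnorm(nb * 2), nb, 2)
        z <- fm$out + exp(fs$out / 2) * eps
        fd <- nn_forward(dec, z, training = TRUE)
        # gradients: recon MSE (mean over elements) + beta * mean KL
        dxh <- 2 * (fd$out - xb) / (nb * d)
        bd <- nn_backward(dec, fd$caches, dxh)
        dz <- bd$dx
        dm <- dz + beta / nb * fm$out
        dsd <- dz * eps * 0.5 * exp(fs$out / 2) +
          beta / nb * 0.5 * (exp(fs$out) - 1)
        bm <- nn_backward(mu, fm$caches, dm)
        bs <- nn_backward(lv, fs$caches, dsd)
        be <- nn_backward(enc, fe$caches, bm$dx + bs$dx)
        st <- opt_step(opts$dec, dec, bd$grads); opts$dec <- st$opt; dec <- st$model
        st <- opt_step(opts$mu, mu, bm$grads); opts$mu <- st$opt; mu <- st$model
        st <- opt_step(opts$lv, lv, bs$grads); opts$lv <- st$opt; lv <- st$model
        st <- opt_step(opts$enc, enc, be$grads); opts$enc <- st$opt; enc <- st$model
      }
    }
  })
  h <- nn_predict(enc, x)
  nn_predict(mu, h)
}

# K-means that tolerates duplicate points: when the requested k is not
# below the number of distinct rows, every distinct row becomes its own
# cluster (stats::kmeans rejects that case).
safe_kmeans <- function(x, k, seed) {
  x <- as.matrix(x)
  keys <- apply(x, 1, paste, collapse = "\r")
  n_distinct <- length(unique(keys))
  if (k >= n_distinct) return(match(keys, unique(keys)))
  with_seed(seed, stats::kmeans(x, k, nstart = 10))$cluster
}

# Mean silhouette width over all points (Euclidean), used for the
# programmatic choice of the context count.
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  ulab <- unique(labels)
  if (length(ulab) < 2) return(NA_real_)
  dm <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(dm[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(ulab[ulab != labels[i]],
                    function(l) mean(dm[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster the latent space into prediction contexts
#'
#' K-means on the 2-D latent coordinates. The context count is normally
#' chosen by inspecting the latent space; `k = "auto"` provides a
#' programmatic default that scans k = 2..10 and keeps the
#' silhouette-maximizing value. An explicit `k` overrides the scan.
#'
#' @param latent n x 2 latent coordinates.
#' @param k Integer >= 2, or `"auto"`.
#' @param seed Integer seed.
#' @return Integer context labels with attribute `"k"`.
#' @export
cluster_contexts <- function(latent, k = "auto", seed = 1) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (identical(k, "auto")) {
    ks <- 2:min(10, n - 1)
    sil <- vapply(ks, function(kk) {
      cl <- safe_kmeans(latent, kk, derive_seed(seed, "kscan", kk))
      silhouette_score(latent, cl)
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k < 2) stop2("cluster_contexts needs k >= 2")
  if (k > n) stop2("cluster_contexts: k exceeds number of instances")
  structure(safe_kmeans(latent, k, derive_seed(seed, "kmeans")), k = k)
}

#' Summarize one context: mean explanation and top peak regions
#'
#' Averages the member explanations and member spectra, then locates the
#' spectral regions driving the context: every segment becomes a point in a
#' three-dimensional space (mean spectral intensity in the segment,
#' min-max-normalized absolute LIME weight, segment-position z-score),
#' the points are clustered by K-means into `n_clusters` (15) groups, the
#' groups are ranked by the product of their mean absolute weight and mean
#' intensity, and the `n_top` (5) highest-scoring groups are reported as
#' index regions (the contiguous span of each group's segments).
#'
#' @param explanations List of `sers_lime` for the context members.
#' @param spectra Matrix of the members' spectra (rows).
#' @param n_clusters Number of segment clusters (reduced with a warning if
#'   there are fewer segments).
#' @param n_top Number of top regions reported.
#' @param seed Integer seed.
#' @return A `sers_context`: `mean_weights`, `mean_limits`,
#'   `mean_spectrum`, `segment_map`, `top_regions` (start, end, score),
#'   `n_members`.
#' @export
context_regions <- function(explanations, spectra, n_clusters = 15,
                            n_top = 5, seed = 1) {
  stopifnot(length(explanations) >= 1)
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == length(explanations))
  sm <- explanations[[1]]$segment_map
  W <- do.call(rbind, lapply(explanations, function(e) e$weights))
  mean_w <- colMeans(W)
  mean_lower <- colMeans(do.call(rbind, lapply(explanations,
                                               function(e) e$limits["lower", ])))
  mean_upper <- colMeans(do.call(rbind, lapply(explanations,
                                               function(e) e$limits["upper", ])))
  mean_spectrum <- colMeans(spectra)
  ns <- nrow(sm)
  if (n_clusters > ns) {
    warning("context_regions: fewer segments (", ns, ") than clusters (",
            n_clusters, "); reducing")
    n_clusters <- ns
  }
  seg_int <- vapply(seq_len(ns), function(j)
    mean(mean_spectrum[sm[j, 1]:sm[j, 2]]), numeric(1))
  aw <- abs(mean_w)
  norm_w <- if (diff(range(aw)) > 0) (aw - min(aw)) / diff(range(aw))
            else rep(0, ns)
  centers <- rowMeans(sm)
  pos_z <- as.numeric(scale(centers))
  pts <- cbind(seg_int, norm_w, pos_z)
  cl <- safe_kmeans(pts, n_clusters, derive_seed(seed, "regions"))
  score <- vapply(seq_len(n_clusters), function(g)
    mean(norm_w[cl == g]) * mean(seg_int[cl == g]), numeric(1))
  top <- order(score, decreasing = TRUE)[seq_len(min(n_top, n_clusters))]
  regions <- do.call(rbind, lapply(top, function(g) {
    segs <- which(cl == g)
    c(start = unname(sm[min(segs), 1]), end = unname(sm[max(segs), 2]),
      score = unname(score[g]))
  }))
  structure(list(mean_weights = mean_w,
                 mean_limits = rbind(lower = mean_lower, upper = mean_upper),
                 mean_spectrum = mean_spectrum, segment_map = sm,
                 top_regions = regions, n_members = length(explanations)),
            class = "sers_context")
}

#' Match a context against reference spectra
#'
#' Both the context's mean spectrum and each reference spectrum are scaled
#' elementwise by the context's explanation-weight profile (each position
#' inherits its segment's absolute mean LIME weight, normalized to a
#' maximum of 1; if all weights vanish a uniform profile is used), then
#' compared by [cosine_similarity()]. Matches are returned sorted by
#' descending similarity, so the top row names the compound the context's
#' prediction-relevant regions most resemble.
#'
#' @param context A `sers_context`.
#' @param references Matrix of reference spectra in rows (rownames =
#'   analyte names), on the same grid as the context spectra.
#' @return Data frame (analyte, cosine) sorted descending.
#' @export
match_context <- function(context, references) {
  references <- as.matrix(references)
  p <- length(context$mean_spectrum)
  if (ncol(references) != p)
    stop2("match_context: reference grid length ", ncol(references),
          " does not match context spectrum length ", p)
  sm <- context$segment_map
  aw <- abs(context$mean_weights)
  prof <- rep(1, p)
  if (max(aw) > 0) {
    wn <- aw / max(aw)
    for (j in seq_len(nrow(sm))) prof[sm[j, 1]:sm[j, 2]] <- wn[j]
  }
  target <- context$mean_spectrum * prof
  sims <- vapply(seq_len(nrow(references)), function(i)
    cosine_similarity(target, references[i, ] * prof), numeric(1))
  out <- data.frame(analyte = rownames(references) %||%
                      paste0("ref", seq_len(nrow(references))),
                    cosine = sims)
  out[order(-out$cosine), , drop = FALSE]
}

#' Run the full context-explainability pipeline
#'
#' Per-instance LIME explanations of the quantifier over a whole dataset,
#' flattened and embedded in the 2-D latent space of a VAE; K-means context
#' clusters; per-context mean explanations, top peak regions, and weighted
#' cosine matches against reference spectra. This exposes the distinct
#' rationales the model uses — the target analyte's own peaks, confounder
#' peaks that merely correlate with the target, or outlier patterns.
#'
#' @param model A trained `sers_quant`.
#' @param ds A `sers_dataset` (all instances are explained).
#' @param references Matrix of reference spectra in rows (rownames =
#'   analytes), same grid as `ds`.
#' @param k Context count, or `"auto"` (see [cluster_contexts()]).
#' @param segment_width,n_samples LIME settings (see [lime_explain()]).
#' @param spec VAE settings (see [vae_spec()]).
#' @param seed Integer master seed.
#' @return A `sers_crime`: per-context `sers_context`s with
#'   `matches`, plus `labels`, `latent`, and the explanation list.
#' @export
crime <- function(model, ds, references, k = "auto", segment_width = 25,
                  n_samples = 300, spec = vae_spec(), seed = 1) {
  stopifnot(inherits(ds, "sers_dataset"))
  n <- n_spectra(ds)
  explanations <- lapply(seq_len(n), function(i)
    lime_explain(model, ds$intensities[i, ], segment_width = segment_width,
                 n_samples = n_samples, seed = derive_seed(seed, "lime", i)))
  flat <- flatten_explanations(explanations)
  latent <- fit_latent(flat, spec, seed = derive_seed(seed, "latent"))
  labels <- cluster_contexts(latent, k = k, seed = derive_seed(seed, "ctx"))
  contexts <- lapply(sort(unique(labels)), function(l) {
    idx <- which(labels == l)
    ctx <- context_regions(explanations[idx],
                           ds$intensities[idx, , drop = FALSE],
                           seed = derive_seed(seed, "regions", l))
    ctx$context_id <- l
    ctx$member_indices <- idx
    ctx$matches <- match_context(ctx, references)
    ctx
  })
  structure(list(contexts = contexts, labels = labels, latent = latent,
                 explanations = explanations, flat = flat),
            class = "sers_crime")
}

#' @export
print.sers_crime <- function(x, ...) {
  cat(sprintf("<sers_crime> %d contexts over %d instances\n",
              length(x$contexts), length(x$labels)))
  for (ctx in x$contexts)
    cat(sprintf("  context %d (n=%d): top match %s (cosine %.3f)\n",
                ctx$context_id, ctx$n_members, ctx$matches$analyte[1],
                ctx$matches$cosine[1]))
  invisible(x)
}

#' Plot the context latent space
#'
#' Scatter plot of the 2-D latent coordinates colored by context label —
#' the view used to inspect context separation and choose the context
#' count.
#'
#' @param x A `sers_crime`.
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @export
crime_latent_plot <- function(x, file = NULL) {
  stopifnot(inherits(x, "sers_crime"))
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(x$latent, col = x$labels, pch = 19,
                 xlab = "latent 1", ylab = "latent 2",
                 main = "Explanation contexts in VAE latent space")
  graphics::legend("topright", legend = paste("context", sort(unique(x$labels))),
                   col = sort(unique(x$labels)), pch = 19, cex = 0.8)
  invisible(x)
}
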