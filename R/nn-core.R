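# Minimal reverse-mode neural network engine.
#
# Layers are plain lists carrying a `kind`, a config, and (after nn_build) a
# named list of parameter arrays. Forward passes return an output plus a
# cache; backward passes map the output gradient to an input gradient and
# per-parameter gradients. Batched data is either a matrix (n x d) for dense
# stages or a 3-D array (n x L x C) for convolutional stages; token stages
# (transformer) use (n x P x H). All heavy operations reduce to BLAS matrix
# products, so training runs at practical speed on CPU.

# ---- activations -----------------------------------------------------------

act_forward <- function(name, z) {
  switch(name,
         linear = z,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         gelu = z * stats::pnorm(z),
         stop2("unknown activation: ", name))
}

act_grad <- function(name, z) {
  switch(name,
         linear = array(1, dim(z) %||% length(z)),
         relu = (z > 0) + 0,
         tanh = 1 - tanh(z)^2,
         sigmoid = { s <- 1 / (1 + exp(-z)); s * (1 - s) },
         gelu = stats::pnorm(z) + z * stats::dnorm(z),
         stop2("unknown activation: ", name))
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# ---- layer constructors ----------------------------------------------------

#' Neural network layer constructors
#'
#' Building blocks for the package's quantification and denoising networks.
#' Assemble them with [nn_model()], then [nn_build()], [nn_fit()] and
#' [nn_predict()]. Custom SERS layers ([layer_multiscale()],
#' [layer_region_scaling()], [layer_three_pl()], [layer_paired_conv()]) are
#' documented separately.
#'
#' @param units,activation Dense layer width and activation
#'   (`linear`, `relu`, `tanh`, `sigmoid`, `gelu`).
#' @name nn-layers
NULL

#' @rdname nn-layers
#' @export
layer_dense <- function(units, activation = "linear") {
  list(kind = "dense", cfg = list(units = as.integer(units),
                                  activation = activation))
}

#' @rdname nn-layers
#' @param filters,kernel 1-D convolution filter count and kernel width;
#'   padding is length-preserving ("same"), and the convolution uses the
#'   cross-correlation convention (no kernel flip).
#' @export
layer_conv1d <- function(filters, kernel, activation = "linear") {
  list(kind = "conv1d", cfg = list(filters = as.integer(filters),
                                   kernel = as.integer(kernel),
                                   activation = activation))
}

#' @rdname nn-layers
#' @param width Average-pooling window and stride (non-overlapping);
#'   trailing positions that do not fill a window are dropped.
#' @export
layer_avgpool <- function(width) {
  list(kind = "avgpool", cfg = list(width = as.integer(width)))
}

#' @rdname nn-layers
#' @export
layer_flatten <- function() list(kind = "flatten", cfg = list())

#' @rdname nn-layers
#' @export
layer_reshape_conv <- function() list(kind = "reshape_conv", cfg = list())

#' @rdname nn-layers
#' @param rate Dropout rate in \[0, 1); active only during training.
#' @export
layer_dropout <- function(rate) {
  list(kind = "dropout", cfg = list(rate = rate))
}

# ---- build -----------------------------------------------------------------

#' Assemble and initialize a network
#'
#' `nn_model()` collects layers; `nn_build()` walks them once with the input
#' shape, initializing parameters (Glorot-uniform fan-based init) under a
#' fixed seed and recording every layer's output shape.
#'
#' @param layers List of layer objects.
#' @return `nn_model()`: an unbuilt model. `nn_build()`: the built model.
#' @export
nn_model <- function(layers) {
  structure(list(layers = layers, built = FALSE), class = "sers_nn")
}

#' @rdname nn_model
#' @param model An `sers_nn` model.
#' @param input_shape Input shape without the batch dimension: `d` for a
#'   dense input or `c(L, C)` for a convolutional input.
#' @param seed Integer seed for weight initialization.
#' @export
nn_build <- function(model, input_shape, seed = 1) {
  stopifnot(inherits(model, "sers_nn"))
  with_seed(derive_seed(seed, "init"), {
    shape <- input_shape
    for (i in seq_along(model$layers)) {
      l <- model$layers[[i]]
      l <- nn_layer_init(l, shape)
      shape <- l$cfg$out_shape
      model$layers[[i]] <- l
    }
  })
  model$built <- TRUE
  model$output_shape <- shape
  model
}

nn_layer_init <- function(l, in_shape) {
  l$cfg$in_shape <- in_shape
  k <- l$kind
  if (k == "dense") {
    d <- in_shape[1]
    stopifnot(length(in_shape) == 1)
    u <- l$cfg$units
    l$params <- list(W = glorot(d, u, c(d, u)), b = numeric(u))
    l$cfg$out_shape <- u
  } else if (k == "reshape_conv") {
    stopifnot(length(in_shape) == 1)
    l$cfg$out_shape <- c(in_shape, 1L)
  } else if (k == "conv1d") {
    stopifnot(length(in_shape) == 2)
    L <- in_shape[1]; C <- in_shape[2]
    if (L < l$cfg$kernel)
      stop2("conv1d: input length ", L, " < kernel ", l$cfg$kernel)
    kk <- l$cfg$kernel; f <- l$cfg$filters
    l$params <- list(W = glorot(kk * C, f, c(kk * C, f)), b = numeric(f))
    l$cfg$out_shape <- c(L, f)
  } else if (k == "multiscale") {
    stopifnot(length(in_shape) == 2)
    L <- in_shape[1]; C <- in_shape[2]
    if (L < max(l$cfg$kernels))
      stop2("multiscale: input length ", L, " < largest kernel ",
            max(l$cfg$kernels))
    f <- l$cfg$filters
    l$params <- list()
    for (bi in seq_along(l$cfg$kernels)) {
      kk <- l$cfg$kernels[bi]
      l$params[[paste0("W", bi)]] <- glorot(kk * C, f, c(kk * C, f))
      l$params[[paste0("b", bi)]] <- numeric(f)
    }
    l$cfg$out_shape <- c(L, f * length(l$cfg$kernels))
  } else if (k == "paired_conv") {
    stopifnot(length(in_shape) == 2)
    L <- in_shape[1]; C <- in_shape[2]
    kk <- l$cfg$kernel; f <- l$cfg$filters
    l$params <- list(W = glorot(kk * C, f, c(kk * C, f)), b = numeric(f))
    l$cfg$out_shape <- c(L, 2L * f)
  } else if (k == "region_scaling") {
    stopifnot(length(in_shape) == 2)
    reg <- l$cfg$regions
    validate_regions(reg, in_shape[1])
    l$params <- list(s = rep(l$cfg$scale_init, nrow(reg)))
    l$cfg$out_shape <- in_shape
  } else if (k == "avgpool") {
    stopifnot(length(in_shape) == 2)
    l$cfg$out_shape <- c(in_shape[1] %/% l$cfg$width, in_shape[2])
  } else if (k == "flatten") {
    l$cfg$out_shape <- prod(in_shape)
  } else if (k == "dropout") {
    l$cfg$out_shape <- in_shape
  } else if (k == "three_pl") {
    stopifnot(length(in_shape) == 1, in_shape[1] == 1)
    l$params <- list(upper = l$cfg$upper_init,
                     midpoint = l$cfg$midpoint_init,
                     log_steepness = log(l$cfg$steepness_init))
    l$cfg$out_shape <- 1L
  } else if (k == "patch_embed") {
    stopifnot(length(in_shape) == 2, in_shape[2] == 1)
    p <- l$cfg$patch; h <- l$cfg$hidden
    P <- as.integer(ceiling(in_shape[1] / p))
    l$cfg$n_patches <- P
    l$cfg$pad_to <- P * p
    l$params <- list(W = glorot(p, h, c(p, h)), b = numeric(h),
                     pos = array(stats::rnorm(P * h, 0, 0.02), c(P, h)))
    l$cfg$out_shape <- c(P, h)
  } else if (k == "transformer_block") {
    stopifnot(length(in_shape) == 2)
    H <- in_shape[2]
    # per-head key dim need not divide the hidden size; project to
    # heads * head_dim internally and back to H on output
    dh <- as.integer(ceiling(H / l$cfg$heads))
    D <- dh * l$cfg$heads
    l$cfg$head_dim <- dh
    mh <- l$cfg$mlp_hidden
    l$params <- list(
      g1 = rep(1, H), be1 = numeric(H),
      Wq = glorot(H, D, c(H, D)), bq = numeric(D),
      Wk = glorot(H, D, c(H, D)), bk = numeric(D),
      Wv = glorot(H, D, c(H, D)), bv = numeric(D),
      Wo = glorot(D, H, c(D, H)), bo = numeric(H),
      g2 = rep(1, H), be2 = numeric(H),
      W1 = glorot(H, mh, c(H, mh)), b1 = numeric(mh),
      W2 = glorot(mh, H, c(mh, H)), b2 = numeric(H))
    l$cfg$out_shape <- in_shape
  } else if (k == "meanpool_tokens") {
    stopifnot(length(in_shape) == 2)
    l$cfg$out_shape <- in_shape[2]
  } else stop2("unknown layer kind: ", k)
  if (is.null(l$params)) l$params <- list()
  l
}

validate_regions <- function(reg, L) {
  reg <- as.matrix(reg)
  if (ncol(reg) != 2) stop2("regions must have two columns (start, end)")
  if (any(reg[, 1] > reg[, 2])) stop2("region start must be <= end")
  if (any(reg[, 1] < 1) || any(reg[, 2] > L))
    stop2("regions must lie within the spectrum length (", L, ")")
  if (nrow(reg) > 1) {
    o <- order(reg[, 1])
    r <- reg[o, , drop = FALSE]
    if (any(r[-1, 1] <= r[-nrow(r), 2]))
      stop2("regions must be non-overlapping")
  }
  invisible(reg)
}

# ---- conv helpers ----------------------------------------------------------

conv_pad_left <- function(k) (k - 1L) %/% 2L

# Patch extraction and its adjoint are the training hot path; both live in
# compiled code (src/conv_ops.cpp).
conv_im2col <- function(x, k) {
  dm <- dim(x)
  im2col_cpp(x, dm[1], dm[2], dm[3], k)
}

conv_col2im <- function(dcol, n, L, C, k) {
  col2im_cpp(dcol, n, L, C, k)
}

conv_forward <- function(x, W, b, k) {
  dm <- dim(x); n <- dm[1]; L <- dm[2]
  xcol <- conv_im2col(x, k)
  z <- xcol %*% W
  z <- z + rep(b, each = n * L)
  dim(z) <- c(n, L, length(b))
  list(z = z, xcol = xcol)
}

conv_backward <- function(dz, xcol, W, n, L, C, k) {
  f <- ncol(W)
  dim(dz) <- c(n * L, f)
  dW <- crossprod(xcol, dz)
  db <- colSums(dz)
  dx <- conv_col2im(dz %*% t(W), n, L, C, k)
  list(dx = dx, dW = dW, db = db)
}

# ---- forward/backward ------------------------------------------------------

nn_layer_forward <- function(l, x, training = FALSE) {
  k <- l$kind
  p <- l$params
  if (k == "dense") {
    z <- x %*% p$W
    z <- z + rep(p$b, each = nrow(x))
    list(out = act_forward(l$cfg$activation, z), cache = list(x = x, z = z))
  } else if (k == "reshape_conv") {
    dim(x) <- c(dim(x), 1L)
    list(out = x, cache = list())
  } else if (k == "conv1d") {
    cf <- conv_forward(x, p$W, p$b, l$cfg$kernel)
    list(out = act_forward(l$cfg$activation, cf$z),
         cache = list(xcol = cf$xcol, z = cf$z, dm = dim(x)))
  } else if (k == "multiscale") {
    outs <- vector("list", length(l$cfg$kernels))
    caches <- vector("list", length(l$cfg$kernels))
    for (bi in seq_along(l$cfg$kernels)) {
      cf <- conv_forward(x, p[[paste0("W", bi)]], p[[paste0("b", bi)]],
                         l$cfg$kernels[bi])
      outs[[bi]] <- cf$z
      caches[[bi]] <- cf$xcol
    }
    dm <- dim(x)
    f <- l$cfg$filters
    out <- array(0, c(dm[1], dm[2], f * length(outs)))
    for (bi in seq_along(outs))
      out[, , ((bi - 1L) * f + 1L):(bi * f)] <- outs[[bi]]
    list(out = out, cache = list(xcols = caches, dm = dm))
  } else if (k == "paired_conv") {
    cf <- conv_forward(x, p$W, p$b, l$cfg$kernel)
    z <- cf$z
    dm <- dim(z)
    out <- array(0, c(dm[1], dm[2], 2L * dm[3]))
    out[, , seq_len(dm[3])] <- tanh(z)
    out[, , dm[3] + seq_len(dm[3])] <- pmax(z, 0)
    list(out = out, cache = list(xcol = cf$xcol, z = z, dm = dim(cf$xcol),
                                 in_dm = c(dm[1], dm[2], l$cfg$in_shape[2])))
  } else if (k == "region_scaling") {
    out <- x
    reg <- l$cfg$regions
    for (r in seq_len(nrow(reg)))
      out[, reg[r, 1]:reg[r, 2], ] <- x[, reg[r, 1]:reg[r, 2], , drop = FALSE] * p$s[r]
    list(out = out, cache = list(x = x))
  } else if (k == "avgpool") {
    w <- l$cfg$width
    dm <- dim(x)
    L2 <- dm[2] %/% w
    out <- x[, seq(1, by = w, length.out = L2), , drop = FALSE]
    if (w > 1)
      for (j in 2:w)
        out <- out + x[, seq(j, by = w, length.out = L2), , drop = FALSE]
    list(out = out / w, cache = list(dm = dm))
  } else if (k == "flatten") {
    dm <- dim(x)
    dim(x) <- c(dm[1], prod(dm[-1]))
    list(out = x, cache = list(dm = dm))
  } else if (k == "dropout") {
    if (training && l$cfg$rate > 0) {
      mask <- (stats::runif(length(x)) >= l$cfg$rate) / (1 - l$cfg$rate)
      dim(mask) <- dim(x)
      list(out = x * mask, cache = list(mask = mask))
    } else list(out = x, cache = list(mask = NULL))
  } else if (k == "three_pl") {
    s <- exp(p$log_steepness)
    sig <- 1 / (1 + exp(-s * (x - p$midpoint)))
    list(out = p$upper * sig, cache = list(x = x, sig = sig, s = s))
  } else if (k == "patch_embed") {
    dm <- dim(x)
    n <- dm[1]; pt <- l$cfg$patch; P <- l$cfg$n_patches
    xp <- array(0, c(n, l$cfg$pad_to))
    xp[, seq_len(dm[2])] <- x[, , 1]
    xt <- array(0, c(n, P, pt))
    for (q in seq_len(P))
      xt[, q, ] <- xp[, ((q - 1L) * pt + 1L):(q * pt)]
    xtm <- xt; dim(xtm) <- c(n * P, pt)
    z <- xtm %*% p$W
    z <- z + rep(p$b, each = n * P)
    dim(z) <- c(n, P, l$cfg$hidden)
    for (q in seq_len(P))
      z[, q, ] <- z[, q, ] + rep(p$pos[q, ], each = n)
    list(out = z, cache = list(xtm = xtm, n = n, L = dm[2]))
  } else if (k == "transformer_block") {
    tf_block_forward(l, x, training)
  } else if (k == "meanpool_tokens") {
    dm <- dim(x)
    out <- x[, 1, ]
    if (dm[2] > 1) for (q in 2:dm[2]) out <- out + x[, q, ]
    if (is.null(dim(out))) dim(out) <- c(dm[1], dm[3])
    list(out = out / dm[2], cache = list(dm = dm))
  } else stop2("unknown layer kind: ", k)
}

nn_layer_backward <- function(l, cache, dy) {
  k <- l$kind
  p <- l$params
  if (k == "dense") {
    dz <- dy * act_grad(l$cfg$activation, cache$z)
    list(dx = dz %*% t(p$W),
         grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
  } else if (k == "reshape_conv") {
    dim(dy) <- dim(dy)[1:2]
    list(dx = dy, grads = list())
  } else if (k == "conv1d") {
    dz <- dy * act_grad(l$cfg$activation, cache$z)
    dm <- cache$dm
    cb <- conv_backward(dz, cache$xcol, p$W, dm[1], dm[2], dm[3], l$cfg$kernel)
    list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
  } else if (k == "multiscale") {
    dm <- cache$dm
    f <- l$cfg$filters
    dx <- array(0, dm)
    grads <- list()
    for (bi in seq_along(l$cfg$kernels)) {
      dzb <- dy[, , ((bi - 1L) * f + 1L):(bi * f), drop = FALSE]
      cb <- conv_backward(dzb, cache$xcols[[bi]], p[[paste0("W", bi)]],
                          dm[1], dm[2], dm[3], l$cfg$kernels[bi])
      dx <- dx + cb$dx
      grads[[paste0("W", bi)]] <- cb$dW
      grads[[paste0("b", bi)]] <- cb$db
    }
    list(dx = dx, grads = grads)
  } else if (k == "paired_conv") {
    z <- cache$z
    f <- dim(z)[3]
    dz <- dy[, , seq_len(f), drop = FALSE] * (1 - tanh(z)^2) +
      dy[, , f + seq_len(f), drop = FALSE] * ((z > 0) + 0)
    dmin <- cache$in_dm
    cb <- conv_backward(dz, cache$xcol, p$W, dmin[1], dmin[2], dmin[3],
                        l$cfg$kernel)
    list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
  } else if (k == "region_scaling") {
    reg <- l$cfg$regions
    dx <- dy
    ds <- numeric(nrow(reg))
    for (r in seq_len(nrow(reg))) {
      idx <- reg[r, 1]:reg[r, 2]
      ds[r] <- sum(dy[, idx, , drop = FALSE] * cache$x[, idx, , drop = FALSE])
      dx[, idx, ] <- dy[, idx, , drop = FALSE] * p$s[r]
    }
    list(dx = dx, grads = list(s = ds))
  } else if (k == "avgpool") {
    w <- l$cfg$width
    dm <- cache$dm
    L2 <- dm[2] %/% w
    dx <- array(0, dm)
    for (j in seq_len(w))
      dx[, seq(j, by = w, length.out = L2), ] <- dy / w
    list(dx = dx, grads = list())
  } else if (k == "flatten") {
    dim(dy) <- cache$dm
    list(dx = dy, grads = list())
  } else if (k == "dropout") {
    if (!is.null(cache$mask)) dy <- dy * cache$mask
    list(dx = dy, grads = list())
  } else if (k == "three_pl") {
    sig <- cache$sig; s <- cache$s
    core <- p$upper * sig * (1 - sig) * s
    list(dx = dy * core,
         grads = list(upper = sum(dy * sig),
                      midpoint = -sum(dy * core),
                      log_steepness = sum(dy * p$upper * sig * (1 - sig) *
                                            (cache$x - p$midpoint) * s)))
  } else if (k == "patch_embed") {
    n <- cache$n; P <- l$cfg$n_patches; pt <- l$cfg$patch
    dpos <- array(0, dim(p$pos))
    for (q in seq_len(P)) dpos[q, ] <- colSums(dy[, q, , drop = FALSE][, 1, ])
    dym <- dy; dim(dym) <- c(n * P, l$cfg$hidden)
    dW <- crossprod(cache$xtm, dym)
    db <- colSums(dym)
    dxt <- dym %*% t(p$W)
    dim(dxt) <- c(n, P, pt)
    dxp <- array(0, c(n, l$cfg$pad_to))
    for (q in seq_len(P))
      dxp[, ((q - 1L) * pt + 1L):(q * pt)] <- dxt[, q, ]
    dx <- dxp[, seq_len(cache$L), drop = FALSE]
    dim(dx) <- c(n, cache$L, 1L)
    list(dx = dx, grads = list(W = dW, b = db, pos = dpos))
  } else if (k == "transformer_block") {
    tf_block_backward(l, cache, dy)
  } else if (k == "meanpool_tokens") {
    dm <- cache$dm
    dx <- array(0, dm)
    for (q in seq_len(dm[2])) dx[, q, ] <- dy / dm[2]
    list(dx = dx, grads = list())
  } else stop2("unknown layer kind: ", k)
}

#' Run a network forward
#'
#' @param model A built `sers_nn`.
#' @param x Input batch (matrix or 3-D array).
#' @param training Enable training-only behavior (dropout).
#' @return `nn_forward()`: list with `out` and per-layer `caches`;
#'   `nn_predict()`: the output only.
#' @export
nn_forward <- function(model, x, training = FALSE) {
  stopifnot(isTRUE(model$built))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    fw <- nn_layer_forward(model$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- nn_layer_backward(model$layers[[i]], caches[[i]], dout)
    dout <- bw$dx
    grads[[i]] <- bw$grads
  }
  list(dx = dout, grads = grads)
}

#' @rdname nn_forward
#' @param batch_size Prediction batch size.
#' @export
nn_predict <- function(model, x, batch_size = 1024L) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  outs <- vector("list", ceiling(n / batch_size))
  bi <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx, , , drop = FALSE]
    bi <- bi + 1L
    outs[[bi]] <- nn_forward(model, xb, training = FALSE)$out
  }
  do.call(rbind, outs)
}

# ---- losses ----------------------------------------------------------------

nn_loss <- function(pred, y, loss) {
  if (is.null(dim(y)) && !is.null(dim(pred))) dim(y) <- dim(pred)
  d <- pred - y
  switch(loss,
         mse = list(value = mean(d^2), grad = 2 * d / length(d)),
         mae = list(value = mean(abs(d)), grad = sign(d) / length(d)),
         stop2("unknown loss: ", loss))
}

# ---- optimizers ------------------------------------------------------------

opt_create <- function(model, kind = c("adam", "nadam"), lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  kind <- match.arg(kind)
  state <- lapply(model$layers, function(l)
    lapply(l$params, function(p)
      list(m = array(0, dim(p) %||% length(p)),
           v = array(0, dim(p) %||% length(p)))))
  list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, state = state)
}

opt_step <- function(opt, model, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      st <- opt$state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / bc1
      vhat <- st$v / bc2
      upd <- if (opt$kind == "nadam")
        (b1 * mhat + (1 - b1) * g / bc1) / (sqrt(vhat) + opt$eps)
      else mhat / (sqrt(vhat) + opt$eps)
      p0 <- model$layers[[i]]$params[[nm]]
      np <- p0 - opt$lr * upd
      dim(np) <- dim(p0)  # keep scalars scalar (state arrays carry dim 1)
      model$layers[[i]]$params[[nm]] <- np
      opt$state[[i]][[nm]] <- st
    }
  }
  list(opt = opt, model = model)
}

# ---- training loop ---------------------------------------------------------

take_rows <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx, , , drop = FALSE]
}

#' Train a network by mini-batch gradient descent
#'
#' Shuffled mini-batches, Adam or Nadam updates, optional validation
#' monitoring with early stopping (patience in epochs) and checkpointing of
#' the best-validation-loss weights, which are restored at the end. Fully
#' deterministic under `seed`.
#'
#' @param model A built `sers_nn`.
#' @param x,y Training inputs and targets (`y` vector or matrix).
#' @param x_val,y_val Optional validation data.
#' @param loss `"mae"` or `"mse"`.
#' @param optimizer `"adam"` or `"nadam"`.
#' @param lr Learning rate.
#' @param epochs,batch_size Training schedule.
#' @param patience Early-stopping patience in epochs (`Inf` to disable).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return List with the trained `model`, a `history` data frame
#'   (epoch, train_loss, val_loss) and `best_val`.
#' @export
nn_fit <- function(model, x, y, x_val = NULL, y_val = NULL, loss = "mae",
                   optimizer = "adam", lr = 1e-3, epochs = 10L,
                   batch_size = 32L, patience = Inf, seed = 1,
                   verbose = FALSE) {
  stopifnot(isTRUE(model$built))
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  if (is.matrix(y)) stopifnot(nrow(y) == n) else stopifnot(length(y) == n)
  opt <- opt_create(model, optimizer, lr)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- NULL
  wait <- 0L
  with_seed(derive_seed(seed, "fit"), {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        b <- idx[start:min(start + batch_size - 1L, n)]
        xb <- take_rows(x, b)
        yb <- if (is.matrix(y)) y[b, , drop = FALSE] else y[b]
        fw <- nn_forward(model, xb, training = TRUE)
        lo <- nn_loss(fw$out, yb, loss)
        bw <- nn_backward(model, fw$caches, lo$grad)
        st <- opt_step(opt, model, bw$grads)
        opt <- st$opt
        model <- st$model
        ep_loss <- ep_loss + lo$value
        nb <- nb + 1L
      }
      vl <- NA_real_
      if (!is.null(x_val)) {
        pv <- nn_predict(model, x_val)
        vl <- nn_loss(pv, y_val, loss)$value
        if (vl < best_val - 1e-12) {
          best_val <- vl
          best_params <- lapply(model$layers, function(l) l$params)
          wait <- 0L
        } else wait <- wait + 1L
      }
      history[ep, ] <- list(ep, ep_loss / nb, vl)
      if (verbose)
        message(sprintf("epoch %d: train %.5f val %.5f", ep, ep_loss / nb, vl))
      if (wait >= patience) break
    }
  })
  if (!is.null(best_params))
    for (i in seq_along(model$layers))
      model$layers[[i]]$params <- best_params[[i]]
  list(model = model, history = history,
       best_val = if (is.finite(best_val)) best_val else NA_real_)
}
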