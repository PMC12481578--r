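# Transformer building blocks for the 1-D vision transformer regressor.
# Pre-layer-norm blocks: x + Drop(MHSA(LN(x))), then x + Drop(MLP(LN(x)))
# with GELU in the MLP. Attention loops over (sample, head) pairs; the
# per-pair matrices are tiny (n_patches^2), so the loop cost is negligible
# next to the dense projections.

addb <- function(m, b) m + rep(b, each = nrow(m))

ln_forward <- function(xm, g, b, eps = 1e-5) {
  mu <- rowMeans(xm)
  xc <- xm - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  list(y = addb(xhat * rep(g, each = nrow(xm)), b), xhat = xhat, sd = sd)
}

ln_backward <- function(dy, xhat, sd, g) {
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
  list(dx = dx, dg = dg, db = db)
}

#' Transformer and patch-embedding layers
#'
#' `layer_patch_embed()` splits a length-L single-channel input into
#' non-overlapping patches (right-padding with zeros to the next patch
#' multiple so no data is discarded), linearly embeds each patch and adds a
#' learnable positional embedding. `layer_transformer_block()` is a
#' pre-layer-norm block with multi-head self-attention and a GELU MLP.
#' `layer_meanpool_tokens()` averages token embeddings for the regression
#' head.
#'
#' @param patch Patch width in grid points.
#' @param hidden Embedding dimension.
#' @export
layer_patch_embed <- function(patch = 25, hidden = 64) {
  list(kind = "patch_embed", cfg = list(patch = as.integer(patch),
                                        hidden = as.integer(hidden)))
}

#' @rdname layer_patch_embed
#' @param heads Number of attention heads (must divide `hidden`).
#' @param mlp_hidden Width of the block MLP.
#' @param dropout Dropout rate applied after attention and MLP.
#' @export
layer_transformer_block <- function(heads = 6, mlp_hidden = 128,
                                    dropout = 0.1) {
  list(kind = "transformer_block",
       cfg = list(heads = as.integer(heads),
                  mlp_hidden = as.integer(mlp_hidden), dropout = dropout))
}

#' @rdname layer_patch_embed
#' @export
layer_meanpool_tokens <- function() list(kind = "meanpool_tokens", cfg = list())

#' Number of patches for a given input length
#'
#' Inputs are right-padded with zeros to the next multiple of the patch
#' width, so every grid point contributes to some patch.
#'
#' @param input_dim Input length in grid points.
#' @param patch Patch width.
#' @export
vit_patch_count <- function(input_dim, patch = 25) {
  as.integer(ceiling(input_dim / patch))
}

tf_block_forward <- function(l, x, training) {
  p <- l$params
  dm <- dim(x); n <- dm[1]; P <- dm[2]; H <- dm[3]
  nh <- l$cfg$heads; dh <- l$cfg$head_dim; scale <- 1 / sqrt(dh)
  xm <- x; dim(xm) <- c(n * P, H)
  ln1 <- ln_forward(xm, p$g1, p$be1)
  u <- ln1$y
  Q <- addb(u %*% p$Wq, p$bq)
  K <- addb(u %*% p$Wk, p$bk)
  V <- addb(u %*% p$Wv, p$bv)
  O <- matrix(0, n * P, nh * dh)
  A_all <- vector("list", n * nh)
  for (i in seq_len(n)) {
    rows <- i + (0:(P - 1L)) * n
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      qb <- Q[rows, cols, drop = FALSE]
      kb <- K[rows, cols, drop = FALSE]
      S <- tcrossprod(qb, kb) * scale
      S <- S - apply(S, 1, max)
      A <- exp(S)
      A <- A / rowSums(A)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      A_all[[(i - 1L) * nh + h]] <- A
    }
  }
  attn <- addb(O %*% p$Wo, p$bo)
  mask1 <- NULL
  if (training && l$cfg$dropout > 0) {
    mask1 <- matrix((stats::runif(length(attn)) >= l$cfg$dropout) /
                      (1 - l$cfg$dropout), nrow(attn))
    attn <- attn * mask1
  }
  h1 <- xm + attn
  ln2 <- ln_forward(h1, p$g2, p$be2)
  v2 <- ln2$y
  m1 <- addb(v2 %*% p$W1, p$b1)
  a1 <- act_forward("gelu", m1)
  m2 <- addb(a1 %*% p$W2, p$b2)
  mask2 <- NULL
  if (training && l$cfg$dropout > 0) {
    mask2 <- matrix((stats::runif(length(m2)) >= l$cfg$dropout) /
                      (1 - l$cfg$dropout), nrow(m2))
    m2 <- m2 * mask2
  }
  y <- h1 + m2
  dim(y) <- dm
  list(out = y,
       cache = list(dm = dm, ln1 = ln1, ln2 = ln2, u = u, Q = Q, K = K,
                    V = V, O = O, A_all = A_all, h1 = h1, v2 = v2, m1 = m1,
                    a1 = a1, mask1 = mask1, mask2 = mask2))
}

tf_block_backward <- function(l, cache, dy) {
  p <- l$params
  dm <- cache$dm; n <- dm[1]; P <- dm[2]; H <- dm[3]
  nh <- l$cfg$heads; dh <- l$cfg$head_dim; scale <- 1 / sqrt(dh)
  dym <- dy; dim(dym) <- c(n * P, H)
  # MLP branch
  dm2 <- dym
  if (!is.null(cache$mask2)) dm2 <- dm2 * cache$mask2
  dW2 <- crossprod(cache$a1, dm2)
  db2 <- colSums(dm2)
  da1 <- dm2 %*% t(p$W2)
  dm1 <- da1 * act_grad("gelu", cache$m1)
  dW1 <- crossprod(cache$v2, dm1)
  db1 <- colSums(dm1)
  dv2 <- dm1 %*% t(p$W1)
  l2 <- ln_backward(dv2, cache$ln2$xhat, cache$ln2$sd, p$g2)
  dh1 <- dym + l2$dx
  # attention branch
  dattn <- dh1
  if (!is.null(cache$mask1)) dattn <- dattn * cache$mask1
  dWo <- crossprod(cache$O, dattn)
  dbo <- colSums(dattn)
  dO <- dattn %*% t(p$Wo)
  dQ <- matrix(0, n * P, nh * dh); dK <- dQ; dV <- dQ
  for (i in seq_len(n)) {
    rows <- i + (0:(P - 1L)) * n
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A_all[[(i - 1L) * nh + h]]
      dOb <- dO[rows, cols, drop = FALSE]
      vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * scale
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * scale
    }
  }
  du <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  dWq <- crossprod(cache$u, dQ); dbq <- colSums(dQ)
  dWk <- crossprod(cache$u, dK); dbk <- colSums(dK)
  dWv <- crossprod(cache$u, dV); dbv <- colSums(dV)
  l1 <- ln_backward(du, cache$ln1$xhat, cache$ln1$sd, p$g1)
  dxm <- dh1 + l1$dx
  dim(dxm) <- dm
  list(dx = dxm,
       grads = list(g1 = l1$dg, be1 = l1$db, Wq = dWq, bq = dbq, Wk = dWk,
                    bk = dbk, Wv = dWv, bv = dbv, Wo = dWo, bo = dbo,
                    g2 = l2$dg, be2 = l2$db, W1 = dW1, b1 = db1, W2 = dW2,
                    b2 = db2))
}
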