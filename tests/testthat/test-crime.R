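test_that("cosine similarity follows its closed form and invariances", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
  expect_equal(cosine_similarity(1:3, 4:6), 0.974632, tolerance = 5e-7)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(cosine_similarity(3.7 * a, b), cosine_similarity(a, b))
  expect_equal(cosine_similarity(a, 0.2 * b), cosine_similarity(a, b))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

make_archetypes <- function(n = 60, d = 40, gap = 2, noise = 0.05,
                            seed = 9) {
  set.seed(seed)
  a1 <- runif(d)
  a2 <- runif(d) + gap
  x <- rbind(matrix(rep(a1, each = n / 2), n / 2),
             matrix(rep(a2, each = n / 2), n / 2)) +
    matrix(rnorm(n * d, 0, noise), n)
  list(x = x, planted = rep(1:2, each = n / 2))
}

test_that("the VAE latent space separates planted explanation archetypes", {
  arc <- make_archetypes()
  lat <- fit_latent(arc$x, vae_spec(), seed = 4)
  expect_equal(dim(lat), c(60, 2))
  lab <- cluster_contexts(lat, k = 2, seed = 4)
  expect_equal(ari_oracle(lab, arc$planted), 1)
  expect_gt(silhouette_score(lat, lab), 0.5)
  # deterministic under the seed
  lat2 <- fit_latent(arc$x, vae_spec(), seed = 4)
  expect_identical(lat, lat2)
  # the automatic context count finds the two archetypes
  lab_auto <- cluster_contexts(lat, k = "auto", seed = 4)
  expect_equal(attr(lab_auto, "k"), 2)
})

test_that("degenerate latent inputs collapse with a warning", {
  x <- matrix(1, 12, 5)
  expect_warning(lat <- fit_latent(x, vae_spec(epochs = 1), seed = 1),
                 "identical")
  expect_equal(lat, matrix(0, 12, 2))
  expect_error(fit_latent(matrix(1, 5, 3)), "at least 10")
})

test_that("context clustering validates k and supports the extremes", {
  set.seed(2)
  lat <- matrix(rnorm(20), 10, 2)
  expect_error(cluster_contexts(lat, k = 1), "k >= 2")
  expect_error(cluster_contexts(lat, k = 11), "exceeds")
  each_own <- cluster_contexts(lat, k = 10, seed = 1)
  expect_equal(length(unique(each_own)), 10)
})

make_ctx_members <- function(n = 4, p = 100, sw = 20, seed = 3) {
  set.seed(seed)
  f <- function(X) rowSums(X)
  x <- matrix(runif(n * p), n)
  es <- lapply(seq_len(n), function(i)
    lime_explain(f, x[i, ], segment_width = sw, n_samples = 60, seed = i))
  list(es = es, x = x)
}

test_that("a context's mean explanation is the exact member average", {
  mem <- make_ctx_members()
  expect_warning(ctx <- context_regions(mem$es, mem$x, seed = 1),
                 "fewer segments")
  W <- do.call(rbind, lapply(mem$es, function(e) e$weights))
  expect_equal(ctx$mean_weights, colMeans(W))
  expect_equal(ctx$mean_spectrum, colMeans(mem$x))
  one <- suppressWarnings(context_regions(mem$es[1], mem$x[1, , drop = FALSE],
                                          seed = 1))
  expect_equal(one$mean_weights, mem$es[[1]]$weights)
  expect_equal(one$n_members, 1)
})

test_that("region ranking puts a dominant high-intensity segment first", {
  # construct a context with 20 segments; segment 7 has both the largest
  # weight and the largest mean intensity, so its cluster must rank first
  p <- 500; sw <- 25; ns <- 20
  x <- matrix(0.1, 2, p)
  x[, (6 * sw + 1):(7 * sw)] <- 1
  fake_expl <- function(w) {
    structure(list(weights = w, intercept = 0,
                   limits = rbind(lower = rep(0, ns), upper = rep(1, ns)),
                   segment_map = cbind(start = seq(1, p, sw),
                                       end = seq(sw, p, sw)),
                   prediction = 1), class = "sers_lime")
  }
  w <- rep(0.01, ns); w[7] <- 1
  ctx <- context_regions(list(fake_expl(w), fake_expl(w)), x, seed = 2)
  expect_lte(nrow(ctx$top_regions), 5)
  top1 <- ctx$top_regions[1, ]
  expect_true(top1["start"] <= 6 * sw + 1 && top1["end"] >= 7 * sw)
  expect_equal(nrow(ctx$top_regions), 5)
})

test_that("context matching reduces to plain cosine under uniform weights", {
  p <- 120
  set.seed(5)
  refs <- rbind(a = runif(p), b = runif(p))
  sm <- cbind(start = seq(1, p, 20), end = seq(20, p, 20))
  ctx <- structure(list(mean_weights = rep(0.5, 6),
                        mean_spectrum = runif(p), segment_map = sm),
                   class = "sers_context")
  m <- match_context(ctx, refs)
  plain <- vapply(1:2, function(i)
    cosine_similarity(ctx$mean_spectrum, refs[i, ]), numeric(1))
  expect_equal(sort(m$cosine, decreasing = TRUE),
               sort(plain, decreasing = TRUE))
  # a reference identical to the context spectrum scores 1 whatever the
  # weights
  ctx$mean_weights <- runif(6)
  m2 <- match_context(ctx, rbind(self = ctx$mean_spectrum, other = refs[1, ]))
  expect_equal(m2$cosine[m2$analyte == "self"], 1)
  expect_equal(m2$analyte[1], "self")
  expect_error(match_context(ctx, refs[, 1:50]), "grid length")
})
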