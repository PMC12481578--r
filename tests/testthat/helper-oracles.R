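# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense base-R linear algebra, sliding-window
# polynomial fits, and direct correlation sums.

# Dense iteratively reweighted penalized least squares (asymmetric
# least-squares baseline), base R only.
dense_als_oracle <- function(y, lam = 1000, p = 0.1, n_iter = 10) {
  m <- length(y)
  D <- diff(diag(m), differences = 2)
  P <- lam * t(D) %*% D
  w <- rep(1, m)
  z <- y
  for (i in seq_len(n_iter)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  as.numeric(z)
}

# Savitzky-Golay oracle: per-window least-squares polynomial fit in the
# centered sample index, derivative = deriv! * coefficient.
polyfit_sg_oracle <- function(y, window, polyorder, deriv) {
  half <- (window - 1) / 2
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    fit <- stats::lm(y[idx] ~ poly(idx - i, polyorder, raw = TRUE))
    out[i] <- factorial(deriv) * stats::coef(fit)[deriv + 1]
  }
  out
}

# Direct cross-correlation with "same" zero padding (pad_left =
# floor((k-1)/2)), single channel.
direct_xcorr_oracle <- function(x, kernel, bias = 0) {
  k <- length(kernel)
  pl <- (k - 1) %/% 2
  L <- length(x)
  xp <- c(rep(0, pl), x, rep(0, k - 1 - pl))
  vapply(seq_len(L), function(t) sum(xp[t:(t + k - 1)] * kernel) + bias,
         numeric(1))
}

# Adjusted Rand index oracle comes from mclust (tests only).
ari_oracle <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_no_error <- function(expr) expect_error(expr, NA)
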