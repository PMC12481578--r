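#' Derive a reproducible child seed
#'
#' Mixes a master seed with one or more string/integer keys into a new seed in
#' `[1, 2^31 - 2]`. Used throughout the package so that every stochastic stage
#' (simulation, pairing, weight initialization, shuffling, perturbation) draws
#' from an independent, reproducible stream derived from one master seed.
#'
#' @param seed Integer master seed.
#' @param ... Keys (coerced to character) identifying the consumer.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(7, "simulate", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(vapply(list(...), function(k) paste(as.character(k), collapse = ","),
                      character(1)), collapse = "/")
  x <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(key)) x <- (x * 31 + ch) %% 2147483647
  as.integer(x %% 2147483645) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

assert_finite_vector <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x) || any(!is.finite(x)))
    stop2(what, " must be a finite numeric vector")
  invisible(x)
}
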