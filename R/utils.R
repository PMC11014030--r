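#' @importFrom stats median quantile sd rnorm runif rpois rlnorm pnorm qnorm
#'   qt qf lm approx integrate convolve filter complete.cases aov
#'   wilcox.test t.test
#' @importFrom utils read.csv write.csv packageVersion combn
#' @importFrom grDevices adjustcolor
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Interquartile range with linear-interpolation quantiles (type 7), the
# convention used for both artifact thresholds and profile standardization.
iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

# Dilate a logical mask by `w` samples on each side of every TRUE run.
dilate_mask <- function(mask, w) {
  n <- length(mask)
  if (w <= 0L || !any(mask)) return(mask)
  idx <- which(mask)
  starts <- pmax(idx - w, 1L)
  ends <- pmin(idx + w, n)
  delta <- integer(n + 1L)
  for (k in seq_along(starts)) {
    delta[starts[k]] <- delta[starts[k]] + 1L
    delta[ends[k] + 1L] <- delta[ends[k] + 1L] - 1L
  }
  cumsum(delta[seq_len(n)]) > 0L
}

# Trapezoidal integral of regularly sampled y with spacing h.
trapz_reg <- function(y, h) {
  n <- length(y)
  if (n < 2L) return(0)
  h * (sum(y) - (y[1L] + y[n]) / 2)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(TRUE)
}
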