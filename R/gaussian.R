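#' Gaussian kernel for a given odd side length
#'
#' One-dimensional normalized Gaussian tap weights for a `k`-tap kernel.
#' When `sigma` is `NULL` it is derived from the kernel size by the
#' standard image-processing convention `sigma = 0.3 * ((k - 1)/2 - 1) +
#' 0.8`, so that a stated kernel size fully determines the blur.
#'
#' @param k odd positive integer side length.
#' @param sigma optional positive standard deviation in pixels.
#' @return numeric vector of `k` weights summing to 1.
#' @export
gaussian_kernel <- function(k, sigma = NULL) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("kernel size must be odd and positive")
  if (is.null(sigma)) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  r <- (k - 1L) / 2L
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Reflect-101 index for 1-based positions 1..n extended by the pad radius:
# ... 3 2 | 1 2 3 ... n | n-1 n-2 ... (periodic for radii exceeding n - 1).
reflect_idx <- function(n, r) {
  if (n == 1L) return(rep(1L, 1L + 2L * r))
  i <- ((1L - r):(n + r)) - 1L
  p <- 2L * n - 2L
  m <- ((i %% p) + p) %% p
  ifelse(m >= n, p - m, m) + 1L
}

# Separable convolution of a matrix with a 1-D kernel along both axes,
# reflect-101 border handling.
conv_sep <- function(m, w) {
  k <- length(w)
  r <- (k - 1L) / 2L
  # rows (vertical pass)
  p <- m[reflect_idx(nrow(m), r), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_len(k)) out <- out + w[t] * p[t:(t + nrow(m) - 1L), , drop = FALSE]
  # columns (horizontal pass)
  p <- out[, reflect_idx(ncol(m), r), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_len(k)) out <- out + w[t] * p[, t:(t + ncol(m) - 1L), drop = FALSE]
  out
}

#' Gaussian blur of a matrix or image array
#'
#' Separable Gaussian filter with a `k x k` truncated kernel and
#' reflect-101 border handling (no dark halo is injected at image edges).
#' Input values are treated as continuous; callers round back to 8 bits
#' where the pipeline requires it.
#'
#' @param x numeric matrix `[h, w]` or array `[h, w, c]`.
#' @param k odd kernel side length.
#' @param sigma optional standard deviation, see [gaussian_kernel()].
#' @return blurred object of the same shape.
#' @export
gaussian_blur <- function(x, k, sigma = NULL) {
  w <- gaussian_kernel(k, sigma)
  if (length(dim(x)) == 3L) {
    out <- x
    for (c in seq_len(dim(x)[3])) out[, , c] <- conv_sep(x[, , c], w)
    out
  } else {
    conv_sep(as.matrix(x), w)
  }
}
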