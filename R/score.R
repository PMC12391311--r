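#' Scoring configuration
#'
#' @param sigma2_max maximum variance used to normalize the variance
#'   penalty (default 5000, on the squared 0..255 intensity scale). The
#'   smaller `sigma2_max`, the faster the score falls with increasing
#'   variance of the left/right differences.
#' @param intensity_scale full-scale intensity normalizing the mean
#'   absolute difference (255 for 8-bit images), keeping the mean-based
#'   score term in \[0, 1\].
#' @return an object of class `score_config`.
#' @export
score_config <- function(sigma2_max = 5000, intensity_scale = 255) {
  stopifnot(sigma2_max > 0, intensity_scale > 0)
  structure(list(sigma2_max = sigma2_max, intensity_scale = intensity_scale),
            class = "score_config")
}

# Column containing a real x coordinate: 0-based column j iff
# j < x < j + 1. An x on a pixel boundary lies in no column.
column_containing <- function(x) {
  j <- floor(x)
  if (j < x && x < j + 1) j else NA_integer_
}

#' Pair left-half pixels with their mirrored right-half counterparts
#'
#' For every mask-foreground pixel whose center lies left of the mirror
#' midline, reflects its center about `mask$midline_x`; when the mirror
#' position falls on a mask-foreground pixel inside the image, the pair of
#' intensities (left value, mirrored right value) is emitted. Pixels in
#' the column containing the midline (if the midline crosses a pixel
#' interior) are excluded on both sides to avoid self-pairing.
#'
#' @param d a `diff_map`.
#' @param mask a `face_mask` carrying the midline.
#' @return a list with numeric vectors `L` and `R` and the pair count `n`.
#' @export
paired_half_pixels <- function(d, mask) {
  if (!any(mask$raster)) stop("empty mask: no pixels to pair")
  h <- nrow(mask$raster); w <- ncol(mask$raster)
  m <- mask$midline_x
  if (m <= 0 || m >= w) stop("midline outside image")
  mid_col <- column_containing(m)

  fg <- which(mask$raster, arr.ind = TRUE)
  col0 <- fg[, 2] - 1L                       # 0-based column
  keep <- (col0 + 0.5) < m
  if (!is.na(mid_col)) keep <- keep & col0 != mid_col
  fg <- fg[keep, , drop = FALSE]
  col0 <- col0[keep]
  # nearest pixel column to the reflected center 2m - (col0 + 0.5)
  mir <- as.integer(round(2 * m - col0 - 1))
  ok <- mir >= 0L & mir < w
  if (!is.na(mid_col)) ok <- ok & mir != mid_col
  fg <- fg[ok, , drop = FALSE]; mir <- mir[ok]
  ok2 <- mask$raster[cbind(fg[, 1], mir + 1L)]
  fg <- fg[ok2, , drop = FALSE]; mir <- mir[ok2]
  if (nrow(fg) == 0L) {
    stop("no valid left/right pixel pairs: symmetry score undefined")
  }
  list(L = d$raster[fg],
       R = d$raster[cbind(fg[, 1], mir + 1L)],
       n = nrow(fg))
}

#' Mean-difference symmetry term
#'
#' One minus the mean absolute difference between left and mirrored right
#' intensities, normalized by the full-scale intensity so the result lies
#' in \[0, 1\] (1 = identical halves).
#'
#' @param L,R paired intensity vectors from [paired_half_pixels()].
#' @param cfg a `score_config`.
#' @return scalar in \[0, 1\].
#' @export
compute_s_mean <- function(L, R, cfg = score_config()) {
  stopifnot(length(L) == length(R), length(L) >= 1L)
  1 - mean(abs(L - R)) / cfg$intensity_scale
}

#' Variance weight of the symmetry score
#'
#' `1 - min(sigma2 / sigma2_max, 1)` with `sigma2` the population variance
#' of the signed differences `L - R` on the raw 0..255 scale. Penalizes
#' spatially irregular asymmetries beyond their mean magnitude; reaches 0
#' at `sigma2 >= sigma2_max`.
#'
#' @param differences signed paired differences `L - R`.
#' @param cfg a `score_config`.
#' @return scalar weight in \[0, 1\].
#' @export
variance_weight <- function(differences, cfg = score_config()) {
  stopifnot(length(differences) >= 1L)
  s2 <- mean((differences - mean(differences))^2)
  1 - min(s2 / cfg$sigma2_max, 1)
}

#' Variance-weighted left/right symmetry score
#'
#' Combines the mean-difference term and the variance weight into the
#' final score `S = S_mean * (1 - min(sigma2 / sigma2_max, 1))`, ranging
#' from 0 (low symmetry) to 1 (high symmetry).
#'
#' @param d a `diff_map`.
#' @param mask a `face_mask` carrying the midline.
#' @param cfg a `score_config`.
#' @param expression_index expression index recorded in the result.
#' @return an object of class `symmetry_result` with fields `s_mean`,
#'   `variance`, `score`, `n_valid` and `expression_index`.
#' @export
symmetry_score <- function(d, mask, cfg = score_config(),
                           expression_index = NA_integer_) {
  p <- paired_half_pixels(d, mask)
  diffs <- p$L - p$R
  s_mean <- compute_s_mean(p$L, p$R, cfg)
  s2 <- mean((diffs - mean(diffs))^2)
  structure(
    list(s_mean = s_mean,
         variance = s2,
         score = s_mean * variance_weight(diffs, cfg),
         n_valid = p$n,
         expression_index = as.integer(expression_index)),
    class = "symmetry_result"
  )
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf(
    "<symmetry_result> expr %s: S = %.4f (S_mean %.4f, variance %.1f, N = %d)\n",
    ifelse(is.na(x$expression_index), "?", x$expression_index),
    x$score, x$s_mean, x$variance, x$n_valid))
  invisible(x)
}
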