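#' Processed difference image
#'
#' Single-channel 8-bit raster holding the blurred, amplified and clipped
#' absolute difference between the neutral reference and an aligned
#' expression image — the common input to heatmap rendering and symmetry
#' scoring.
#'
#' @param raster numeric matrix `[h, w]` with values in 0..255.
#' @param amplification integer amplification factor applied.
#' @param smooth_kernel odd kernel side length used for smoothing.
#' @return an object of class `diff_map`.
#' @export
diff_map <- function(raster, amplification = 5L, smooth_kernel = 111L) {
  raster <- as.matrix(raster)
  if (anyNA(raster) || min(raster) < 0 || max(raster) > 255) {
    stop("diff_map: values must be finite and in [0, 255]")
  }
  structure(list(raster = raster,
                 amplification = as.integer(amplification),
                 smooth_kernel = as.integer(smooth_kernel)),
            class = "diff_map")
}

#' @export
print.diff_map <- function(x, ...) {
  cat(sprintf("<diff_map> %dx%d px, kernel %d, amplification x%d, mean %.2f\n",
              ncol(x$raster), nrow(x$raster), x$smooth_kernel,
              x$amplification, mean(x$raster)))
  invisible(x)
}

#' Pre-blur an image before differencing
#'
#' Applies a slight 5x5 Gaussian blur to suppress high-frequency content
#' (facial hair, skin texture) that would otherwise dominate the pixelwise
#' difference between reference and expression image.
#'
#' @param image a `face_image`.
#' @param k odd kernel side length (default 5).
#' @return the blurred `face_image`.
#' @export
preblur <- function(image, k = 5L) {
  face_image(clip8(gaussian_blur(image$raster, k)),
             image$expression_index, image$visit_date)
}

#' Masked absolute difference, converted to grayscale
#'
#' Per-pixel absolute difference between the (pre-blurred) reference and
#' aligned expression image, computed per channel and collapsed to one
#' channel with Rec.601 luma weights (0.299, 0.587, 0.114). The mask is
#' applied to both images beforehand, so every pixel outside the mask is 0.
#'
#' @param ref,expr_aligned `face_image`s in identical (reference) dims.
#' @param mask a `face_mask` in the same dims.
#' @return numeric matrix `[h, w]` of raw grayscale differences in 0..255.
#' @export
abs_diff_gray <- function(ref, expr_aligned, mask) {
  if (!identical(dim(ref$raster), dim(expr_aligned$raster))) {
    stop("dimension mismatch between reference and expression image")
  }
  if (!identical(dim(mask$raster), dim(ref$raster)[1:2])) {
    stop("dimension mismatch between mask and images")
  }
  m <- mask$raster * 1
  d <- abs(ref$raster * rep(m, 3L) - expr_aligned$raster * rep(m, 3L))
  luma_gray(d)
}

#' Smooth and amplify a raw difference raster
#'
#' Gaussian-smooths the raw difference with a large `kernel x kernel` blur
#' (default 111), absorbing residual misalignment while preserving the
#' overall movement pattern, then multiplies by `factor` (default 5) with
#' saturation at 255. On the default 8-bit scale any smoothed difference of
#' 51 or more therefore saturates (51 x 5 = 255).
#'
#' @param raw numeric matrix of raw grayscale differences (0..255).
#' @param kernel odd smoothing kernel side length.
#' @param factor positive integer amplification factor.
#' @return a `diff_map`.
#' @export
smooth_amplify <- function(raw, kernel = 111L, factor = 5L) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) {
    stop("smoothing kernel must be odd and positive")
  }
  if (factor < 1) stop("amplification factor must be positive")
  sm <- clip8(gaussian_blur(as.matrix(raw), kernel))
  diff_map(pmin(sm * factor, 255), factor, kernel)
}

#' Rainbow heatmap of a difference map
#'
#' Renders the processed difference as an RGB image using a rainbow
#' (blue -> cyan -> green -> yellow -> red) color map: value 0 is pure
#' blue (no movement-related change), 255 pure red (saturated change). The
#' red channel is non-decreasing and the blue channel non-increasing in the
#' difference value, so hotter colors always mean larger differences.
#'
#' @param d a `diff_map`.
#' @return a `face_image` heatmap.
#' @export
render_heatmap <- function(d) {
  pal <- rainbow_palette()
  v <- as.integer(d$raster) + 1L
  h <- nrow(d$raster); w <- ncol(d$raster)
  out <- array(0L, dim = c(h, w, 3L))
  out[, , 1] <- matrix(pal[v, 1], h, w)
  out[, , 2] <- matrix(pal[v, 2], h, w)
  out[, , 3] <- matrix(pal[v, 3], h, w)
  face_image(out)
}

# 256 x 3 integer palette: piecewise-linear blue -> cyan -> green ->
# yellow -> red with monotone red (rising) and blue (falling) channels.
rainbow_palette <- function() {
  t <- (0:255) / 255
  ramp <- function(x) clip8(255 * x)
  r <- ramp(pmin(pmax((t - 0.50) / 0.25, 0), 1))
  g <- ramp(pmin(pmin(t / 0.25, 1), pmax((1 - t) / 0.25, 0)))
  b <- ramp(pmin(pmax((0.50 - t) / 0.25, 0), 1))
  cbind(r, g, b)
}

#' Mean movement intensity within the mask
#'
#' Mean processed-difference value over mask-foreground pixels. Low values
#' indicate a hesitantly performed expression whose high symmetry score may
#' not be justified; the pipeline flags (never deletes) such results via a
#' configurable threshold.
#'
#' @param d a `diff_map`.
#' @param mask a `face_mask` with at least one foreground pixel.
#' @return mean intensity (0..255).
#' @export
movement_intensity <- function(d, mask) {
  if (!any(mask$raster)) stop("empty mask: movement intensity undefined")
  mean(d$raster[mask$raster])
}

#' Write a difference map as a grayscale PNG
#' @param d a `diff_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_map <- function(d, path) {
  png::writePNG(d$raster / 255, path)
  invisible(path)
}
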