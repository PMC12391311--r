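#' Face mask container
#'
#' Binary raster isolating the analysis region, plus the real-valued pixel
#' column of the facial mirror midline.
#'
#' @param raster logical matrix `[h, w]`, `TRUE` = foreground.
#' @param midline_x real-valued x coordinate of the mirror axis.
#' @return an object of class `face_mask`.
#' @export
face_mask <- function(raster, midline_x) {
  stopifnot(is.matrix(raster), is.finite(midline_x))
  structure(list(raster = raster & TRUE, midline_x = as.numeric(midline_x)),
            class = "face_mask")
}

#' @export
print.face_mask <- function(x, ...) {
  cat(sprintf("<face_mask> %dx%d px, %d foreground px, midline x = %.2f\n",
              ncol(x$raster), nrow(x$raster), sum(x$raster), x$midline_x))
  invisible(x)
}

# Pixel-center coordinate grids (0-based): center of column j is j + 0.5,
# of row i is i + 0.5.
pixel_centers <- function(dims) {
  w <- as.integer(dims[1]); h <- as.integer(dims[2])
  list(x = matrix(rep(seq_len(w) - 0.5, each = h), h, w),
       y = matrix(rep(seq_len(h) - 0.5, times = w), h, w))
}

#' Build the facial analysis mask from 9 landmarks
#'
#' The mask is the union of a rectangular upper half and a half-elliptical
#' lower half covering the face. The defining landmarks are the four eye
#' corners (mesh 33, 133, 362, 263), nose bridge and tip (1, 0), upper and
#' lower lip centers (13, 14) and the chin (152). The rectangle spans
#' horizontally the eye-corner extent padded by `padding_frac` of its width
#' per side, and vertically from a forehead margin above the eye line down
#' to the midpoint between the eye line and the padded chin. The half-ellipse sits below that
#' midpoint with a horizontal semi-axis of half the padded rectangle width
#' and a vertical semi-axis reaching the padded chin. A pixel is foreground
#' when its center lies inside the analytic shape.
#'
#' The rectangle top is raised above the eye line by `brow_margin_frac`
#' of the eye-to-chin height (plus padding) so the eyebrow region is
#' covered; its exact position is immaterial since
#' [remove_brow_region()] trims everything above the brow line.
#'
#' @param lms a `landmark_set`.
#' @param dims `c(width, height)` of the mask raster (the reference dims).
#' @param padding_frac padding fraction per side (default 0.10).
#' @param brow_margin_frac forehead margin above the eye line as a
#'   fraction of the eye-to-chin height (default 0.25).
#' @return a `face_mask` (midline from [mask_midline()]).
#' @export
build_mask <- function(lms, dims, padding_frac = 0.10,
                       brow_margin_frac = 0.25) {
  eyes <- lm_xy(lms, c(mesh_idx$eye_outer_left, mesh_idx$eye_inner_left,
                       mesh_idx$eye_inner_right, mesh_idx$eye_outer_right))
  chin <- lm_xy(lms, mesh_idx$chin)
  nine <- lm_xy(lms, mesh_idx$mask)
  if (max(dist(nine)) < 1e-9) stop("degenerate geometry: mask landmarks coincide")
  eye_y <- mean(eyes[, 2])
  width0 <- max(eyes[, 1]) - min(eyes[, 1])
  height0 <- chin[2] - eye_y
  if (width0 < 1e-9 || height0 < 1e-9) {
    stop("degenerate geometry: zero-extent face region")
  }
  pad_x <- padding_frac * width0
  pad_y <- padding_frac * height0
  x0 <- min(eyes[, 1]) - pad_x
  x1 <- max(eyes[, 1]) + pad_x
  top <- eye_y - brow_margin_frac * height0 - pad_y
  chin_pad <- chin[2] + pad_y
  junction <- (eye_y + chin_pad) / 2
  cx <- (x0 + x1) / 2
  a <- (x1 - x0) / 2            # horizontal semi-axis
  b <- chin_pad - junction      # vertical semi-axis

  g <- pixel_centers(dims)
  in_rect <- g$x >= x0 & g$x <= x1 & g$y >= top & g$y <= junction
  in_ell <- g$y > junction &
    ((g$x - cx) / a)^2 + ((g$y - junction) / b)^2 <= 1
  face_mask(in_rect | in_ell, mask_midline(lms))
}

#' Remove the above-eyebrow region from a mask
#'
#' Clears every mask pixel above the eyebrow cut line, excluding hair and
#' forehead areas whose movement is unrelated to the assessed expression.
#' The cut is the single horizontal line `y_cut = max(y)` over the ten
#' eyebrow landmarks (`mesh_idx$brow`); foreground survives only at rows
#' `y >= y_cut`.
#'
#' @param mask a `face_mask`.
#' @param lms the `landmark_set` providing the eyebrow landmarks.
#' @return the cut `face_mask`.
#' @export
remove_brow_region <- function(mask, lms) {
  y_cut <- max(lm_xy(lms, mesh_idx$brow)[, 2])
  rows <- seq_len(nrow(mask$raster)) - 1L   # 0-based row index = pixel y
  keep <- rows >= y_cut
  out <- mask$raster
  out[!keep, ] <- FALSE
  face_mask(out, mask$midline_x)
}

#' Facial mirror midline
#'
#' The x coordinate of the mirror axis, taken as the mean x over the
#' facial-midline landmarks (nose bridge/tip, lip centers, chin:
#' mesh 1, 0, 13, 14, 152). Using midline landmarks rather than the mask
#' bounding box keeps the axis robust to asymmetric mask extents caused by
#' palsy.
#'
#' @param lms a `landmark_set`.
#' @return real-valued x coordinate of the midline.
#' @export
mask_midline <- function(lms) {
  mean(lm_xy(lms, mesh_idx$midline)[, 1])
}

#' Write a mask as an 8-bit PNG (0/255)
#' @param mask a `face_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$raster * 1, path)
  invisible(path)
}
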