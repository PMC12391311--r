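#' Similarity transform
#'
#' A 4-degree-of-freedom planar transform `p -> scale * R(rotation) p +
#' translation`, used to register an expression image to the neutral
#' reference. Shear and anisotropic scaling are deliberately excluded: the
#' registration normalizes head pose and camera distance, which a
#' translation + rotation + isotropic scale fully describe.
#'
#' @param scale positive scalar.
#' @param rotation rotation angle in radians (positive = clockwise on
#'   screen, since y points down).
#' @param translation numeric `c(tx, ty)` in pixels.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  stopifnot(is.finite(scale), scale > 0, is.finite(rotation),
            length(translation) == 2L, all(is.finite(translation)))
  structure(
    list(scale = scale, rotation = rotation,
         translation = as.numeric(translation)),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, rotation %.6g rad, translation (%.6g, %.6g)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Apply, invert and compose similarity transforms
#'
#' @param t,t1,t2 `similarity_transform` objects.
#' @param pts numeric `n x 2` matrix of points.
#' @return `apply_transform`: the transformed `n x 2` matrix.
#'   `invert_transform`: the inverse transform. `compose_transform`: the
#'   transform equivalent to applying `t1` first, then `t2`.
#' @export
apply_transform <- function(t, pts) {
  pts <- rbind(pts)
  out <- t$scale * pts %*% t(rot_mat(t$rotation))
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(t) {
  s <- 1 / t$scale
  tr <- -s * (rot_mat(-t$rotation) %*% t$translation)
  similarity_transform(s, -t$rotation, as.numeric(tr))
}

#' @rdname apply_transform
#' @export
compose_transform <- function(t2, t1) {
  tr <- t2$scale * (rot_mat(t2$rotation) %*% t1$translation) + t2$translation
  similarity_transform(t2$scale * t1$scale, t1$rotation + t2$rotation,
                       as.numeric(tr))
}

#' Least-squares similarity alignment between two landmark sets
#'
#' Estimates the similarity transform mapping `src` points onto `dst`
#' points, minimizing the summed squared distances over all 478
#' correspondences. The closed form treats points as complex numbers: with
#' centered coordinates, the optimal `scale * exp(i * rotation)` is the
#' complex regression coefficient of dst on src; the translation maps the
#' src centroid onto the dst centroid. Exact on noiseless
#' similarity-transformed copies.
#'
#' @param src,dst `landmark_set` objects with corresponding points.
#' @return a `similarity_transform` such that `apply_transform(t,
#'   src$points)` approximates `dst$points` in least squares.
#' @export
estimate_alignment <- function(src, dst) {
  stopifnot(inherits(src, "landmark_set"), inherits(dst, "landmark_set"))
  zs <- complex(real = src$points[, 1], imaginary = src$points[, 2])
  zd <- complex(real = dst$points[, 1], imaginary = dst$points[, 2])
  ms <- mean(zs); md <- mean(zd)
  cs <- zs - ms; cd <- zd - md
  denom <- sum(Mod(cs)^2)
  if (denom < 1e-12) stop("degenerate source landmarks: all points coincident")
  a <- sum(Conj(cs) * cd) / denom
  tr <- md - a * ms
  similarity_transform(Mod(a), Arg(a), c(Re(tr), Im(tr)))
}

# Bilinear sampling of one channel at coordinates (x, y); pixel (i, j)
# carries its value at center (j + 0.5, i + 0.5) in 0-based coordinates.
# Out-of-source samples are 0.
sample_bilinear <- function(ch, x, y) {
  h <- nrow(ch); w <- ncol(ch)
  gx <- x - 0.5; gy <- y - 0.5
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  px <- function(i, j) {
    ok <- i >= 0 & i < h & j >= 0 & j < w
    v <- numeric(length(i))
    v[ok] <- ch[cbind(i[ok] + 1L, j[ok] + 1L)]
    v
  }
  (1 - fy) * ((1 - fx) * px(i0, j0)     + fx * px(i0, j0 + 1L)) +
       fy  * ((1 - fx) * px(i0 + 1L, j0) + fx * px(i0 + 1L, j0 + 1L))
}

warp_raster <- function(raster, t, out_dims) {
  w <- as.integer(out_dims[1]); h <- as.integer(out_dims[2])
  ti <- invert_transform(t)
  centers <- cbind(rep(seq_len(w) - 0.5, each = h),
                   rep(seq_len(h) - 0.5, times = w))
  src <- apply_transform(ti, centers)
  out <- array(0, dim = c(h, w, dim(raster)[3]))
  for (c in seq_len(dim(raster)[3])) {
    out[, , c] <- matrix(sample_bilinear(raster[, , c], src[, 1], src[, 2]),
                         h, w)
  }
  out
}

#' Warp a face image by a similarity transform
#'
#' Bilinearly resamples `image` into the output frame so that a feature at
#' source position `p` appears at `apply_transform(t, p)`. Pixels sampling
#' outside the source are 0 (black).
#'
#' @param image a `face_image`.
#' @param t a `similarity_transform`.
#' @param out_dims `c(width, height)` of the output raster.
#' @return a `face_image` with the same expression index and visit date.
#' @export
warp_image <- function(image, t, out_dims = image_dims(image)) {
  out <- warp_raster(image$raster, t, out_dims)
  face_image(clip8(out), image$expression_index, image$visit_date)
}

#' Scale a face to a 200-pixel interocular distance
#'
#' Uniformly rescales the image and its landmarks so the Euclidean distance
#' between the outer eye corners (mesh 33 and 263) equals
#' `target_distance` pixels, removing camera-distance and resolution
#' differences between photographs. The landmark distance is exact after
#' scaling; the raster is bilinearly resampled by the same factor.
#'
#' @param image a `face_image`.
#' @param lms the matching `landmark_set`.
#' @param target_distance target interocular distance in pixels.
#' @return a list with elements `image`, `lms` and `scale_factor`.
#' @export
interocular_scale <- function(image, lms, target_distance = 200) {
  d <- interocular_distance(lms)
  if (d < 1e-9) stop("degenerate geometry: coincident outer eye corners")
  f <- target_distance / d
  dims <- image_dims(image)
  if (abs(f - 1) < 1e-12) {
    return(list(image = image, lms = lms, scale_factor = 1))
  }
  out_dims <- pmax(1L, as.integer(round(dims * f)))
  img2 <- warp_image(image, similarity_transform(scale = f), out_dims)
  lms2 <- landmark_set(lms$points * f, out_dims)
  list(image = img2, lms = lms2, scale_factor = f)
}

#' Center an image on the reference canvas
#'
#' Places `image` centered on a canvas of `ref_dims`; content extending
#' beyond the canvas is cropped and landmark coordinates are shifted by the
#' same centering offset (so they may fall outside the canvas after a
#' crop). The offset is `floor((ref - src) / 2)` per axis, ties toward the
#' top-left.
#'
#' @param image a `face_image`.
#' @param lms the matching `landmark_set`.
#' @param ref_dims `c(width, height)` of the reference image.
#' @return a list with elements `image`, `lms` and `offset` (`c(dx, dy)`).
#' @export
center_on_canvas <- function(image, lms, ref_dims) {
  ref_w <- as.integer(ref_dims[1]); ref_h <- as.integer(ref_dims[2])
  stopifnot(ref_w > 0L, ref_h > 0L)
  d <- image_dims(image)
  off <- c(floor((ref_w - d["width"]) / 2), floor((ref_h - d["height"]) / 2))
  canvas <- array(0L, dim = c(ref_h, ref_w, 3L))
  # overlapping block in 0-based destination coordinates
  dx0 <- max(0L, off[1]); dx1 <- min(ref_w - 1L, off[1] + d["width"] - 1L)
  dy0 <- max(0L, off[2]); dy1 <- min(ref_h - 1L, off[2] + d["height"] - 1L)
  if (dx1 >= dx0 && dy1 >= dy0) {
    canvas[(dy0 + 1L):(dy1 + 1L), (dx0 + 1L):(dx1 + 1L), ] <-
      image$raster[(dy0 - off[2] + 1L):(dy1 - off[2] + 1L),
                   (dx0 - off[1] + 1L):(dx1 - off[1] + 1L), ]
  }
  pts <- lms$points
  pts[, 1] <- pts[, 1] + off[1]
  pts[, 2] <- pts[, 2] + off[2]
  list(image = face_image(canvas, image$expression_index, image$visit_date),
       lms = landmark_set(pts, c(ref_w, ref_h)),
       offset = unname(off))
}
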