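#' Face image container
#'
#' Wraps an 8-bit RGB raster together with its expression index (1 = neutral
#' reference, 2-9 = standardized expressions) and an optional visit date.
#' The raster is stored as an integer array of dimension height x width x 3
#' with values in 0..255.
#'
#' @param raster numeric or integer array `[h, w, 3]` (or `[h, w]`, promoted
#'   to three identical channels) with values in 0..255.
#' @param expression_index integer in 1..9.
#' @param visit_date optional `Date` (or string coercible to one).
#' @return an object of class `face_image`.
#' @export
face_image <- function(raster, expression_index = 1L, visit_date = NULL) {
  if (length(dim(raster)) == 2L) {
    raster <- array(rep(raster, 3L), dim = c(dim(raster), 3L))
  }
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] == 3L)
  r <- array(as.integer(round(raster)), dim = dim(raster))
  if (anyNA(r) || min(r) < 0L || max(r) > 255L) {
    stop("face_image: channel values must be finite and in [0, 255]")
  }
  ei <- as.integer(expression_index)
  if (ei < 1L || ei > 9L) stop("face_image: expression_index must be in 1..9")
  if (!is.null(visit_date)) visit_date <- as.Date(visit_date)
  structure(
    list(raster = r, expression_index = ei, visit_date = visit_date),
    class = "face_image"
  )
}

#' @export
print.face_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<face_image> %dx%d px, expression %d%s\n", d[2], d[1],
              x$expression_index,
              if (is.null(x$visit_date)) "" else paste0(", ", x$visit_date)))
  invisible(x)
}

#' Image dimensions as (width, height)
#' @param image a `face_image`.
#' @return integer vector `c(width, height)`.
#' @export
image_dims <- function(image) {
  d <- dim(image$raster)
  c(width = d[2], height = d[1])
}

#' Read a face image from PNG or JPEG
#'
#' @param path file path ending in .png, .jpg or .jpeg (case-insensitive).
#' @param expression_index,visit_date passed to [face_image()].
#' @return a `face_image`.
#' @export
read_face_image <- function(path, expression_index = 1L, visit_date = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) arr <- arr[, , 1:3]
  face_image(round(arr * 255), expression_index, visit_date)
}

#' Write a face image as PNG
#' @param image a `face_image`.
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_face_image <- function(image, path) {
  png::writePNG(image$raster / 255, path)
  invisible(path)
}

# Rec.601 luma conversion of an [h, w, 3] array to a single [h, w] matrix.
luma_gray <- function(raster) {
  0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
}

# Clamp-and-round to the 8-bit range.
clip8 <- function(x) {
  pmin(pmax(round(x), 0), 255)
}
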