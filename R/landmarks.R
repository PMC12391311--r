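#' Face-mesh landmark indices used by the pipeline
#'
#' Named 0-based indices into the 478-point face-mesh numbering scheme.
#' `left`/`right` refer to the image (viewer) side. The outer eye corners
#' (33, 263) are the temporal-most eye points and define the interocular
#' distance; the nine `mask` points define the analysis mask; the `midline`
#' points define the mirror axis; the `brow` points define the eyebrow cut.
#'
#' @format a named list of integer vectors.
#' @export
mesh_idx <- list(
  eye_outer_left  = 33L,
  eye_inner_left  = 133L,
  eye_inner_right = 362L,
  eye_outer_right = 263L,
  nose_bridge     = 1L,
  nose_tip        = 0L,
  lip_upper       = 13L,
  lip_lower       = 14L,
  chin            = 152L,
  mask    = c(33L, 133L, 362L, 263L, 1L, 0L, 13L, 14L, 152L),
  midline = c(1L, 0L, 13L, 14L, 152L),
  brow    = c(70L, 63L, 105L, 66L, 107L, 336L, 296L, 334L, 293L, 300L)
)

N_LANDMARKS <- 478L

#' Landmark set container
#'
#' Holds the 478 facial landmarks of one image in pixel coordinates
#' (0-based, origin top-left, y down), indexed by the face-mesh numbering
#' scheme (0..477).
#'
#' @param points numeric matrix `478 x 2` (columns x, y), row `i` holding
#'   mesh index `i - 1`.
#' @param source_dims integer `c(width, height)` of the image the points
#'   refer to.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, source_dims) {
  points <- as.matrix(points)
  if (nrow(points) != N_LANDMARKS || ncol(points) != 2L) {
    stop("landmark_set: expected a ", N_LANDMARKS, " x 2 point matrix, got ",
         nrow(points), " x ", ncol(points))
  }
  if (!all(is.finite(points))) stop("landmark_set: non-finite coordinates")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(
    list(points = points,
         source_dims = c(width = as.integer(source_dims[1]),
                         height = as.integer(source_dims[2]))),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points on %dx%d px image\n",
              nrow(x$points), x$source_dims[1], x$source_dims[2]))
  invisible(x)
}

#' Extract landmark coordinates by mesh index
#'
#' @param lms a `landmark_set`.
#' @param idx integer vector of 0-based mesh indices.
#' @return numeric matrix `length(idx) x 2` of (x, y) coordinates.
#' @export
lm_xy <- function(lms, idx) {
  idx <- as.integer(idx)
  if (any(idx < 0L) || any(idx >= N_LANDMARKS)) stop("mesh index out of range")
  lms$points[idx + 1L, , drop = FALSE]
}

#' Interocular distance in pixels
#' @param lms a `landmark_set`.
#' @return Euclidean distance between the outer eye corners (mesh 33, 263).
#' @export
interocular_distance <- function(lms) {
  p <- lm_xy(lms, c(mesh_idx$eye_outer_left, mesh_idx$eye_outer_right))
  sqrt(sum((p[1, ] - p[2, ])^2))
}

#' Landmark providers
#'
#' A landmark provider is a function `function(image)` returning either a
#' `478 x 2` matrix of normalized \[0, 1\] coordinates or `NULL` when no face
#' is found. [detect_landmarks()] converts normalized coordinates to pixels
#' by multiplying by image width/height.
#'
#' `replay_provider()` wraps a fixed template (pixel coordinates plus the
#' dimensions they refer to) and replays it for every image — the provider
#' used in tests and for procedurally generated faces, standing in for an
#' external 478-point face-mesh model.
#'
#' @param lms a `landmark_set` whose coordinates the provider replays.
#' @return a provider function.
#' @export
replay_provider <- function(lms) {
  stopifnot(inherits(lms, "landmark_set"))
  norm <- sweep(lms$points, 2L, as.numeric(lms$source_dims), "/")
  function(image) norm
}

#' Detect the 478 facial landmarks of an image
#'
#' Applies a landmark provider (see [replay_provider()]) and converts its
#' normalized coordinates to pixel coordinates of `image`. The provider must
#' honor the 478-point contract; any other point count is an error.
#'
#' @param image a `face_image`.
#' @param provider a provider function.
#' @param label image label used in error messages.
#' @return a `landmark_set` in pixel coordinates of `image`.
#' @export
detect_landmarks <- function(image, provider, label = "image") {
  raw <- provider(image)
  if (is.null(raw)) stop("no face detected in ", label)
  raw <- as.matrix(raw)
  if (nrow(raw) != N_LANDMARKS || ncol(raw) < 2L) {
    stop("landmark provider contract violation for ", label, ": expected ",
         N_LANDMARKS, " (x, y) points, got ", nrow(raw))
  }
  d <- image_dims(image)
  pts <- cbind(raw[, 1] * d["width"], raw[, 2] * d["height"])
  landmark_set(pts, d)
}

#' Read / write landmark sets
#'
#' CSV serialization uses columns `index` (0-based mesh index), `x`, `y`;
#' JSON serialization stores `points` (list of \[x, y\]) and `source_dims`.
#'
#' @param lms a `landmark_set`.
#' @param path file path (.csv or .json).
#' @param source_dims `c(width, height)`, required when reading CSV.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a `landmark_set`.
#' @export
write_landmarks <- function(lms, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- data.frame(index = seq_len(N_LANDMARKS) - 1L,
                     x = lms$points[, 1], y = lms$points[, 2])
    write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(
      list(source_dims = as.integer(lms$source_dims),
           points = unname(as.data.frame(lms$points))),
      path, digits = NA, auto_unbox = TRUE)
  } else stop("unsupported landmark format: ", ext)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path, source_dims = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    if (is.null(source_dims)) stop("source_dims required for CSV landmarks")
    df <- read.csv(path)
    df <- df[order(df$index), ]
    landmark_set(cbind(df$x, df$y), source_dims)
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    landmark_set(as.matrix(obj$points), obj$source_dims)
  } else stop("unsupported landmark format: ", ext)
}
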