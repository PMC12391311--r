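#' Specification of a procedural synthetic face pair
#'
#' Describes a neutral/expression photograph pair of a schematic face drawn
#' from geometric primitives (ellipses, bars, arcs) with mild mirrored
#' texture noise, plus matching analytic 478-point landmark sets. The
#' `asymmetry` parameter emulates unilateral palsy: the displacement of the
#' moving features on the image-right side is attenuated by the factor
#' `1 - asymmetry`, so `asymmetry = 0` gives a bilaterally symmetric
#' expression change and `asymmetry = 1` freezes the right side entirely.
#'
#' Expression indices follow the photographic protocol: 2 eyes gently
#' closed, 3 eyes tightly closed, 4 frowning/forehead wrinkling, 5 nose
#' wrinkling, 6 closed-mouth stretch, 7 mouth stretch with teeth showing,
#' 8 lip pursing, 9 mouth corners down.
#'
#' @param expression_index integer 2-9.
#' @param asymmetry real in \[0, 1\].
#' @param dims canvas `c(width, height)` in pixels.
#' @param displacement base feature displacement in pixels on the
#'   unscaled canvas.
#' @param noise_sd standard deviation of the additive texture noise
#'   (gray levels); the noise field is mirrored about the facial midline.
#' @param seed integer random seed; generation is a pure function of the
#'   spec including the seed.
#' @return an object of class `synthetic_face_spec`.
#' @export
synthetic_face_spec <- function(expression_index, asymmetry = 0,
                                dims = c(320L, 400L), displacement = 14,
                                noise_sd = 1.5, seed = 1L) {
  expression_index <- as.integer(expression_index)
  stopifnot(expression_index >= 2L, expression_index <= 9L,
            asymmetry >= 0, asymmetry <= 1, displacement >= 0, noise_sd >= 0)
  structure(list(expression_index = expression_index, asymmetry = asymmetry,
                 dims = as.integer(dims), displacement = displacement,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_face_spec")
}

# Evaluate code under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

# Base geometry of the schematic face, bilaterally symmetric about
# x = width / 2 (all lengths scale with the canvas).
face_geometry <- function(dims) {
  w <- dims[1]; h <- dims[2]
  sx <- w / 320; sy <- h / 400
  cx <- w / 2; cy <- h / 2
  list(w = w, h = h, sx = sx, sy = sy, cx = cx, cy = cy,
       face_ax = 135 * sx, face_ay = 180 * sy,
       eye_y = cy - 50 * sy, eye_dx = 55 * sx,
       eye_ax = 24 * sx, eye_ay = 11 * sy,
       eye_outer = 80 * sx, eye_inner = 30 * sx,
       brow_y = cy - 80 * sy, brow_x0 = 30 * sx, brow_x1 = 80 * sx,
       brow_th = 7 * sy,
       nose_top = cy - 30 * sy, nose_bot = cy + 12 * sy,
       nose_hw = 4 * sx, nostril_dx = 14 * sx, nostril_y = cy + 14 * sy,
       mouth_y = cy + 76 * sy, mouth_ax = 45 * sx, lip_h = 10 * sy,
       chin_y = cy + 150 * sy)
}

# Per-side expression parameters. m = c(left, right) movement fractions;
# u = base displacement in pixels.
expression_params <- function(expr, m, u, g) {
  par <- list(eye_close = c(0, 0), brow_dy = c(0, 0), nostril_dy = c(0, 0),
              nose_mark = c(0, 0), mouth_ax = rep(g$mouth_ax, 2L),
              lip_h = rep(g$lip_h, 2L), mouth_open = c(0, 0),
              corner_dy = c(0, 0))
  switch(as.character(expr),
    "1" = par,
    "2" = { par$eye_close <- 0.55 * m; par },
    "3" = { par$eye_close <- 0.95 * m; par$brow_dy <- 0.3 * u * m; par },
    "4" = { par$brow_dy <- u * m; par },   # frown: brows pulled downward
    "5" = { par$nostril_dy <- -0.5 * u * m; par$nose_mark <- m; par },
    "6" = { par$mouth_ax <- g$mouth_ax + 1.2 * u * m
            par$corner_dy <- -0.3 * u * m; par },
    "7" = { par$mouth_ax <- g$mouth_ax + 0.9 * u * m
            par$mouth_open <- 0.7 * u * m
            par$lip_h <- g$lip_h + 0.5 * u * m; par },
    "8" = { par$mouth_ax <- g$mouth_ax - u * m
            par$lip_h <- g$lip_h + 0.4 * u * m; par },
    "9" = { par$corner_dy <- 0.8 * u * m; par },
    stop("unknown expression index: ", expr)
  )
}

# Paint a filled ellipse (optionally with a linear vertical droop toward
# the horizontal extremes) onto an [h, w, 3] raster. Side-dependent
# parameters: ax, ay, droop are length-2 (left, right of cx).
paint_ellipse <- function(img, cx, cy, ax, ay, color, droop = c(0, 0)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (length(ax) == 1L) ax <- rep(ax, 2L)
  if (length(ay) == 1L) ay <- rep(ay, 2L)
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  left <- x < cx
  a <- ifelse(left, ax[1], ax[2])
  b <- ifelse(left, ay[1], ay[2])
  dr <- ifelse(left, droop[1], droop[2])
  yy <- y - cy - dr * pmin(abs(x - cx) / a, 1)
  inside <- ((x - cx) / a)^2 + (yy / b)^2 <= 1 & a > 0 & b > 0
  for (c in 1:3) {
    ch <- img[, , c]
    ch[inside] <- color[c]
    img[, , c] <- ch
  }
  img
}

paint_rect <- function(img, x0, x1, y0, y1, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cols <- which(seq_len(w) - 0.5 >= x0 & seq_len(w) - 0.5 <= x1)
  rows <- which(seq_len(h) - 0.5 >= y0 & seq_len(h) - 0.5 <= y1)
  if (length(rows) && length(cols)) {
    for (c in 1:3) img[rows, cols, c] <- color[c]
  }
  img
}

SKIN  <- c(225, 185, 160)
BACKG <- c(190, 190, 190)
BROWC <- c(70, 50, 40)
EYEW  <- c(245, 245, 245)
IRIS  <- c(45, 45, 45)
NOSEC <- c(203, 163, 138)
NOSTR <- c(120, 90, 75)
LIPC  <- c(155, 60, 60)
TEETH <- c(250, 250, 250)

# Render the schematic face for one set of per-side expression parameters.
draw_face <- function(g, par, noise) {
  img <- array(0, dim = c(g$h, g$w, 3L))
  for (c in 1:3) img[, , c] <- BACKG[c]
  img <- paint_ellipse(img, g$cx, g$cy, g$face_ax, g$face_ay, SKIN)
  # eyebrows
  for (s in 1:2) {
    yb <- g$brow_y + par$brow_dy[s]
    x0 <- if (s == 1L) g$cx - g$brow_x1 else g$cx + g$brow_x0
    x1 <- if (s == 1L) g$cx - g$brow_x0 else g$cx + g$brow_x1
    img <- paint_rect(img, x0, x1, yb - g$brow_th / 2, yb + g$brow_th / 2, BROWC)
  }
  # eyes: white sclera shrinking as the lid closes, iris hidden when shut
  for (s in 1:2) {
    sgn <- if (s == 1L) -1 else 1
    ex <- g$cx + sgn * g$eye_dx
    open_h <- g$eye_ay * (1 - par$eye_close[s])
    if (open_h > 0.5) {
      img <- paint_ellipse(img, ex, g$eye_y, g$eye_ax, open_h, EYEW)
      if (open_h > 3) {
        img <- paint_ellipse(img, ex, g$eye_y, min(5.5, open_h), min(5.5, open_h), IRIS)
      }
    } else {
      img <- paint_rect(img, ex - g$eye_ax, ex + g$eye_ax,
                        g$eye_y - 1, g$eye_y + 1, NOSTR)
    }
  }
  # nose bar, nostrils and (for nose wrinkling) darkened flank marks
  img <- paint_rect(img, g$cx - g$nose_hw, g$cx + g$nose_hw,
                    g$nose_top, g$nose_bot, NOSEC)
  for (s in 1:2) {
    sgn <- if (s == 1L) -1 else 1
    img <- paint_ellipse(img, g$cx + sgn * g$nostril_dx,
                         g$nostril_y + par$nostril_dy[s], 4 * g$sx, 3 * g$sy, NOSTR)
    if (par$nose_mark[s] > 0) {
      shade <- SKIN - 70 * par$nose_mark[s]
      img <- paint_rect(img, g$cx + sgn * 22 * g$sx - 4 * g$sx,
                        g$cx + sgn * 22 * g$sx + 4 * g$sx,
                        g$cy - 10 * g$sy, g$cy + 8 * g$sy, shade)
    }
  }
  # mouth: per-side half-widths/heights, corners drooping or rising
  img <- paint_ellipse(img, g$cx, g$mouth_y, par$mouth_ax, par$lip_h, LIPC,
                       droop = par$corner_dy)
  if (any(par$mouth_open > 0.5)) {
    img <- paint_ellipse(img, g$cx, g$mouth_y, 0.8 * par$mouth_ax,
                         pmax(par$mouth_open, 0.01), TEETH,
                         droop = par$corner_dy)
  }
  clip8(img + array(rep(noise, 3L), dim = dim(img)))
}

# Texture noise field mirrored about the vertical canvas midline so a
# symmetric face stays exactly symmetric.
mirrored_noise <- function(w, h, sd) {
  if (sd == 0) return(matrix(0, h, w))
  m <- matrix(rnorm(h * w, 0, sd), h, w)
  half <- floor(w / 2)
  m[, (w - half + 1L):w] <- m[, half:1L]
  m
}

# Analytic 478-point landmark template for one parameter set. Named mesh
# indices sit on their face features; the remaining indices lie on an
# interior ring of the face ellipse so that whole-set alignment is
# exercised.
face_landmarks <- function(g, par) {
  i <- seq_len(N_LANDMARKS) - 1L
  th <- 2 * pi * i / N_LANDMARKS
  pts <- cbind(g$cx + 0.92 * g$face_ax * cos(th),
               g$cy + 0.92 * g$face_ay * sin(th))
  set <- function(idx, x, y) {
    pts[idx + 1L, ] <<- cbind(x, y)
    invisible(NULL)
  }
  set(mesh_idx$eye_outer_left,  g$cx - g$eye_outer, g$eye_y)
  set(mesh_idx$eye_inner_left,  g$cx - g$eye_inner, g$eye_y)
  set(mesh_idx$eye_inner_right, g$cx + g$eye_inner, g$eye_y)
  set(mesh_idx$eye_outer_right, g$cx + g$eye_outer, g$eye_y)
  brow_xs <- seq(g$brow_x1, g$brow_x0, length.out = 5L)
  set(mesh_idx$brow[1:5],  g$cx - brow_xs, g$brow_y + par$brow_dy[1])
  set(mesh_idx$brow[6:10], g$cx + brow_xs, g$brow_y + par$brow_dy[2])
  lip_h <- mean(par$lip_h) + mean(pmax(par$mouth_open, 0))
  set(mesh_idx$nose_bridge, g$cx, g$nose_top)
  set(mesh_idx$nose_tip,    g$cx, g$nose_bot)
  set(mesh_idx$lip_upper,   g$cx, g$mouth_y - lip_h)
  set(mesh_idx$lip_lower,   g$cx, g$mouth_y + lip_h)
  set(mesh_idx$chin,        g$cx, g$chin_y)
  landmark_set(pts, c(g$w, g$h))
}

#' Generate a synthetic neutral/expression face pair
#'
#' Draws the neutral and expression image described by `spec` plus their
#' analytic 478-point landmark sets. Deterministic given the spec
#' (including its seed); the expression image differs from the neutral
#' one only in the feature region the expression index implies.
#'
#' @param spec a [synthetic_face_spec()].
#' @return a list with `neutral`, `expression` (`face_image`s) and
#'   `neutral_lms`, `expression_lms` (`landmark_set`s).
#' @export
generate_face_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_face_spec"))
  g <- face_geometry(spec$dims)
  m <- c(1, 1 - spec$asymmetry)
  par0 <- expression_params(1L, c(0, 0), spec$displacement, g)
  parE <- expression_params(spec$expression_index, m, spec$displacement, g)
  with_seed(spec$seed, {
    n1 <- mirrored_noise(g$w, g$h, spec$noise_sd)
    n2 <- mirrored_noise(g$w, g$h, spec$noise_sd)
    list(
      neutral = face_image(draw_face(g, par0, n1), 1L),
      expression = face_image(draw_face(g, parE, n2), spec$expression_index),
      neutral_lms = face_landmarks(g, par0),
      expression_lms = face_landmarks(g, parE)
    )
  })
}

#' Simulate a longitudinal score series
#'
#' Generates per-visit aggregate symmetry scores
#' `clip(base + true_slope * i + noise, 0, 1)` for examination indices
#' `i = 0 .. n - 1`, with i.i.d. Gaussian noise. Deterministic given the
#' seed.
#'
#' @param true_slope score change per examination step.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n number of visits (>= 2).
#' @param seed integer seed.
#' @param base baseline score at the first visit.
#' @param start_date date of the first visit; visits are 30 days apart.
#' @param patient_id identifier stored in the output.
#' @return a data.frame with columns `patient_id`, `visit_index`, `date`,
#'   `score`.
#' @export
generate_score_series <- function(true_slope, noise_sd, n, seed = 1L,
                                  base = 0.6, start_date = as.Date("2024-01-15"),
                                  patient_id = "P001") {
  stopifnot(n >= 2L)
  i <- seq_len(n) - 1L
  scores <- with_seed(seed, {
    pmin(pmax(base + true_slope * i + rnorm(n, 0, noise_sd), 0), 1)
  })
  data.frame(patient_id = patient_id, visit_index = i,
             date = start_date + 30L * i, score = scores)
}

#' Write a synthetic dataset tree for end-to-end runs
#'
#' Materializes procedurally generated visits under
#' `dir/<patient_id>/<visit_date>/expr_<n>.png` with landmark sidecar
#' files `expr_<n>.landmarks.json`, the layout consumed by
#' [run_dataset()]. The per-visit asymmetry of each patient is given by
#' `asymmetry`, a matrix with one row per patient and one column per
#' visit (a decreasing row simulates recovery under therapy).
#'
#' @param dir output directory (created if missing).
#' @param asymmetry numeric matrix `[n_patients, n_visits]` in \[0, 1\].
#' @param expressions expression indices to generate (default 2:9).
#' @param dims canvas dims per image.
#' @param displacement,noise_sd passed to [synthetic_face_spec()].
#' @param seed integer seed; each image derives its own sub-seed.
#' @param start_date first visit date; visits are 30 days apart.
#' @return the data directory, invisibly.
#' @export
write_synthetic_dataset <- function(dir, asymmetry, expressions = 2:9,
                                    dims = c(320L, 400L), displacement = 14,
                                    noise_sd = 1.5, seed = 1L,
                                    start_date = as.Date("2024-01-15")) {
  asymmetry <- rbind(asymmetry)
  for (p in seq_len(nrow(asymmetry))) {
    pid <- sprintf("P%03d", p)
    for (v in seq_len(ncol(asymmetry))) {
      vdate <- format(start_date + 30L * (v - 1L))
      vdir <- file.path(dir, pid, vdate)
      dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
      written_neutral <- FALSE
      for (e in expressions) {
        sub_seed <- (seed * 10000L + p * 1000L + v * 100L + e) %% .Machine$integer.max
        spec <- synthetic_face_spec(e, asymmetry[p, v], dims = dims,
                                    displacement = displacement,
                                    noise_sd = noise_sd, seed = sub_seed)
        pair <- generate_face_pair(spec)
        if (!written_neutral) {
          write_face_image(pair$neutral, file.path(vdir, "expr_1.png"))
          write_landmarks(pair$neutral_lms,
                          file.path(vdir, "expr_1.landmarks.json"))
          written_neutral <- TRUE
        }
        write_face_image(pair$expression, file.path(vdir, sprintf("expr_%d.png", e)))
        write_landmarks(pair$expression_lms,
                        file.path(vdir, sprintf("expr_%d.landmarks.json", e)))
      }
    }
  }
  invisible(dir)
}
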