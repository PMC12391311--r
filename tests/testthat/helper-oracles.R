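# Independent oracles used across the suite.

# Numeric-optimization fit of a similarity transform (scale, rotation,
# translation) minimizing summed squared distances — an independent check
# of the closed-form alignment estimator.
oracle_fit_similarity <- function(src, dst) {
  sse <- function(p) {
    s <- exp(p[1]); th <- p[2]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    pred <- s * src %*% t(R)
    pred[, 1] <- pred[, 1] + p[3]; pred[, 2] <- pred[, 2] + p[4]
    sum((pred - dst)^2)
  }
  fit <- optim(c(0, 0, 0, 0), sse, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  list(scale = exp(fit$par[1]), rotation = fit$par[2],
       translation = fit$par[3:4])
}

# Explicit per-pixel loop implementing left/right pairing and the
# variance-weighted score on raw matrices (0-based midline coordinate).
oracle_symmetry_score <- function(dmat, maskmat, midline_x,
                                  sigma2_max = 5000, intensity_scale = 255) {
  h <- nrow(maskmat); w <- ncol(maskmat)
  mid_col <- if (floor(midline_x) < midline_x && midline_x < floor(midline_x) + 1)
    floor(midline_x) else NA
  L <- c(); R <- c()
  for (i in seq_len(h)) {
    for (j0 in 0:(w - 1L)) {
      if (!maskmat[i, j0 + 1L]) next
      if (j0 + 0.5 >= midline_x) next
      if (!is.na(mid_col) && j0 == mid_col) next
      jm <- round(2 * midline_x - j0 - 1)
      if (jm < 0 || jm > w - 1L) next
      if (!is.na(mid_col) && jm == mid_col) next
      if (!maskmat[i, jm + 1L]) next
      L <- c(L, dmat[i, j0 + 1L]); R <- c(R, dmat[i, jm + 1L])
    }
  }
  if (!length(L)) return(NULL)
  d <- L - R
  s_mean <- 1 - mean(abs(d)) / intensity_scale
  s2 <- mean((d - mean(d))^2)
  list(L = L, R = R, s_mean = s_mean, variance = s2, n = length(L),
       score = s_mean * (1 - min(s2 / sigma2_max, 1)))
}

# Direct 2-D convolution of a matrix with the outer product of a 1-D
# kernel, reflect-101 borders — reference for the separable blur.
oracle_conv2d <- function(m, w1d) {
  k <- length(w1d); r <- (k - 1L) / 2L
  ref <- function(i, n) {
    if (n == 1L) return(1L)
    p <- 2L * n - 2L
    m0 <- ((i - 1L) %% p + p) %% p
    (if (m0 >= n) p - m0 else m0) + 1L
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      acc <- 0
      for (a in -r:r) for (b in -r:r) {
        acc <- acc + w1d[a + r + 1L] * w1d[b + r + 1L] *
          m[ref(i + a, nrow(m)), ref(j + b, ncol(m))]
      }
      out[i, j] <- acc
    }
  }
  out
}

# A neutral landmark template (478 analytic points, interocular 160 px on
# a 320 x 400 canvas) plus its images, shared by several tests.
template_pair <- function(expression_index = 7, asymmetry = 0, seed = 1L, ...) {
  generate_face_pair(synthetic_face_spec(expression_index, asymmetry,
                                         seed = seed, ...))
}

# Tiny flat test image with a deterministic gradient pattern.
gradient_image <- function(w = 32L, h = 32L) {
  r <- outer(seq_len(h), seq_len(w), function(i, j) (i * 7 + j * 3) %% 256)
  face_image(array(rep(r, 3L), dim = c(h, w, 3L)))
}

# Rescale a landmark template so its interocular distance is `target`.
lms_with_eye_distance <- function(target) {
  lms <- template_pair()$neutral_lms
  f <- target / interocular_distance(lms)
  landmark_set(lms$points * f, pmax(1L, round(as.numeric(lms$source_dims) * f)))
}
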