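test_that("transform algebra inverts and composes exactly", {
  t <- similarity_transform(1.3, 0.4, c(12, -7))
  pts <- matrix(runif(20, -50, 50), 10, 2)
  back <- apply_transform(invert_transform(t), apply_transform(t, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  t2 <- similarity_transform(0.8, -0.2, c(-3, 5))
  lhs <- apply_transform(compose_transform(t2, t), pts)
  rhs <- apply_transform(t2, apply_transform(t, pts))
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("alignment of a set onto itself is the identity", {
  lms <- template_pair()$neutral_lms
  t <- estimate_alignment(lms, lms)
  expect_equal(t$scale, 1, tolerance = 1e-9)
  expect_equal(t$rotation, 0, tolerance = 1e-9)
  expect_equal(t$translation, c(0, 0), tolerance = 1e-9)
})

test_that("alignment recovers a known rotation + translation exactly", {
  lms <- template_pair()$neutral_lms
  th <- 10 * pi / 180
  ctr <- colMeans(lms$points)
  shifted <- sweep(lms$points, 2L, ctr)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  dst_pts <- sweep(shifted %*% t(R), 2L, ctr + c(5, -3), "+")
  dst <- landmark_set(dst_pts, lms$source_dims)
  t <- estimate_alignment(lms, dst)
  expect_equal(t$scale, 1, tolerance = 1e-6)
  expect_equal(t$rotation, th, tolerance = 1e-6)
  recovered <- apply_transform(t, lms$points)
  expect_lt(max(abs(recovered - dst_pts)), 1e-6)
})

test_that("alignment is exact on noiseless similarity copies and matches a numeric oracle", {
  lms <- template_pair()$neutral_lms
  set.seed(11)
  for (i in 1:20) {
    s <- runif(1, 0.5, 2)
    th <- runif(1, -30, 30) * pi / 180
    tr <- runif(2, -40, 40)
    t_true <- similarity_transform(s, th, tr)
    dst <- landmark_set(apply_transform(t_true, lms$points), lms$source_dims)
    t <- estimate_alignment(lms, dst)
    expect_equal(t$scale, s, tolerance = 1e-6)
    expect_equal(t$rotation, th, tolerance = 1e-6)
    expect_equal(t$translation, tr, tolerance = 1e-6)
  }
  # independent numeric-optimization oracle on one noisy instance
  set.seed(12)
  dst_pts <- apply_transform(similarity_transform(1.2, 0.1, c(4, 9)),
                             lms$points) + rnorm(478 * 2, 0, 0.5)
  t <- estimate_alignment(lms, landmark_set(dst_pts, lms$source_dims))
  o <- oracle_fit_similarity(lms$points, dst_pts)
  expect_equal(t$scale, o$scale, tolerance = 1e-5)
  expect_equal(t$rotation, o$rotation, tolerance = 1e-5)
  expect_equal(t$translation, o$translation, tolerance = 1e-4)
})

test_that("noisy alignment recovers parameters within the sampling tolerance", {
  lms <- template_pair()$neutral_lms
  ctr <- rbind(colMeans(lms$points))
  tol <- 3 * 0.5 / sqrt(478)
  set.seed(21)
  ok <- logical(100)
  for (i in 1:100) {
    t_true <- similarity_transform(runif(1, 0.8, 1.2),
                                   runif(1, -0.2, 0.2), runif(2, -10, 10))
    dst_pts <- apply_transform(t_true, lms$points) + rnorm(478 * 2, 0, 0.5)
    t <- estimate_alignment(lms, landmark_set(dst_pts, lms$source_dims))
    # translation accuracy is judged at the centroid, where the estimator
    # is parameterized; scale and rotation errors are tiny by comparison
    ok[i] <- abs(t$scale - t_true$scale) < tol &&
      abs(t$rotation - t_true$rotation) < tol &&
      max(abs(apply_transform(t, ctr) - apply_transform(t_true, ctr))) < tol
  }
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate landmark sets are rejected", {
  lms <- landmark_set(matrix(5, 478, 2), c(10, 10))
  expect_error(estimate_alignment(lms, lms), "degenerate")
})

test_that("identity warp returns the input bit-identically", {
  img <- gradient_image(40, 30)
  out <- warp_image(img, similarity_transform())
  expect_identical(out$raster, img$raster)
})

test_that("integer translation shifts pixels without interpolation", {
  img <- gradient_image(40, 30)
  out <- warp_image(img, similarity_transform(translation = c(10, 0)))
  expect_identical(out$raster[, 11:40, ], img$raster[, 1:30, ])
  expect_true(all(out$raster[, 1:10, ] == 0L))
})

test_that("quarter-turn warp round-trips the interior", {
  img <- gradient_image(60, 60)
  ctr <- similarity_transform(translation = c(-30, -30))
  rot <- compose_transform(
    similarity_transform(translation = c(30, 30)),
    compose_transform(similarity_transform(rotation = pi / 2), ctr))
  fwd <- warp_image(img, rot)
  back <- warp_image(fwd, invert_transform(rot))
  interior <- 16:45
  expect_lte(max(abs(back$raster[interior, interior, ] -
                     img$raster[interior, interior, ])), 2)
})

test_that("interocular scaling lands exactly on the 200 px target", {
  img <- gradient_image(64, 80)
  for (d in c(50, 100, 137, 400)) {
    lms <- lms_with_eye_distance(d)
    out <- interocular_scale(img, lms)
    expect_equal(interocular_distance(out$lms), 200, tolerance = 0.5)
    expect_equal(out$scale_factor, 200 / d, tolerance = 1e-9)
  }
})

test_that("interocular scaling is the identity at 200 px and idempotent", {
  img <- gradient_image(64, 80)
  lms <- lms_with_eye_distance(200)
  out <- interocular_scale(img, lms)
  expect_identical(out$image$raster, img$raster)
  expect_identical(out$scale_factor, 1)
  once <- interocular_scale(img, lms_with_eye_distance(100))
  twice <- interocular_scale(once$image, once$lms)
  expect_equal(twice$scale_factor, 1, tolerance = 1e-9)
  expect_identical(twice$image$raster, once$image$raster)
})

test_that("coincident eye corners raise a degenerate-geometry error", {
  pts <- template_pair()$neutral_lms$points
  pts[34, ] <- pts[264, ]   # mesh 33 onto mesh 263
  lms <- landmark_set(pts, c(320, 400))
  expect_error(interocular_scale(gradient_image(), lms), "degenerate")
})

test_that("canvas centering pads, crops and shifts landmarks consistently", {
  img <- gradient_image(100, 100)
  lms <- template_pair()$neutral_lms
  same <- center_on_canvas(img, lms, c(100, 100))
  expect_identical(same$image$raster, img$raster)
  expect_identical(same$offset, c(0, 0))

  pad <- center_on_canvas(img, lms, c(200, 200))
  expect_identical(pad$offset, c(50, 50))
  expect_identical(unname(image_dims(pad$image)), c(200L, 200L))
  expect_identical(pad$image$raster[51:150, 51:150, ], img$raster)
  expect_equal(pad$lms$points, lms$points + 50, ignore_attr = TRUE)

  big <- gradient_image(300, 300)
  crop <- center_on_canvas(big, lms, c(200, 200))
  expect_identical(crop$offset, c(-50, -50))
  expect_identical(crop$image$raster, big$raster[51:250, 51:250, ])
})

test_that("centering preserves relative landmark geometry", {
  lms <- template_pair()$neutral_lms
  out <- center_on_canvas(gradient_image(100, 100), lms, c(257, 119))
  d0 <- dist(lms$points[seq(1, 478, by = 25), ])
  d1 <- dist(out$lms$points[seq(1, 478, by = 25), ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})
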