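test_that("pairing counts follow the mirror geometry", {
  # symmetric mask about a pixel-boundary midline: full pairing, N = k
  m <- matrix(FALSE, 6, 8)
  m[2:5, 2:7] <- TRUE
  mask <- face_mask(m, 4)
  d <- diff_map(matrix(0, 6, 8))
  p <- paired_half_pixels(d, mask)
  expect_identical(p$n, as.integer(sum(m) / 2))

  # mask entirely left of the midline: no overlap
  left_only <- matrix(FALSE, 6, 8); left_only[, 1:3] <- TRUE
  expect_error(paired_half_pixels(d, face_mask(left_only, 4)),
               "no valid left/right pixel pairs")
})

test_that("pairing matches a brute-force reflection loop on asymmetric masks", {
  set.seed(33)
  for (i in 1:25) {
    h <- sample(4:8, 1); w <- sample(5:9, 1)
    m <- matrix(runif(h * w) < 0.5, h, w)
    vals <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    midline <- runif(1, 1.2, w - 1.2)
    oracle <- oracle_symmetry_score(vals, m, midline)
    got <- tryCatch(paired_half_pixels(diff_map(vals), face_mask(m, midline)),
                    error = function(e) NULL)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_identical(got$n, oracle$n)
      expect_equal(sort(abs(got$L - got$R)),
                   sort(abs(oracle$L - oracle$R)), ignore_attr = TRUE)
    }
  }
})

test_that("mean-difference term evaluates the stated arithmetic", {
  cfg <- score_config()
  expect_equal(compute_s_mean(c(10, 20, 30), c(10, 20, 30), cfg), 1)
  expect_equal(compute_s_mean(rep(255, 4), rep(0, 4), cfg), 0)
  L <- c(20, 10, 20, 10); R <- c(10, 20, 10, 20)  # differences +-10
  expect_equal(compute_s_mean(L, R, cfg), 1 - 10 / 255, tolerance = 1e-12)
})

test_that("variance weight hits its documented anchors", {
  cfg <- score_config()
  expect_equal(variance_weight(rep(7, 10), cfg), 1)
  expect_equal(variance_weight(c(10, -10, 10, -10), cfg), 0.98)
  # population variance exactly sigma2_max -> weight 0, and 0 beyond
  d <- c(rep(sqrt(5000), 2), rep(-sqrt(5000), 2))
  expect_equal(variance_weight(d, cfg), 0)
  expect_equal(variance_weight(3 * d, cfg), 0)
})

test_that("symmetry score composes its two factors", {
  # DiffMap symmetric about the midline -> score exactly 1
  v <- matrix(rep(c(3, 9, 9, 3), each = 6), 6, 4)
  mask <- face_mask(matrix(TRUE, 6, 4), 2)
  r <- symmetry_score(diff_map(v), mask)
  expect_identical(r$score, 1)
  expect_identical(r$s_mean, 1)

  # alternating +-10 differences -> (1 - 10/255) * 0.98
  v2 <- matrix(0, 6, 4)
  v2[, 1] <- rep(c(10, 0), 3); v2[, 4] <- rep(c(0, 10), 3)
  v2[, 2] <- rep(c(0, 10), 3); v2[, 3] <- rep(c(10, 0), 3)
  r2 <- symmetry_score(diff_map(v2), mask)
  expect_equal(r2$score, (1 - 10 / 255) * (1 - 100 / 5000), tolerance = 1e-12)
  expect_equal(r2$variance, 100, tolerance = 1e-12)
})

test_that("score equals the brute-force oracle on random instances", {
  set.seed(77)
  n_checked <- 0L
  for (i in 1:300) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    m <- matrix(runif(h * w) < 0.6, h, w)
    vals <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    midline <- runif(1, 0.6, w - 0.6)
    oracle <- oracle_symmetry_score(vals, m, midline)
    if (is.null(oracle)) next
    r <- symmetry_score(diff_map(vals), face_mask(m, midline))
    expect_equal(r$score, oracle$score, tolerance = 1e-12)
    expect_equal(r$s_mean, oracle$s_mean, tolerance = 1e-12)
    expect_identical(r$n_valid, oracle$n)
    expect_true(r$score >= 0 && r$score <= r$s_mean && r$s_mean <= 1)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 200L)
})

test_that("score is invariant under mirror reflection of map and mask", {
  set.seed(88)
  for (i in 1:20) {
    w <- 8L
    m <- matrix(runif(48) < 0.7, 6, w)
    vals <- matrix(sample(0:255, 48, replace = TRUE), 6, w)
    r1 <- tryCatch(symmetry_score(diff_map(vals), face_mask(m, w / 2)),
                   error = function(e) NULL)
    r2 <- tryCatch(symmetry_score(diff_map(vals[, w:1]),
                                  face_mask(m[, w:1], w / 2)),
                   error = function(e) NULL)
    if (is.null(r1)) { expect_null(r2); next }
    expect_equal(r1$score, r2$score, tolerance = 1e-12)
  }
})

test_that("uniform asymmetry lowers the score; variance lowers the weight", {
  mask <- face_mask(matrix(TRUE, 10, 10), 5)
  base <- matrix(40, 10, 10)
  s0 <- symmetry_score(diff_map(base), mask)$score
  shifted <- base; shifted[, 1:5] <- base[, 1:5] + 30
  s1 <- symmetry_score(diff_map(shifted), mask)$score
  expect_lt(s1, s0)

  # non-increasing in variance at fixed s_mean: |d| fixed at 50, vary signs
  cfg <- score_config()
  w_lo <- variance_weight(rep(50, 8), cfg)            # variance 0
  w_mid <- variance_weight(c(rep(50, 6), -50, -50), cfg)
  w_hi <- variance_weight(rep(c(50, -50), 4), cfg)    # variance 2500
  expect_true(w_lo >= w_mid && w_mid >= w_hi)
})
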