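test_that("visit aggregation averages available expression scores", {
  expect_equal(aggregate_visit_score(rep(0.9, 8)), 0.9)
  expect_equal(aggregate_visit_score(c(0.8, 0.9)), 0.85)
  expect_equal(aggregate_visit_score(0.7), 0.7)
  expect_equal(aggregate_visit_score(c(0.2, 0.8, 0.9), "median"), 0.8)
  s <- c("6" = 0.5, "7" = 0.25)
  expect_equal(aggregate_visit_score(s, 7), 0.25)
  expect_error(aggregate_visit_score(numeric(0)), "no expression scores")
})

test_that("rolling median smooths interiors and passes short series through", {
  expect_identical(rolling_median(c(0.5, 0.6)), c(0.5, 0.6))
  expect_equal(rolling_median(c(0.5, 0.9, 0.5))[2], 0.5)
  mono <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(rolling_median(mono)[2:3], mono[2:3])
  # output never leaves the min/max of its window
  set.seed(9)
  for (i in 1:50) {
    v <- runif(sample(3:12, 1))
    f <- rolling_median(v)
    for (j in seq_along(v)) {
      win <- v[max(1, j - 1):min(length(v), j + 1)]
      expect_gte(f[j], min(win)); expect_lte(f[j], max(win))
    }
  }
})

test_that("Theil-Sen slope is the median pairwise slope", {
  expect_equal(theil_sen_slope(0:5, rep(0.4, 6)), 0)
  expect_equal(theil_sen_slope(0:5, 0.2 + 0.1 * (0:5)), 0.1, tolerance = 1e-12)
  # outlier case against the explicit double loop
  t <- 0:6
  y <- 0.5 + 0.1 * t; y[4] <- 0.95
  slopes <- c()
  for (i in 1:6) for (j in (i + 1):7) {
    slopes <- c(slopes, (y[j] - y[i]) / (t[j] - t[i]))
  }
  expect_equal(theil_sen_slope(t, y), median(slopes), tolerance = 1e-12)
  expect_error(theil_sen_slope(c(1, 1), c(0, 1)), "distinct")
  expect_error(theil_sen_slope(1, 0.5), "at least two")
})

test_that("Theil-Sen slope is equivariant under added linear trends", {
  set.seed(14)
  for (i in 1:25) {
    t <- sort(sample(0:20, 8))
    y <- runif(8)
    a <- runif(1, -2, 2); b <- runif(1, -1, 1)
    expect_equal(theil_sen_slope(t, y + a * t + b),
                 theil_sen_slope(t, y) + a, tolerance = 1e-10)
  }
})

test_that("trend labels partition slopes at the +-0.001 threshold", {
  expect_identical(classify_trend(0), "no_significant_change")
  expect_identical(classify_trend(0.01), "improvement")
  expect_identical(classify_trend(-0.01), "deterioration")
  expect_identical(classify_trend(0.001), "no_significant_change")
  expect_identical(classify_trend(-0.001), "no_significant_change")
  expect_identical(classify_trend(0.001 + 1e-9), "improvement")
  expect_identical(classify_trend(-0.001 - 1e-9), "deterioration")
  set.seed(15)
  for (s in runif(50, -1, 1)) {
    expect_identical(sum(c("improvement", "deterioration",
                           "no_significant_change") == classify_trend(s)), 1L)
  }
})

test_that("score_trend chains filtering, slope and label", {
  s <- generate_score_series(0.05, 0, n = 5, seed = 1)
  tr <- score_trend(s$score)
  expect_equal(tr$slope, 0.05, tolerance = 1e-9)
  expect_identical(tr$label, "improvement")
  tr2 <- score_trend(rev(s$score))
  expect_identical(tr2$label, "deterioration")
  expect_error(score_trend(0.5), "at least two")
  # an isolated outlier is absorbed by the rolling median
  y <- 0.6 + 0.02 * (0:6); y[4] <- 0.2
  tro <- score_trend(y)
  expect_identical(tro$label, "improvement")
  expect_lt(abs(tro$slope - 0.02), 0.005)
  # without filtering the outlier would drag the raw fit far more
  expect_lt(abs(tro$slope - 0.02), abs(theil_sen_slope(0:6, y) - 0.02) + 0.005)
})

test_that("trend classification recovers generating trend signs", {
  n_ok <- 0L
  for (seed in 1:200) {
    s <- generate_score_series(0, 0.0005, n = 10, seed = seed)
    n_ok <- n_ok + (score_trend(s$score)$label == "no_significant_change")
  }
  expect_gte(n_ok / 200, 0.95)
})

test_that("Spearman correlation matches hand-ranked arithmetic and base R", {
  r <- spearman_correlation(c(0, 1, 2, 3), c(0.9, 0.8, 0.85, 0.6))
  rg <- rank(c(0, 1, 2, 3)); rs <- rank(c(0.9, 0.8, 0.85, 0.6))
  hand <- sum((rg - mean(rg)) * (rs - mean(rs))) /
    sqrt(sum((rg - mean(rg))^2) * sum((rs - mean(rs))^2))
  expect_equal(r$r, hand, tolerance = 1e-12)
  expect_equal(r$r, suppressWarnings(
    cor.test(c(0, 1, 2, 3), c(0.9, 0.8, 0.85, 0.6),
             method = "spearman")$estimate[[1]]), tolerance = 1e-12)

  perfect <- spearman_correlation(0:5, seq(0.9, 0.4, by = -0.1))
  expect_equal(perfect$r, -1)
  expect_equal(perfect$p, 0)
  expect_true(perfect$significant)

  expect_error(spearman_correlation(rep(2, 5), runif(5)), "constant")
  expect_error(spearman_correlation(0:1, c(0.1, 0.2)), "at least 3")
})

test_that("t-approximate and exact permutation p values agree in form", {
  set.seed(31)
  g <- c(0, 1, 2, 3, 4, 5)
  s <- c(0.95, 0.9, 0.8, 0.85, 0.6, 0.62)
  approx <- spearman_correlation(g, s)
  exact <- spearman_correlation(g, s, exact = TRUE)
  expect_equal(approx$r, exact$r)
  expect_lt(abs(approx$p - exact$p), 0.05)
  # exact null is valid: p of a perfectly monotone pairing is 2 / n!
  ex <- spearman_correlation(1:5, c(5, 4, 3, 2, 1) / 10, exact = TRUE)
  expect_equal(ex$p, 2 / factorial(5), tolerance = 1e-12)
  expect_error(spearman_correlation(1:9, runif(9), exact = TRUE), "n <= 8")
})
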