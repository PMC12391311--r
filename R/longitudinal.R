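#' Aggregate the per-expression scores of one visit
#'
#' Collapses the available expression scores (indices 2-9) of a visit into
#' one scalar for trend analysis. The default is the arithmetic mean over
#' available expressions; `method = "median"` or a single expression index
#' (`method = 7`) are alternatives.
#'
#' @param scores numeric vector of per-expression scores, optionally named
#'   by expression index.
#' @param method `"mean"`, `"median"`, or an expression index 2-9 (scores
#'   must then be named by index).
#' @return scalar aggregate score.
#' @export
aggregate_visit_score <- function(scores, method = "mean") {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no expression scores to aggregate")
  if (identical(method, "mean")) return(mean(scores))
  if (identical(method, "median")) return(median(scores))
  idx <- suppressWarnings(as.integer(method))
  if (!is.na(idx)) {
    v <- scores[as.character(idx)]
    if (is.na(v)) stop("expression ", idx, " not present in scores")
    return(unname(v))
  }
  stop("unknown aggregation method: ", method)
}

#' Rolling median filter
#'
#' Centered rolling median of window `window` (default 3), damping
#' outliers while preserving the overall trend. Series shorter than
#' `window` are returned unchanged. Near the two ends the centered window
#' shrinks symmetrically to the available points (keeping it odd, so the
#' outermost values pass through unchanged and exactly linear series stay
#' linear); the output has the input length.
#'
#' @param values numeric vector.
#' @param window odd positive window size.
#' @return filtered numeric vector of the same length.
#' @export
rolling_median <- function(values, window = 3L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(values)
  if (n < window) return(values)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    median(values[(i - h):(i + h)])
  }, numeric(1))
}

#' Theil-Sen robust slope
#'
#' Median of all pairwise slopes `(y_j - y_i) / (t_j - t_i)` over `i < j`
#' with distinct `t`; robust to outliers and small sample sizes.
#'
#' @param t numeric time axis (e.g. examination index).
#' @param y numeric observations.
#' @return scalar slope in y-units per t-unit.
#' @export
theil_sen_slope <- function(t, y) {
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2L || length(unique(t)) < 2L) {
    stop("Theil-Sen slope needs at least two points with distinct times")
  }
  dt <- outer(t, t, "-")
  dy <- outer(y, y, "-")
  use <- upper.tri(dt) & dt != 0
  median(dy[use] / dt[use])
}

#' Classify a score trend from its slope
#'
#' `improvement` when the slope exceeds `tau`, `deterioration` when it
#' falls below `-tau`, otherwise `no_significant_change`. The comparisons
#' are strict, so boundary slopes count as no significant change — a
#' conservative rule excluding minor fluctuations (default `tau` 0.001
#' score units per examination step).
#'
#' @param slope finite slope.
#' @param tau non-negative trend threshold.
#' @return one of `"improvement"`, `"deterioration"`,
#'   `"no_significant_change"`.
#' @export
classify_trend <- function(slope, tau = 0.001) {
  stopifnot(is.finite(slope), tau >= 0)
  if (slope > tau) "improvement"
  else if (slope < -tau) "deterioration"
  else "no_significant_change"
}

#' Robust trend of a per-patient score series
#'
#' Applies the rolling median (when at least `window` points are
#' available), fits the Theil-Sen slope over the examination index (or
#' days since first visit with `time_axis = "days"`), and labels the
#' trend.
#'
#' @param scores numeric per-visit aggregate scores, time-ordered.
#' @param dates optional visit dates (required for `time_axis = "days"`).
#' @param window rolling-median window (default 3).
#' @param tau trend threshold (default 0.001).
#' @param time_axis `"index"` (default) or `"days"`.
#' @return an object of class `trend_result` with fields `slope`, `label`
#'   and `n_points`.
#' @export
score_trend <- function(scores, dates = NULL, window = 3L, tau = 0.001,
                        time_axis = c("index", "days")) {
  time_axis <- match.arg(time_axis)
  n <- length(scores)
  if (n < 2L) stop("trend analysis needs at least two time points")
  t <- if (time_axis == "days") {
    if (is.null(dates)) stop("dates required for time_axis = 'days'")
    as.numeric(as.Date(dates) - as.Date(dates)[1])
  } else {
    seq_len(n) - 1
  }
  filtered <- rolling_median(scores, window)
  slope <- theil_sen_slope(t, filtered)
  structure(list(slope = slope, label = classify_trend(slope, tau),
                 n_points = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> slope %.5f over %d points: %s\n",
              x$slope, x$n_points, x$label))
  invisible(x)
}

#' Spearman rank correlation between clinical grades and scores
#'
#' Rank correlation with average-rank tie handling, suited to ordinal
#' clinical grades paired with continuous symmetry scores. The two-sided p
#' value uses the t-distribution approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom; for
#' small samples (`n <= 8`, no ties) `exact = TRUE` enumerates the exact
#' permutation null instead.
#'
#' @param grades ordinal values (e.g. clinical grades 0-6).
#' @param scores paired continuous scores.
#' @param exact use the exact permutation p value (n <= 8 only).
#' @return a list with `r`, `p`, `n` and `significant` (p < 0.05).
#' @export
spearman_correlation <- function(grades, scores, exact = FALSE) {
  ok <- is.finite(grades) & is.finite(scores)
  g <- grades[ok]; s <- scores[ok]
  n <- length(g)
  if (n < 3L) stop("Spearman correlation needs at least 3 paired observations")
  if (length(unique(g)) < 2L || length(unique(s)) < 2L) {
    stop("undefined correlation: constant input vector")
  }
  r <- cor(rank(g), rank(s))
  if (exact) {
    if (n > 8L) stop("exact permutation p value limited to n <= 8")
    perms <- permutations_of(n)
    rg <- rank(g)
    null_r <- apply(perms, 1L, function(p) cor(rg, rank(s)[p]))
    p <- mean(abs(null_r) >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tt), df = n - 2)
    }
  }
  list(r = r, p = p, n = n, significant = p < 0.05)
}

# All permutations of 1..n as a matrix (n! rows); n is small by contract.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
  unname(out)
}
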