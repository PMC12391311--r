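#' Pipeline run configuration
#'
#' Collects every tunable pipeline parameter with the published defaults:
#' 5x5 pre-blur, 111x111 smoothing, x5 amplification, maximum variance
#' 5000, trend threshold 0.001 and rolling-median window 3. The mask
#' padding fraction (0.10 per side) and the minimum movement intensity
#' (processed-difference gray levels below which an expression is flagged
#' as hesitant) are pipeline choices exposed here.
#'
#' @param preblur_kernel odd kernel for the pre-difference blur.
#' @param smooth_kernel odd kernel for the post-difference smoothing.
#' @param amplification integer amplification factor.
#' @param sigma2_max variance normalizer of the score weight.
#' @param padding_frac mask padding fraction per side.
#' @param trend_threshold Theil-Sen slope threshold for trend labels.
#' @param rolling_window rolling-median window size.
#' @param movement_intensity_min flagging threshold (strict `<`).
#' @param interocular_target target interocular distance in pixels.
#' @param aggregate per-visit aggregation, see [aggregate_visit_score()].
#' @param provider `"stored"` (landmark sidecar files) or a provider
#'   function, see [detect_landmarks()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(preblur_kernel = 5L, smooth_kernel = 111L,
                       amplification = 5L, sigma2_max = 5000,
                       padding_frac = 0.10, trend_threshold = 0.001,
                       rolling_window = 3L, movement_intensity_min = 5,
                       interocular_target = 200, aggregate = "mean",
                       provider = "stored") {
  cfg <- list(preblur_kernel = as.integer(preblur_kernel),
              smooth_kernel = as.integer(smooth_kernel),
              amplification = as.integer(amplification),
              sigma2_max = sigma2_max, padding_frac = padding_frac,
              trend_threshold = trend_threshold,
              rolling_window = as.integer(rolling_window),
              movement_intensity_min = movement_intensity_min,
              interocular_target = interocular_target,
              aggregate = aggregate, provider = provider)
  for (k in c("preblur_kernel", "smooth_kernel")) {
    if (cfg[[k]] < 1L || cfg[[k]] %% 2L == 0L) {
      stop(k, " must be odd and positive")
    }
  }
  if (cfg$amplification < 1L) stop("amplification must be positive")
  stopifnot(cfg$sigma2_max > 0, cfg$padding_frac >= 0,
            cfg$trend_threshold >= 0, cfg$movement_intensity_min >= 0)
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Parses lines of the form `key = value` (comments start with `#`).
#' Values are converted to numbers where possible; keys must be
#' [run_config()] arguments. Unset keys keep their defaults.
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(gsub("[\"']", "", kv[2]))
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (is.na(num)) val else num
  }
  do.call(run_config, args)
}

#' Score one neutral/expression image pair
#'
#' Runs the full per-expression pipeline: interocular scaling of both
#' images, centering of the expression image on the reference canvas,
#' whole-landmark-set similarity alignment, mask construction on the
#' reference landmarks (with the above-eyebrow region removed), pre-blur,
#' masked absolute grayscale difference, smoothing + amplification, and
#' the variance-weighted symmetry score.
#'
#' @param ref a neutral-reference `face_image`.
#' @param ref_lms its `landmark_set`.
#' @param expr an expression `face_image`.
#' @param expr_lms its `landmark_set`.
#' @param cfg a `run_config`.
#' @return a list with `result` (`symmetry_result`),
#'   `movement_intensity`, `diff` (`diff_map`), `mask` (`face_mask`),
#'   `aligned` (the registered expression `face_image`), `ref_scaled`
#'   (the scaled reference) and `transform`.
#' @export
score_expression_pair <- function(ref, ref_lms, expr, expr_lms,
                                  cfg = run_config()) {
  rs <- interocular_scale(ref, ref_lms, cfg$interocular_target)
  es <- interocular_scale(expr, expr_lms, cfg$interocular_target)
  ref_dims <- image_dims(rs$image)
  ec <- center_on_canvas(es$image, es$lms, ref_dims)
  tr <- estimate_alignment(ec$lms, rs$lms)
  aligned <- warp_image(ec$image, tr, ref_dims)

  mask <- remove_brow_region(build_mask(rs$lms, ref_dims, cfg$padding_frac),
                             rs$lms)
  raw <- abs_diff_gray(preblur(rs$image, cfg$preblur_kernel),
                       preblur(aligned, cfg$preblur_kernel), mask)
  d <- smooth_amplify(raw, cfg$smooth_kernel, cfg$amplification)
  res <- symmetry_score(d, mask, score_config(cfg$sigma2_max),
                        expr$expression_index)
  list(result = res, movement_intensity = movement_intensity(d, mask),
       diff = d, mask = mask, aligned = aligned, ref_scaled = rs$image,
       transform = tr)
}

visit_landmarks <- function(vdir, n, image, cfg) {
  if (identical(cfg$provider, "stored")) {
    side <- file.path(vdir, sprintf("expr_%d.landmarks.json", n))
    if (!file.exists(side)) stop("missing landmark sidecar: ", side)
    read_landmarks(side)
  } else {
    detect_landmarks(image, cfg$provider,
                     label = file.path(vdir, sprintf("expr_%d", n)))
  }
}

#' Score every expression of one visit directory
#'
#' A visit directory holds `expr_1.png` (neutral reference) plus any of
#' `expr_2.png` .. `expr_9.png`; with `provider = "stored"`, each image
#' has a `expr_<n>.landmarks.json` sidecar. Expressions whose processing
#' fails are skipped with a logged error; a missing neutral image fails
#' the visit.
#'
#' @param vdir visit directory.
#' @param cfg a `run_config`.
#' @param heatmap_dir optional directory to write heatmap PNGs into.
#' @return a list with `rows` (data.frame: expression_index, s_mean,
#'   variance, score, n_valid, movement_intensity, low_movement) and
#'   `errors` (character vector).
#' @export
score_visit <- function(vdir, cfg = run_config(), heatmap_dir = NULL) {
  errors <- character()
  neutral_path <- file.path(vdir, "expr_1.png")
  if (!file.exists(neutral_path)) {
    stop("missing neutral reference image: ", neutral_path)
  }
  ref <- read_face_image(neutral_path, 1L)
  ref_lms <- visit_landmarks(vdir, 1L, ref, cfg)
  rows <- list()
  for (n in 2:9) {
    p <- file.path(vdir, sprintf("expr_%d.png", n))
    if (!file.exists(p)) next
    row <- tryCatch({
      expr <- read_face_image(p, n)
      expr_lms <- visit_landmarks(vdir, n, expr, cfg)
      out <- score_expression_pair(ref, ref_lms, expr, expr_lms, cfg)
      if (!is.null(heatmap_dir)) {
        dir.create(heatmap_dir, recursive = TRUE, showWarnings = FALSE)
        write_face_image(render_heatmap(out$diff),
                         file.path(heatmap_dir, sprintf("heatmap_%d.png", n)))
      }
      r <- out$result
      data.frame(expression_index = n, s_mean = r$s_mean,
                 variance = r$variance, score = r$score, n_valid = r$n_valid,
                 movement_intensity = out$movement_intensity)
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", p, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(expression_index = integer(), s_mean = numeric(),
               variance = numeric(), score = numeric(), n_valid = integer(),
               movement_intensity = numeric())
  rows <- flag_insufficient_movement(rows, cfg)
  list(rows = rows, errors = errors)
}

#' Flag expressions with insufficient movement
#'
#' Adds a logical `low_movement` column: `TRUE` where the movement
#' intensity falls strictly below `cfg$movement_intensity_min`. A flagged
#' expression was likely performed hesitantly, so its (often high)
#' symmetry score may not be justified; flagged rows are annotated, never
#' removed.
#'
#' @param rows data.frame with a `movement_intensity` column.
#' @param cfg a `run_config`.
#' @return `rows` with the `low_movement` column added.
#' @export
flag_insufficient_movement <- function(rows, cfg = run_config()) {
  rows$low_movement <- rows$movement_intensity < cfg$movement_intensity_min
  rows
}

#' Run the full pipeline over a dataset directory
#'
#' Expects the layout `input_dir/<patient_id>/<visit_date>/expr_<n>.png`.
#' Every expression image yields one result row; patients with at least
#' two scored visits get a robust trend; a cohort summary counts trend
#' labels. Visits without a neutral image and expressions that fail are
#' skipped with logged errors. Writes `scores.csv`, `trends.csv`,
#' `summary.json` and per-visit heatmaps under `output_dir` when given.
#'
#' @param input_dir dataset root directory.
#' @param cfg a `run_config`.
#' @param output_dir optional output directory.
#' @return a list with `scores` (data.frame), `trends` (data.frame),
#'   `summary` (list) and `errors` (character vector), invisibly when
#'   `output_dir` is set.
#' @export
run_dataset <- function(input_dir, cfg = run_config(), output_dir = NULL) {
  patients <- list.dirs(input_dir, recursive = FALSE)
  scores <- list(); errors <- character()
  for (pdir in patients) {
    pid <- basename(pdir)
    for (vdir in list.dirs(pdir, recursive = FALSE)) {
      vdate <- basename(vdir)
      hm_dir <- if (is.null(output_dir)) NULL else
        file.path(output_dir, "heatmaps", pid, vdate)
      vis <- tryCatch(score_visit(vdir, cfg, hm_dir), error = function(e) {
        errors <<- c(errors, sprintf("%s: %s", vdir, conditionMessage(e)))
        NULL
      })
      if (is.null(vis)) next
      errors <- c(errors, vis$errors)
      if (nrow(vis$rows)) {
        vis$rows <- cbind(patient_id = pid, visit_date = vdate, vis$rows)
        scores[[length(scores) + 1L]] <- vis$rows
      }
    }
  }
  scores <- if (length(scores)) do.call(rbind, scores) else
    data.frame(patient_id = character(), visit_date = character(),
               expression_index = integer(), s_mean = numeric(),
               variance = numeric(), score = numeric(), n_valid = integer(),
               movement_intensity = numeric(), low_movement = logical())
  trends <- dataset_trends(scores, cfg)
  summary <- list(
    n_patients = length(unique(scores$patient_id)),
    n_visits = nrow(unique(scores[c("patient_id", "visit_date")])),
    n_expressions = nrow(scores),
    trend_counts = as.list(table(factor(trends$label, levels = c(
      "improvement", "deterioration", "no_significant_change")))),
    n_errors = length(errors)
  )
  out <- list(scores = scores, trends = trends, summary = summary,
              errors = errors)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(scores, file.path(output_dir, "scores.csv"), row.names = FALSE)
    write.csv(trends, file.path(output_dir, "trends.csv"), row.names = FALSE)
    jsonlite::write_json(c(summary, list(errors = errors)),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Per-patient trends from a scores table
#'
#' Aggregates the per-expression scores of each visit (see
#' [aggregate_visit_score()]), orders visits by date and computes the
#' robust trend for every patient with at least two visits.
#'
#' @param scores data.frame with columns `patient_id`, `visit_date`,
#'   `expression_index`, `score`.
#' @param cfg a `run_config`.
#' @return data.frame with columns `patient_id`, `n_visits`, `slope`,
#'   `label`.
#' @export
dataset_trends <- function(scores, cfg = run_config()) {
  out <- list()
  for (pid in unique(scores$patient_id)) {
    sub <- scores[scores$patient_id == pid, ]
    visits <- sort(unique(sub$visit_date))
    if (length(visits) < 2L) next
    agg <- vapply(visits, function(v) {
      s <- sub$score[sub$visit_date == v]
      names(s) <- sub$expression_index[sub$visit_date == v]
      aggregate_visit_score(s, cfg$aggregate)
    }, numeric(1))
    tr <- score_trend(unname(agg), dates = visits,
                      window = cfg$rolling_window,
                      tau = cfg$trend_threshold)
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid, n_visits = length(visits),
      slope = tr$slope, label = tr$label)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), n_visits = integer(),
               slope = numeric(), label = character())
}

#' Correlate symmetry scores with ordinal clinical grades
#'
#' Joins a scores table with a grades table on patient and visit date and
#' computes, per expression, the Spearman rank correlation between grade
#' and score (see [spearman_correlation()]).
#'
#' @param scores data.frame with `patient_id`, `visit_date`,
#'   `expression_index`, `score`.
#' @param grades data.frame with `patient_id`, `visit_date`, `grade`
#'   (integer 0-6).
#' @return data.frame with columns `expression_index`, `n`, `r`, `p`,
#'   `significant`.
#' @export
correlate_with_grades <- function(scores, grades) {
  bad <- !is.na(grades$grade) &
    (grades$grade < 0 | grades$grade > 6 | grades$grade != round(grades$grade))
  if (any(bad)) stop("clinical grades must be integers in 0..6")
  merged <- merge(scores, grades, by = c("patient_id", "visit_date"))
  out <- list()
  for (e in sort(unique(merged$expression_index))) {
    sub <- merged[merged$expression_index == e, ]
    sc <- tryCatch(spearman_correlation(sub$grade, sub$score),
                   error = function(err) NULL)
    if (is.null(sc)) next
    out[[length(out) + 1L]] <- data.frame(
      expression_index = e, n = sc$n, r = sc$r, p = sc$p,
      significant = sc$significant)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(expression_index = integer(), n = integer(), r = numeric(),
               p = numeric(), significant = logical())
}
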