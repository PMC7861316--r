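#' Load a scoring rubric from YAML
#'
#' A rubric is an ordered list of metric specifications.  Each metric has a
#' structure, a dosimetric quantity, a maximum point value and -- except for
#' binary metrics -- a full-credit and a zero-credit threshold in the
#' metric's units (optionally prescription-relative).  Points ramp linearly
#' between the two thresholds.
#'
#' @param path YAML file; see the packaged
#'   `extdata/rubric_default.yaml` for the schema.
#' @return An object of class `scoring_rubric`: list with `name`, `version`
#'   and `metrics` (list of metric specs).
#' @export
read_rubric <- function(path) {
  raw <- yaml::read_yaml(path)
  metrics <- lapply(raw$metrics, function(m) {
    m$max_points <- as.numeric(m$max_points)
    stopifnot(m$max_points >= 0,
              m$direction %in% c("higher", "lower", "binary"))
    if (m$direction != "binary") {
      f <- m$full$value; z <- m$zero$value
      if (isTRUE(m$full$rel_rx) != isTRUE(m$zero$rel_rx))
        stop("metric '", m$id, "': thresholds must share the rel_rx flag")
      if (m$direction == "lower" && !(f < z))
        stop("metric '", m$id, "': lower-is-better needs full < zero")
      if (m$direction == "higher" && !(f > z))
        stop("metric '", m$id, "': higher-is-better needs full > zero")
    }
    m
  })
  ids <- vapply(metrics, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate metric ids in rubric")
  structure(list(name = raw$name, version = raw$version, metrics = metrics),
            class = "scoring_rubric")
}

#' The default 164-point rubric
#'
#' Eighteen metrics across target (75 points), lung (35), heart (22),
#' esophagus (12) and spinal cord (20), totalling 164.
#'
#' @return A `scoring_rubric`.
#' @export
default_rubric <- function() {
  read_rubric(system.file("extdata", "rubric_default.yaml",
                          package = "rtplanscore"))
}

#' Total maximum points of a rubric
#' @param rubric a `scoring_rubric`.
#' @export
rubric_total <- function(rubric) {
  stopifnot(inherits(rubric, "scoring_rubric"))
  sum(vapply(rubric$metrics, `[[`, numeric(1), "max_points"))
}

#' @export
print.scoring_rubric <- function(x, ...) {
  cat(sprintf("<scoring_rubric '%s' v%s: %d metrics, %.6g max points>\n",
              x$name, x$version, length(x$metrics), rubric_total(x)))
  invisible(x)
}

#' Award points for a single metric value
#'
#' Piecewise-linear award: full `max_points` at or beyond the full-credit
#' threshold, 0 at or beyond the zero-credit threshold, linear in between,
#' clamped to `[0, max_points]`.  Binary metrics award `max_points` on
#' `TRUE`, 0 on `FALSE`.
#'
#' @param value metric value (in the spec's units; logical for binary).
#' @param spec one metric spec from a `scoring_rubric`.
#' @param prescription_gy prescription in Gy, needed when the spec's
#'   thresholds are prescription-relative.
#' @return points awarded (numeric).
#' @export
score_metric <- function(value, spec, prescription_gy = NULL) {
  if (spec$direction == "binary") {
    if (is.na(value)) stop("non-finite value for metric '", spec$id, "'")
    return(if (isTRUE(as.logical(value))) spec$max_points else 0)
  }
  if (!is.finite(value)) stop("non-finite value for metric '", spec$id, "'")
  f <- spec$full$value; z <- spec$zero$value
  if (isTRUE(spec$full$rel_rx)) {
    if (is.null(prescription_gy))
      stop("metric '", spec$id, "' has prescription-relative thresholds")
    f <- f * prescription_gy; z <- z * prescription_gy
  }
  pts <- spec$max_points * (z - value) / (z - f)
  min(max(pts, 0), spec$max_points)
}

#' @keywords internal
evaluate_metric <- function(case, spec, bin_width_gy = 0.05) {
  nm <- spec$structure
  mask <- case$structures[[nm]]
  if (is.null(mask) || !any(mask$inside)) return(NA_real_)
  dose <- case$dose
  q <- spec$quantity
  if (q %in% c("dose_at_volume", "volume_at_dose")) {
    dvh <- compute_dvh(dose, mask, bin_width_gy = bin_width_gy, structure = nm)
    if (q == "dose_at_volume") return(dose_at_volume(dvh, spec$args$volume_percent))
    return(volume_at_dose(dvh, spec$args$dose_gy))
  }
  if (q %in% c("min_dose", "max_dose", "mean_dose")) {
    s <- summary_stats(dose, mask)
    return(switch(q, min_dose = s$Dmin, max_dose = s$Dmax, mean_dose = s$Dmean))
  }
  body <- case$structures[["body"]]
  ptv <- case$structures[["ptv"]]
  if (q == "conformation_number")
    return(conformation_number(dose, ptv, case$prescription_gy,
                               iso_fraction = spec$args$iso_fraction, body = body))
  if (q == "conformity_index")
    return(conformity_index(dose, ptv, case$prescription_gy,
                            iso_fraction = spec$args$iso_fraction, body = body))
  if (q == "max_in_ptv")
    return(max_dose_location(dose, ptv, body = body)$inside_ptv)
  stop("unknown metric quantity: ", q)
}

#' Score a plan against a rubric
#'
#' Evaluates every rubric metric on the case's dose via the DVH engine and
#' awards points with [score_metric()].  A metric whose structure is absent
#' or empty (typically the GTV) is skipped with 0 points and a warning
#' unless `missing_structure = "error"`.
#'
#' @param case an [rt_case()] with a dose.
#' @param rubric a `scoring_rubric` (default [default_rubric()]).
#' @param plan_label label attached to the report.
#' @param missing_structure `"skip"` (default) or `"error"`.
#' @param bin_width_gy DVH bin width used for DVH-derived metrics.
#' @return An object of class `score_report`: per-metric data frame
#'   (`id`, `label`, `structure`, `value`, `points`, `max_points`),
#'   `raw_score`, `percentage_score`, labels and the rubric name.
#' @export
score_plan <- function(case, rubric = default_rubric(), plan_label = "",
                       missing_structure = c("skip", "error"),
                       bin_width_gy = 0.05) {
  stopifnot(inherits(case, "rt_case"), inherits(rubric, "scoring_rubric"))
  missing_structure <- match.arg(missing_structure)
  if (is.null(case$dose)) stop("case '", case$label, "' has no dose to score")
  rows <- lapply(rubric$metrics, function(spec) {
    value <- evaluate_metric(case, spec, bin_width_gy = bin_width_gy)
    if (length(value) == 1L && is.na(value) && spec$direction != "binary") {
      if (missing_structure == "error")
        stop("structure '", spec$structure, "' required by metric '",
             spec$id, "' is missing or empty")
      warning("structure '", spec$structure, "' missing: metric '",
              spec$id, "' scored 0", call. = FALSE)
      pts <- 0; value <- NA_real_
    } else {
      pts <- score_metric(value, spec, case$prescription_gy)
    }
    data.frame(id = spec$id, label = spec$label, structure = spec$structure,
               value = as.numeric(value), points = pts,
               max_points = spec$max_points, stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  raw <- sum(metrics$points)
  structure(list(metrics = metrics, raw_score = raw,
                 percentage_score = percentage_score(raw, rubric),
                 case_label = case$label, plan_label = plan_label,
                 rubric_name = rubric$name, rubric_total = rubric_total(rubric)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report case '%s' plan '%s': raw %.2f / %g (%.2f%%)>\n",
              x$case_label, x$plan_label, x$raw_score, x$rubric_total,
              x$percentage_score))
  invisible(x)
}

#' Normalize a raw score to a percentage of the rubric total
#'
#' @param raw raw score in `[0, total]`.
#' @param rubric a `scoring_rubric` (default rubric total: 164).
#' @return percentage in `[0, 100]` (full precision; reports render it to
#'   two decimals).
#' @export
percentage_score <- function(raw, rubric = default_rubric()) {
  total <- rubric_total(rubric)
  if (any(raw < 0 | raw > total))
    stop("raw score out of range [0, ", total, "]")
  100 * raw / total
}

#' Difference between two plans' scores
#'
#' @param a,b `score_report` objects scored with the same rubric.
#' @return list with `raw_difference` (`raw(a) - raw(b)`),
#'   `percentage_difference` and a per-metric `deltas` data frame.
#' @export
compare_plans <- function(a, b) {
  stopifnot(inherits(a, "score_report"), inherits(b, "score_report"))
  if (!identical(a$rubric_name, b$rubric_name) ||
      !identical(a$metrics$id, b$metrics$id))
    stop("score reports use different rubrics and cannot be compared")
  deltas <- data.frame(id = a$metrics$id,
                       points_a = a$metrics$points, points_b = b$metrics$points,
                       delta = a$metrics$points - b$metrics$points,
                       stringsAsFactors = FALSE)
  list(raw_difference = a$raw_score - b$raw_score,
       percentage_difference = a$percentage_score - b$percentage_score,
       deltas = deltas)
}

#' Cohort summary of score reports or a printed score table
#'
#' Accepts either a list of `score_report` objects or a data frame with any
#' of the numeric columns `raw_score`, `percentage_score`,
#' `score_difference`, and returns the arithmetic means (the summary rows
#' rendered by the reporting layer use one decimal).
#'
#' @param reports list of `score_report` or a data frame.
#' @return list with `n` and the available means (`mean_raw`,
#'   `mean_percentage`, `mean_difference`).
#' @export
aggregate_reports <- function(reports) {
  if (is.data.frame(reports)) {
    if (nrow(reports) == 0L) stop("empty score table")
    out <- list(n = nrow(reports))
    if ("raw_score" %in% names(reports))
      out$mean_raw <- mean(reports$raw_score)
    if ("percentage_score" %in% names(reports))
      out$mean_percentage <- mean(reports$percentage_score)
    if ("score_difference" %in% names(reports))
      out$mean_difference <- mean(reports$score_difference)
    return(out)
  }
  if (length(reports) == 0L) stop("empty report list")
  stopifnot(all(vapply(reports, inherits, logical(1), "score_report")))
  list(n = length(reports),
       mean_raw = mean(vapply(reports, `[[`, numeric(1), "raw_score")),
       mean_percentage = mean(vapply(reports, `[[`, numeric(1),
                                     "percentage_score")))
}

#' Bundled study score tables
#'
#' Score tables from a five-trainee lung IMRT planning training study,
#' shipped as plain CSV.  `benchmark_score_table()` holds each trainee's
#' pre- ("initial") and post-training ("final") raw and percentage scores on
#' the benchmark case; `training_score_table()` holds the raw scores and
#' the differences to the clinically delivered plan for the five training
#' cases.  Used to validate the rubric's normalization and aggregation
#' arithmetic.
#'
#' @return data frame.
#' @export
benchmark_score_table <- function() {
  utils::read.csv(system.file("extdata", "benchmark_scores.csv",
                              package = "rtplanscore"))
}

#' @rdname benchmark_score_table
#' @export
training_score_table <- function() {
  utils::read.csv(system.file("extdata", "training_scores.csv",
                              package = "rtplanscore"))
}
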