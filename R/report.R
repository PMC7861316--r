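# Comparison reports: trainee plan vs reference plan vs model prediction.

#' Build a comparison report for one case
#'
#' Scores every supplied plan dose on the case, computes pairwise raw-score
#' differences against the first plan, and (when a DVH model is supplied)
#' attaches the model-predicted achievable OAR DVHs.
#'
#' @param case an [rt_case()] (its own dose, if any, is ignored).
#' @param plan_doses named list of [dose_grid()] objects on the case
#'   geometry; at least one.
#' @param model optional `dvh_model` for predicted DVHs.
#' @param rubric a `scoring_rubric`.
#' @return An object of class `comparison_report`: per-plan `score_report`s,
#'   `differences` (vs the first plan), optional `predicted_dvh`.
#' @export
build_comparison_report <- function(case, plan_doses, model = NULL,
                                    rubric = default_rubric()) {
  stopifnot(inherits(case, "rt_case"), length(plan_doses) >= 1,
            !is.null(names(plan_doses)))
  g <- case_geometry(case)
  reports <- list()
  for (nm in names(plan_doses)) {
    d <- plan_doses[[nm]]
    stopifnot(inherits(d, "dose_grid"))
    if (!same_geometry(d$geometry, g))
      stop("plan '", nm, "' is not on the case geometry")
    cs <- case
    cs$dose <- d
    reports[[nm]] <- score_plan(cs, rubric, plan_label = nm)
  }
  ref <- names(plan_doses)[1]
  differences <- lapply(names(plan_doses)[-1], function(nm)
    c(list(plan = nm, reference = ref), compare_plans(reports[[nm]], reports[[ref]])))
  pred <- NULL
  if (!is.null(model))
    pred <- predict_dvh(model, case, case$prescription_gy)
  structure(list(case_label = case$label, reports = reports,
                 differences = differences, predicted_dvh = pred,
                 rubric_name = rubric$name),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report case '%s': %d plans%s>\n", x$case_label,
              length(x$reports),
              if (is.null(x$predicted_dvh)) "" else " + predicted DVHs"))
  for (nm in names(x$reports)) print(x$reports[[nm]])
  invisible(x)
}

#' @keywords internal
.fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' Render a score report or comparison report to a file
#'
#' Deterministic rendering with scores formatted to two decimals (as in
#' study score tables).  Formats: per-metric CSV, JSON (full precision), or
#' a markdown table.
#'
#' @param report a `score_report` or `comparison_report`.
#' @param path output file.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_scorecard <- function(report, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  if (inherits(report, "comparison_report")) {
    reports <- report$reports
  } else if (inherits(report, "score_report")) {
    reports <- stats::setNames(list(report), report$plan_label)
  } else stop("cannot render object of class ", class(report)[1])
  if (format == "json") {
    payload <- list(format = "rtplanscore_scorecard", version = 1L,
                    case = reports[[1]]$case_label,
                    rubric = reports[[1]]$rubric_name,
                    plans = lapply(reports, function(r)
                      list(plan = r$plan_label, raw_score = r$raw_score,
                           percentage_score = r$percentage_score,
                           metrics = r$metrics)))
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", na = "null"), path)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(reports, function(r) {
    m <- r$metrics
    rbind(data.frame(plan = r$plan_label, id = m$id, label = m$label,
                     value = m$value, points = m$points,
                     max_points = m$max_points),
          data.frame(plan = r$plan_label, id = "total", label = "Total",
                     value = NA_real_, points = r$raw_score,
                     max_points = r$rubric_total),
          data.frame(plan = r$plan_label, id = "percentage",
                     label = "Percentage score", value = NA_real_,
                     points = r$percentage_score, max_points = 100))
  }))
  rownames(rows) <- NULL
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    lines <- c("| Plan | Metric | Value | Points | Max |",
               "|------|--------|-------|--------|-----|",
               sprintf("| %s | %s | %s | %s | %g |", rows$plan, rows$label,
                       ifelse(is.na(rows$value), "", .fmt2(rows$value)),
                       .fmt2(rows$points), rows$max_points))
    writeLines(lines, path)
  }
  invisible(path)
}
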