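test_that("default rubric structure: 18 metrics, 164 points, category sums", {
  r <- default_rubric()
  expect_length(r$metrics, 18)
  expect_equal(rubric_total(r), 164)
  pts_by <- function(structs) sum(vapply(r$metrics, function(m)
    if (m$structure %in% structs) m$max_points else 0, numeric(1)))
  expect_equal(pts_by(c("ptv", "gtv")), 75)
  expect_equal(pts_by("lungs"), 35)
  expect_equal(pts_by("heart"), 22)
  expect_equal(pts_by("esophagus"), 12)
  expect_equal(pts_by(c("cord", "cord+3mm")), 20)
})

test_that("piecewise-linear award: boundaries, midpoint, clamping", {
  spec <- list(id = "x", direction = "lower", max_points = 10,
               full = list(value = 20), zero = list(value = 37))
  expect_equal(score_metric(20, spec), 10)
  expect_equal(score_metric(37, spec), 0)
  expect_equal(score_metric(28.5, spec), 10 * (37 - 28.5) / 17)  # = 5
  expect_equal(score_metric(28.5, spec), 5)
  expect_equal(score_metric(5, spec), 10)     # clamp above
  expect_equal(score_metric(99, spec), 0)     # clamp below
  hi <- list(id = "y", direction = "higher", max_points = 21,
             full = list(value = 0.98, rel_rx = TRUE),
             zero = list(value = 0.90, rel_rx = TRUE))
  expect_equal(score_metric(0.98 * 60, hi, prescription_gy = 60), 21)
  expect_equal(score_metric(0.90 * 60, hi, prescription_gy = 60), 0)
  expect_equal(score_metric(0.94 * 60, hi, prescription_gy = 60), 10.5)
  bin <- list(id = "b", direction = "binary", max_points = 10)
  expect_equal(score_metric(TRUE, bin), 10)
  expect_equal(score_metric(FALSE, bin), 0)
  expect_error(score_metric(NaN, spec), "non-finite")
})

test_that("award is monotone: worsening a value never raises the points", {
  lo <- list(id = "l", direction = "lower", max_points = 7,
             full = list(value = 10), zero = list(value = 30))
  vals <- seq(0, 40, by = 0.5)
  pts <- vapply(vals, score_metric, numeric(1), spec = lo)
  expect_true(all(diff(pts) <= 1e-12))
})

test_that("a uniform-prescription PTV plan earns every point", {
  rep <- score_plan(full_credit_case())
  expect_equal(rep$raw_score, 164)
  expect_equal(rep$percentage_score, 100)
})

test_that("an everywhere-failing plan earns zero points", {
  cs <- small_phantom()
  g <- rtplanscore:::case_geometry(cs)
  vals <- array(2 * cs$prescription_gy, g$dims)
  vals[cs$structures$ptv$inside] <- 0
  cs$dose <- dose_grid(g, vals)
  rep <- score_plan(cs)
  expect_equal(rep$raw_score, 0)
})

test_that("degrading only lung V20 loses exactly that metric's points", {
  cs <- full_credit_case()
  g <- rtplanscore:::case_geometry(cs)
  vals <- cs$dose$values + 0
  lung <- which(cs$structures$lungs$inside)
  k <- round(0.285 * length(lung))
  vals[lung[seq_len(k)]] <- 21          # above 20 Gy, below every other threshold
  cs$dose <- dose_grid(g, vals)
  rep <- score_plan(cs)
  v20 <- rep$metrics$value[rep$metrics$id == "lung_v20"]
  expect_equal(v20, 100 * k / length(lung))
  expected_award <- 10 * (37 - v20) / 17
  expect_equal(rep$raw_score, 164 - 10 + expected_award, tolerance = 1e-9)
  # all other metrics still at full credit
  others <- rep$metrics[rep$metrics$id != "lung_v20", ]
  expect_equal(others$points, others$max_points)
})

test_that("a missing GTV is skipped with a warning and zero points", {
  cs <- full_credit_case()
  cs$structures$gtv <- NULL
  expect_warning(rep <- score_plan(cs), "gtv")
  expect_equal(rep$raw_score, 164 - 10)
  expect_error(suppressWarnings(
    score_plan(cs, missing_structure = "error")), "gtv")
})

test_that("scoring is deterministic", {
  a <- score_plan(full_credit_case())
  b <- score_plan(full_credit_case())
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$raw_score, b$raw_score)
})

test_that("percentage normalization is linear and validated", {
  r <- default_rubric()
  expect_equal(percentage_score(0, r), 0)
  expect_equal(percentage_score(164, r), 100)
  expect_equal(percentage_score(82, r), 50)
  expect_error(percentage_score(-1, r), "range")
  expect_error(percentage_score(165, r), "range")
})

test_that("plan comparison: identity, antisymmetry, rubric guard", {
  a <- score_plan(full_credit_case(), plan_label = "a")
  expect_equal(compare_plans(a, a)$raw_difference, 0)
  cs <- small_phantom()
  g <- rtplanscore:::case_geometry(cs)
  vals <- array(0, g$dims); vals[cs$structures$ptv$inside] <- 0.92 * 60
  cs$dose <- dose_grid(g, vals)
  b <- score_plan(cs, plan_label = "b")
  ab <- compare_plans(a, b); ba <- compare_plans(b, a)
  expect_equal(ab$raw_difference, -ba$raw_difference)
  expect_equal(ab$deltas$delta, -ba$deltas$delta)
  other <- a; other$rubric_name <- "other"
  expect_error(compare_plans(a, other), "rubric")
})

test_that("score differences imply a consistent clinical score per case", {
  # two rows of the same training case must imply one clinical raw score
  tab <- training_score_table()
  easy1 <- tab[tab$case == "easy1", ]
  clinical <- easy1$raw_score[easy1$trainee == 2] -
    easy1$score_difference[easy1$trainee == 2]
  expect_equal(clinical, 117.10)
  expect_equal(easy1$raw_score[easy1$trainee == 3] - clinical,
               easy1$score_difference[easy1$trainee == 3])
})

test_that("aggregation averages reports and printed tables", {
  reps <- list(score_plan(full_credit_case(), plan_label = "p1"),
               score_plan(full_credit_case(), plan_label = "p2"))
  agg <- aggregate_reports(reps)
  expect_equal(agg$n, 2)
  expect_equal(agg$mean_raw, 164)
  expect_error(aggregate_reports(list()), "empty")
  expect_error(aggregate_reports(data.frame()), "empty")
})
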