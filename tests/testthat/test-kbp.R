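test_that("DTH: OAR inside the PTV has all mass at non-positive distance", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(20L, 20L, 20L))
  ptv <- array(FALSE, g$dims); ptv[5:16, 5:16, 5:16] <- TRUE
  oar <- array(FALSE, g$dims); oar[8:12, 8:12, 8:12] <- TRUE
  dth <- compute_dth(volume_mask(g, oar), volume_mask(g, ptv))
  expect_equal(dth$cumulative[findInterval(0, dth$bin_edges_mm)], 1)
  expect_true(all(diff(dth$cumulative) >= 0))
})

test_that("DTH of a disjoint OAR is zero below the gap distance", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(30L, 20L, 20L))
  ptv <- array(FALSE, g$dims); ptv[2:6, 5:15, 5:15] <- TRUE
  oar <- array(FALSE, g$dims); oar[12:14, 5:15, 5:15] <- TRUE
  # surface at x index 6 (x = 10 mm), OAR starts index 12 (x = 22): gap 12 mm
  dth <- compute_dth(volume_mask(g, oar), volume_mask(g, ptv))
  expect_true(all(dth$cumulative[dth$bin_edges_mm < 12] == 0))
  expect_gt(dth$cumulative[findInterval(12, dth$bin_edges_mm)], 0)
})

test_that("DTH matches a brute-force surface-distance oracle", {
  set.seed(9)
  g <- grid_geometry(c(0, 0, 0), c(2, 2.5, 3), c(12L, 11L, 10L))
  ptv <- array(FALSE, g$dims); ptv[4:8, 4:8, 4:7] <- TRUE
  oar <- array(stats::runif(prod(g$dims)) < 0.15, g$dims)
  pm <- volume_mask(g, ptv); om <- volume_mask(g, oar)
  # oracle: pairwise distance of OAR voxel centers to PTV surface voxels,
  # surface = PTV voxels with any 6-neighbour outside (grid border counts)
  m <- ptv
  all_in <- array(TRUE, dim(m))
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    shifted <- array(FALSE, dim(m))
    idx <- which(array(TRUE, dim(m)), arr.ind = TRUE)
    src <- sweep(idx, 2, sh, "+")
    ok <- src[, 1] >= 1 & src[, 1] <= dim(m)[1] & src[, 2] >= 1 &
      src[, 2] <= dim(m)[2] & src[, 3] >= 1 & src[, 3] <= dim(m)[3]
    shifted[idx[ok, , drop = FALSE]] <- m[src[ok, , drop = FALSE]]
    all_in <- all_in & shifted
  }
  surf <- which(m & !all_in, arr.ind = TRUE)
  sp <- g$spacing
  oi <- which(oar, arr.ind = TRUE)
  dmin <- apply(oi, 1, function(v)
    sqrt(min(colSums((t(surf) - v)^2 * sp^2))))
  sgn <- ifelse(ptv[which(oar)], -1, 1)
  oracle <- sort(sgn * dmin)
  edges <- seq(-50, 300, by = 2)
  oracle_cum <- findInterval(edges, oracle) / length(oracle)
  dth <- compute_dth(om, pm)
  expect_equal(dth$cumulative, oracle_cum, tolerance = 1e-12)
})

test_that("PCA bases are orthonormal and reconstruct exactly at full rank", {
  set.seed(5)
  X <- matrix(stats::rnorm(40 * 12), 40, 12)
  b <- rtplanscore:::.pca_basis(X, 12)
  expect_lt(max(abs(crossprod(b$components) - diag(ncol(b$components)))), 1e-8)
  scores <- sweep(X, 2, b$mean) %*% b$components
  Xr <- sweep(scores %*% t(b$components), 2, b$mean, "+")
  expect_lt(max(abs(X - Xr)), 1e-8)
})

test_that("feature extraction trivials hold", {
  cs <- small_phantom()
  cfg <- kbp_config(oars = c("heart", "cord"))
  # OAR fully inside the PTV: overlap = OAR volume, out-of-field = 0
  g <- rtplanscore:::case_geometry(cs)
  inner <- erode_mask(cs$structures$ptv, 10)
  cs2 <- cs
  cs2$structures$heart <- inner
  f <- extract_features(cs2, config = cfg)
  expect_equal(f$heart$overlap_volume_cc, f$heart$oar_volume_cc)
  expect_equal(f$heart$out_of_field_fraction, 0)
  expect_false(f$heart$absent)
  # missing OAR is marked absent
  cs3 <- cs
  cs3$structures$heart <- NULL
  f3 <- extract_features(cs3, config = cfg)
  expect_true(f3$heart$absent)
})

test_that("features are invariant to rigid translation of the whole case", {
  cs <- small_phantom()
  cfg <- kbp_config(oars = c("lungs", "cord"))
  shift <- function(case, d) {
    g <- rtplanscore:::case_geometry(case)
    g2 <- grid_geometry(g$origin + d, g$spacing, g$dims)
    case$structures <- lapply(case$structures,
                              function(m) volume_mask(g2, m$inside))
    case
  }
  f1 <- extract_features(cs, config = cfg)
  f2 <- extract_features(shift(cs, c(17.3, -4.2, 9.9)), config = cfg)
  for (nm in c("lungs", "cord")) {
    expect_equal(f2[[nm]]$dth$cumulative, f1[[nm]]$dth$cumulative)
    expect_equal(f2[[nm]]$oar_volume_cc, f1[[nm]]$oar_volume_cc)
    expect_equal(f2[[nm]]$out_of_field_fraction, f1[[nm]]$out_of_field_fraction)
  }
})

test_that("a degenerate cohort of identical cases predicts the common DVH", {
  coh <- kbp_clean_cohort()
  cs <- coh[[1]]
  cfg <- kbp_config(oars = kbp_oars())
  model <- fit_dvh_model(rep(list(cs), 15), cfg)
  pred <- predict_dvh(model, cs, cs$prescription_gy)
  for (nm in names(pred)) {
    truth <- rtplanscore:::relative_dvh_curve(
      cs$dose, cs$structures[[nm]], cs$prescription_gy, cfg$dvh_grid)
    expect_lt(max(abs(pred[[nm]]$cumulative_volume - truth)), 1e-6)
  }
})

test_that("training-order permutation leaves predictions unchanged", {
  coh <- kbp_clean_cohort()[1:20]
  cfg <- kbp_config(oars = kbp_oars())
  m1 <- fit_dvh_model(coh, cfg)
  set.seed(1)
  m2 <- fit_dvh_model(coh[sample(20)], cfg)
  test <- kbp_clean_cohort()[[70]]
  p1 <- predict_dvh(m1, test, test$prescription_gy)
  p2 <- predict_dvh(m2, test, test$prescription_gy)
  for (nm in names(p1))
    expect_equal(p1[[nm]]$cumulative_volume, p2[[nm]]$cumulative_volume,
                 tolerance = 1e-8)
})

test_that("predicted curves are monotone, bounded and anchored at 100%", {
  model <- kbp_clean_model()
  set.seed(8)
  test_cases <- kbp_clean_cohort()[61:64]
  for (cs in test_cases) {
    pred <- predict_dvh(model, cs, cs$prescription_gy)
    for (nm in names(pred)) {
      cv <- pred[[nm]]$cumulative_volume
      expect_equal(cv[1], 100)
      expect_true(all(diff(cv) <= 1e-12))
      expect_true(all(cv >= 0 & cv <= 100))
    }
  }
  # and for deliberately extreme feature vectors
  cs <- test_cases[[1]]
  f <- extract_features(cs, model = model)
  for (nm in names(model$per_oar)) f[[nm]]$vector <- f[[nm]]$vector * 5 + 3
  pred <- predict_dvh(model, f, 60)
  for (nm in names(pred)) {
    cv <- pred[[nm]]$cumulative_volume
    expect_true(all(diff(cv) <= 1e-12) && all(cv >= 0 & cv <= 100))
  }
})

test_that("the model file roundtrips through save/load", {
  model <- kbp_clean_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_dvh_model(model, path)
  back <- load_dvh_model(path)
  cs <- kbp_clean_cohort()[[65]]
  p1 <- predict_dvh(model, cs, cs$prescription_gy)
  p2 <- predict_dvh(back, cs, cs$prescription_gy)
  for (nm in names(p1))
    expect_equal(p2[[nm]]$cumulative_volume, p1[[nm]]$cumulative_volume,
                 tolerance = 1e-12)
})

test_that("too few training cases is a descriptive failure", {
  coh <- kbp_clean_cohort()[1:5]
  expect_error(fit_dvh_model(coh, kbp_config(oars = "lungs")), "at least 14")
})
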