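# brute-force DVH statistics from the explicit voxel dose list
oracle_v_at_d <- function(d, dose_gy) 100 * mean(d >= dose_gy)
oracle_d_at_v <- function(d, v) {
  # largest dose received by at least v% of voxels
  s <- sort(d, decreasing = TRUE)
  k <- ceiling(v / 100 * length(d))
  s[k]
}

uniform_case <- function(gy = 10, n = 4L) {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(n, n, n))
  list(dose = dose_grid(g, array(gy, c(n, n, n))),
       mask = volume_mask(g, array(TRUE, c(n, n, n))))
}

ladder_case <- function() {
  # 100 voxels at 1..100 Gy
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(10L, 10L, 1L))
  list(dose = dose_grid(g, array(1:100, c(10, 10, 1))),
       mask = volume_mask(g, array(TRUE, c(10, 10, 1))))
}

test_that("DVH of a uniform field is a step at the dose level", {
  u <- uniform_case(10)
  dvh <- compute_dvh(u$dose, u$mask)
  expect_equal(dvh$cumulative_volume[1], 100)
  expect_true(all(diff(dvh$cumulative_volume) <= 0))
  expect_equal(volume_at_dose(dvh, 10), 100)
  expect_equal(volume_at_dose(dvh, 10.1), 0)
  expect_equal(dose_at_volume(dvh, 98), 10, tolerance = 0.05)
  expect_equal(utils::tail(dvh$cumulative_volume, 1), 0)
})

test_that("two equal voxels at 2 and 4 Gy give 50% at 3 Gy", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(2L, 1L, 1L))
  dose <- dose_grid(g, array(c(2, 4), c(2, 1, 1)))
  mask <- volume_mask(g, array(TRUE, c(2, 1, 1)))
  dvh <- compute_dvh(dose, mask)
  expect_equal(volume_at_dose(dvh, 3), 50)
})

test_that("doubling the dose doubles the DVH dose axis", {
  f <- random_field(21)
  dvh1 <- compute_dvh(f$dose, f$mask, bin_width_gy = 0.1)
  dvh2 <- compute_dvh(dose_grid(f$geometry, 2 * f$dose$values), f$mask,
                      bin_width_gy = 0.2)
  expect_equal(dvh2$cumulative_volume, dvh1$cumulative_volume)
  expect_equal(dvh2$bin_edges, 2 * dvh1$bin_edges)
})

test_that("the 1..100 Gy ladder reproduces the sort-and-count oracle", {
  l <- ladder_case()
  dvh <- compute_dvh(l$dose, l$mask)
  d <- as.vector(l$dose$values)
  expect_equal(dose_at_volume(dvh, 98), oracle_d_at_v(d, 98), tolerance = 0.051)
  expect_equal(dose_at_volume(dvh, 50), oracle_d_at_v(d, 50), tolerance = 0.051)
  expect_equal(volume_at_dose(dvh, 20), oracle_v_at_d(d, 20))   # 81%
  expect_equal(volume_at_dose(dvh, 0), 100)
  s <- summary_stats(l$dose, l$mask)
  expect_equal(s$Dmean, 50.5)
  expect_equal(s$Dmin, 1)
  expect_equal(s$Dmax, 100)
})

test_that("DVH metrics match the voxel-list oracle on random fields", {
  for (seed in 1:10) {
    f <- random_field(seed)
    d <- f$dose$values[f$mask$inside]
    dvh <- compute_dvh(f$dose, f$mask)
    s <- summary_stats(f$dose, f$mask)
    expect_identical(s$Dmin, min(d))
    expect_identical(s$Dmax, max(d))
    expect_identical(s$Dmean, mean(d))
    # V at bin-edge-aligned doses is exact
    for (dg in c(0, 5, 20, 40.25))
      expect_equal(volume_at_dose(dvh, dg), oracle_v_at_d(d, dg))
    # Dx within one bin width of the oracle
    for (v in c(98, 50, 2))
      expect_lt(abs(dose_at_volume(dvh, v) - oracle_d_at_v(d, v)), 0.05 + 1e-12)
    expect_true(all(diff(dvh$cumulative_volume) <= 0))
    expect_equal(dvh$cumulative_volume[1], 100)
  }
})

test_that("dose_at_volume and volume_at_dose are mutually consistent", {
  f <- random_field(33)
  dvh <- compute_dvh(f$dose, f$mask)
  for (v in dvh$cumulative_volume[dvh$cumulative_volume > 0])
    expect_gte(volume_at_dose(dvh, dose_at_volume(dvh, v)) + 1e-9, v)
})

test_that("halving the bin width moves D98/V20 by less than one bin", {
  for (seed in 4:6) {
    f <- random_field(seed)
    a <- compute_dvh(f$dose, f$mask, bin_width_gy = 0.1)
    b <- compute_dvh(f$dose, f$mask, bin_width_gy = 0.05)
    expect_lt(abs(dose_at_volume(a, 98) - dose_at_volume(b, 98)), 0.1 + 1e-12)
    expect_lt(abs(volume_at_dose(a, 20) - volume_at_dose(b, 20)), 1e-9)
  }
})

test_that("empty masks are descriptive failures", {
  f <- random_field(2)
  empty <- volume_mask(f$geometry, array(FALSE, f$geometry$dims))
  expect_error(compute_dvh(f$dose, empty, structure = "lungs"), "lungs")
  expect_error(summary_stats(f$dose, empty), "empty")
})

# ---- conformity metrics -------------------------------------------------

test_that("CI equals the voxel-count construction (PIV50 = 3 x PTV)", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(30L, 30L, 30L))
  ptv <- array(FALSE, g$dims); ptv[3:27, 3:27, 3:22] <- FALSE
  ptv[6:25, 6:25, 5:9] <- TRUE            # 20*20*5 = 2000 voxels
  iso <- array(FALSE, g$dims); iso[6:25, 6:25, 5:19] <- TRUE  # 6000 voxels
  dose <- array(0, g$dims); dose[iso] <- 35      # >= 0.5 * 60
  d <- dose_grid(g, dose); pm <- volume_mask(g, ptv)
  expect_equal(conformity_index(d, pm, 60, 0.5), 3)
  # exactly-conformal isodose has CI = 1
  dose2 <- array(0, g$dims); dose2[ptv] <- 35
  expect_equal(conformity_index(dose_grid(g, dose2), pm, 60, 0.5), 1)
  # shrinking the isodose strictly decreases CI
  dose3 <- dose; dose3[, , 15:19] <- 0
  expect_lt(conformity_index(dose_grid(g, dose3), pm, 60, 0.5),
            conformity_index(d, pm, 60, 0.5))
})

test_that("CN follows the Paddick construction", {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), c(30L, 30L, 30L))
  ptv <- array(FALSE, g$dims); ptv[6:25, 6:25, 5:9] <- TRUE   # TV = 2000 vox
  d <- array(0, g$dims)
  d[6:25, 6:25, 5:14] <- 58                                   # PIV = 4000 vox
  dg <- dose_grid(g, d); pm <- volume_mask(g, ptv)
  # overlap = TV: CN = TV^2 / (TV * 2 TV) = 0.5
  expect_equal(conformation_number(dg, pm, 60, 0.95), 0.5)
  d2 <- array(0, g$dims); d2[ptv] <- 58
  expect_equal(conformation_number(dose_grid(g, d2), pm, 60, 0.95), 1)
  d3 <- array(0, g$dims); d3[1:3, 1:3, 25:28] <- 58           # disjoint PIV
  expect_equal(conformation_number(dose_grid(g, d3), pm, 60, 0.95), 0)
  d4 <- array(0, g$dims)                                      # empty PIV
  expect_equal(conformation_number(dose_grid(g, d4), pm, 60, 0.95), 0)
  # CN <= min(TVPIV/TV, TVPIV/PIV) on random fields
  for (seed in 1:5) {
    f <- random_field(seed, dims = c(10L, 10L, 8L))
    piv <- f$dose$values >= 0.95 * 40
    tv <- sum(f$mask$inside); pv <- sum(piv)
    if (pv == 0) next
    ov <- sum(piv & f$mask$inside)
    cn <- conformation_number(f$dose, f$mask, 40, 0.95)
    expect_lte(cn, min(ov / tv, ov / pv) + 1e-12)
  }
})

test_that("max dose location reports PTV membership with scan-order ties", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(5L, 5L, 5L))
  ptv <- array(FALSE, g$dims); ptv[2:4, 2:4, 2:4] <- TRUE
  pm <- volume_mask(g, ptv)
  d <- array(1, g$dims); d[3, 3, 3] <- 50
  expect_true(max_dose_location(dose_grid(g, d), pm)$inside_ptv)
  d2 <- array(1, g$dims); d2[5, 5, 5] <- 50
  loc <- max_dose_location(dose_grid(g, d2), pm)
  expect_false(loc$inside_ptv)
  expect_equal(loc$value_gy, 50)
  expect_equal(loc$position_mm, c(4, 4, 4))
  # tie: in-PTV voxel at lower linear index wins
  d3 <- array(1, g$dims); d3[2, 2, 2] <- 50; d3[5, 5, 5] <- 50
  expect_true(max_dose_location(dose_grid(g, d3), pm)$inside_ptv)
  # tie the other way round
  d4 <- array(1, g$dims); d4[1, 1, 1] <- 50; d4[3, 3, 3] <- 50
  expect_false(max_dose_location(dose_grid(g, d4), pm)$inside_ptv)
})
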