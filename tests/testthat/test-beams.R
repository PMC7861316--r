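test_that("index is symmetric under 90-degree rotations of a symmetric case", {
  cs <- sym_cylinder_case()
  prof <- rank_beams(cs, beam_config(angles = c(0, 90, 180, 270)))
  idx <- prof$profile$index
  expect_lt((max(idx) - min(idx)) / mean(idx), 1e-6)
  # full-profile variation stays at voxelization level on a cylinder
  prof_all <- rank_beams(cs, beam_config())
  iall <- prof_all$profile$index
  expect_lt((max(iall) - min(iall)) / mean(iall), 0.02)
})

test_that("mirrored cases give mirrored index profiles", {
  a <- rank_beams(sym_cylinder_case(with_cord = TRUE, cord_x = 30),
                  beam_config())$profile
  b <- rank_beams(sym_cylinder_case(with_cord = TRUE, cord_x = -30),
                  beam_config())$profile
  a <- a[order(a$angle), ]; b <- b[order(b$angle), ]
  mirrored <- b$index[match((360 - a$angle) %% 360, b$angle)]
  expect_equal(a$index, mirrored, tolerance = 1e-6)
})

test_that("rotating the case rotates the index profile (equivariance)", {
  cs <- sym_cylinder_case(with_cord = TRUE, cord_x = 30)
  g <- rtplanscore:::case_geometry(cs)
  rot90 <- function(m) {
    # (x, y) -> (-y, x) on a square-in-plane centered grid
    out <- array(FALSE, dim(m))
    n <- dim(m)[1]
    for (k in seq_len(dim(m)[3]))
      out[, , k] <- t(m[, n:1, k])
    out
  }
  cs_rot <- cs
  cs_rot$structures <- lapply(cs$structures,
                              function(m) volume_mask(g, rot90(m$inside)))
  angles <- seq(0, 350, by = 10)
  p0 <- rank_beams(cs, beam_config(angles = angles))$profile
  p1 <- rank_beams(cs_rot, beam_config(angles = angles))$profile
  p0 <- p0[order(p0$angle), ]; p1 <- p1[order(p1$angle), ]
  rotated <- p1$index[match((p0$angle + 90) %% 360, p1$angle)]
  expect_equal(p0$index, rotated, tolerance = 1e-6)
})

test_that("a cord posterior to the target penalizes the posterior beam", {
  # cord at +y (posterior); beam from 180 deg traverses it, 0 deg spares it
  n <- 48L; h <- 4
  g <- grid_geometry(c(-(n - 1) / 2 * h, -(n - 1) / 2 * h, -46), c(h, h, 4),
                     c(n, n, 24L))
  xs <- grid_axis_mm(g, 1); ys <- grid_axis_mm(g, 2)
  body <- volume_mask(g, array(outer(xs^2, ys^2, "+") <= 90^2, g$dims))
  ptv <- voxelize_ellipsoid(g, c(0, -10, 0), c(22, 22, 22))
  cord <- voxelize_tube(g, function(z) c(0, 60), 6)
  cs <- rt_case(list(body = body,
                     ptv = volume_mask(g, ptv$inside & body$inside),
                     cord = volume_mask(g, cord$inside & body$inside)), 60)
  prof <- rank_beams(cs, beam_config(angles = c(0, 180)))$profile
  i0 <- prof$index[prof$angle == 0]; i180 <- prof$index[prof$angle == 180]
  expect_lt(i180, i0)
  p0 <- prof$penalty_cord[prof$angle == 0]
  p180 <- prof$penalty_cord[prof$angle == 180]
  # independent single-ray oracle: march source -> PTV centroid, count cord
  # path length before the target (where attenuation weighting is high)
  iso <- rtplanscore:::mask_centroid_mm(cs$structures$ptv)
  march_cord_mm <- function(angle) {
    src <- rtplanscore:::beam_source_position(angle, iso, 1000)
    dir <- (iso - src) / sqrt(sum((iso - src)^2))
    ss <- seq(0, sqrt(sum((iso - src)^2)), by = 1)
    pts <- t(src + outer(dir, ss))
    ijk <- round(sweep(sweep(pts, 2, g$origin), 2, g$spacing, "/")) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= g$dims[1] & ijk[, 2] >= 1 &
      ijk[, 2] <= g$dims[2] & ijk[, 3] >= 1 & ijk[, 3] <= g$dims[3]
    sum(cs$structures$cord$inside[ijk[ok, , drop = FALSE]])
  }
  expect_gt(march_cord_mm(180), 0)    # posterior entry crosses the cord
  expect_equal(march_cord_mm(0), 0)   # anterior entry reaches the target first
  expect_gt(p180, p0)
})

test_that("increasing an OAR weight never increases the index", {
  cs <- sym_cylinder_case(with_cord = TRUE, cord_x = 0)
  for (w in c(0.5, 1, 2, 4)) {
    i1 <- rank_beams(cs, beam_config(angles = 180,
                                     oar_weights = c(cord = w)))$profile$index
    i2 <- rank_beams(cs, beam_config(angles = 180,
                                     oar_weights = c(cord = 2 * w)))$profile$index
    expect_lte(i2, i1 + 1e-12)
  }
})

test_that("ranking is sorted with ties broken by the smaller angle", {
  cs <- sym_cylinder_case(with_cord = TRUE, cord_x = 30)
  prof <- rank_beams(cs, beam_config(angles = seq(0, 350, by = 10)))
  p <- prof$profile
  expect_true(all(diff(p$index) <= 1e-15))
  expect_equal(p$angle[1], p$angle[which.max(p$index)])
  ties <- const_profile()
  expect_equal(ties$profile$angle, seq(0, 355, by = 5))
})

test_that("greedy selection on a constant profile picks 0, 20, 40", {
  bq <- select_bouquet(const_profile(), 3, min_separation_deg = 20,
                       mode = "free")
  expect_equal(bq$beams$gantry_angle, c(0, 20, 40))
})

test_that("bouquets always honour the forced separation", {
  cs <- sym_cylinder_case(with_cord = TRUE, cord_x = 30)
  prof <- rank_beams(cs, beam_config())
  for (n in c(3, 7, 11)) {
    bq <- select_bouquet(prof, n, min_separation_deg = 20, mode = "free")
    a <- bq$beams$gantry_angle
    pair <- outer(a, a, rtplanscore:::circular_separation_deg)
    expect_true(all(pair[upper.tri(pair)] >= 20))
  }
})

test_that("greedy selection matches the brute-force separated triple", {
  cs <- sym_cylinder_case(with_cord = TRUE, cord_x = 30)
  prof <- rank_beams(cs, beam_config(angles = seq(0, 350, by = 10)))
  bq <- select_bouquet(prof, 3, min_separation_deg = 20, mode = "free")
  p <- prof$profile
  idx <- stats::setNames(p$index, p$angle)
  amax <- p$angle[1]
  expect_equal(bq$beams$gantry_angle[1], amax)   # first pick is the argmax
  sep <- rtplanscore:::circular_separation_deg
  others <- p$angle[sep(p$angle, amax) >= 20]
  best <- -Inf
  for (i in seq_along(others)) for (j in seq_len(i - 1)) {
    if (sep(others[i], others[j]) >= 20) {
      tot <- idx[as.character(amax)] + idx[as.character(others[i])] +
        idx[as.character(others[j])]
      best <- max(best, tot)
    }
  }
  expect_gte(sum(bq$beams$index) + 1e-9 * best, best)
})

test_that("selection is deterministic and validates its constraints", {
  cs <- sym_cylinder_case(with_cord = TRUE, cord_x = 30)
  prof <- rank_beams(cs, beam_config())
  b1 <- select_bouquet(prof, 8)
  b2 <- select_bouquet(prof, 8)
  expect_identical(b1$beams, b2$beams)
  expect_error(select_bouquet(prof, 3), "7 to 11")
  expect_error(select_bouquet(prof, 12), "7 to 11")
  expect_error(select_bouquet(prof, 10, min_separation_deg = 40), "infeasible")
  expect_error(select_bouquet(const_profile(seq(0, 350, by = 120)), 4,
                              min_separation_deg = 20, mode = "free"),
               "3 of 4")
})
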