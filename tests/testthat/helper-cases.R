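# Shared fixtures, built in code and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# benchmark-analog phantom at the default 2.5 mm grid
benchmark_phantom <- function() {
  cached("benchmark", make_thorax_phantom(reference_case_specs()$benchmark))
}

# small fast phantom (5 mm grid, small body) for plumbing tests
small_phantom_spec <- function(ptv_center_mm = c(20, 0, 0), label = "small",
                               ...) {
  phantom_spec(100, 60, ptv_center_mm = ptv_center_mm, spacing_mm = 5,
               body_semi_axes_mm = c(100, 80), z_extent_mm = 120,
               lung_semi_axes_mm = c(35, 55, 50), lung_offset_x_mm = 55,
               heart_center_mm = c(10, 10, -20),
               heart_semi_axes_mm = c(30, 28, 32),
               esophagus_center_mm = c(0, 25), cord_center_mm = c(0, 52),
               label = label, ...)
}

small_phantom <- function() cached("small_phantom",
                                   make_thorax_phantom(small_phantom_spec()))

# rotationally symmetric case: cylinder body + centered spherical PTV on a
# square-in-plane grid (so 90-degree rotations map the grid onto itself)
sym_cylinder_case <- function(with_cord = FALSE, cord_x = 30) {
  n <- 48L; h <- 4
  g <- grid_geometry(c(-(n - 1) / 2 * h, -(n - 1) / 2 * h, -46), c(h, h, 4),
                     c(n, n, 24L))
  xs <- grid_axis_mm(g, 1); ys <- grid_axis_mm(g, 2)
  body <- volume_mask(g, array(outer(xs^2, ys^2, "+") <= 90^2, g$dims))
  ptv <- voxelize_ellipsoid(g, c(0, 0, 0), c(25, 25, 25))
  ptv <- volume_mask(g, ptv$inside & body$inside)
  structures <- list(body = body, ptv = ptv)
  if (with_cord) {
    cord <- voxelize_tube(g, function(z) c(cord_x, 55), 6)
    structures$cord <- volume_mask(g, cord$inside & body$inside)
  }
  rt_case(structures, 60, label = "cylinder")
}

# crafted constant efficiency profile for selection-contract tests
const_profile <- function(angles = seq(0, 355, by = 5)) {
  pr <- data.frame(angle = angles, index = 1, benefit = 1)
  pr <- pr[order(-pr$index, pr$angle), ]
  structure(list(profile = pr, isocenter_mm = c(0, 0, 0),
                 config = beam_config(angles = angles)),
            class = "efficiency_profile")
}

# random dose field + mask on a small grid
random_field <- function(seed, dims = c(9L, 8L, 7L), max_gy = 70) {
  set.seed(seed)
  g <- grid_geometry(c(0, 0, 0), c(2, 2.5, 3), dims)
  dose <- dose_grid(g, array(stats::runif(prod(dims), 0, max_gy), dims))
  mask <- volume_mask(g, array(stats::runif(prod(dims)) < 0.5, dims))
  if (!any(mask$inside)) mask$inside[1] <- TRUE
  list(geometry = g, dose = dose, mask = mask)
}

kbp_oars <- function() c("lungs", "heart", "esophagus", "cord")

kbp_clean_cohort <- function() cached("kbp_clean", simulate_kbp_cohort(75, seed = 0))
kbp_noisy_cohort <- function() cached("kbp_noisy",
                                      simulate_kbp_cohort(75, seed = 0, noise_sd = 2))

kbp_clean_model <- function() cached("kbp_clean_model",
  fit_dvh_model(kbp_clean_cohort()[1:60], kbp_config(oars = kbp_oars())))

# held-out DVH errors of a model on test cases (percent volume)
kbp_heldout_errors <- function(model, test_cases) {
  cfg <- model$config
  unlist(lapply(test_cases, function(cs) {
    pred <- predict_dvh(model, cs, cs$prescription_gy)
    unlist(lapply(names(pred), function(nm) {
      truth <- rtplanscore:::relative_dvh_curve(
        cs$dose, cs$structures[[nm]], cs$prescription_gy, cfg$dvh_grid)
      pred[[nm]]$cumulative_volume - truth
    }))
  }))
}

# case with a uniform prescription dose inside the PTV and zero elsewhere:
# every rubric metric sits at or beyond its full-credit threshold.  The PTV
# is placed clear of every OAR so the OAR doses really are zero.
full_credit_case <- function() {
  cached("full_credit", {
    cs <- make_thorax_phantom(
      small_phantom_spec(ptv_center_mm = c(45, -25, 25), label = "clean"))
    g <- rtplanscore:::case_geometry(cs)
    vals <- array(0, g$dims)
    vals[cs$structures$ptv$inside] <- cs$prescription_gy
    cs$dose <- dose_grid(g, vals)
    cs
  })
}
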