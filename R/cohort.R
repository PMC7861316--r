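# Cohort generation: sampled thorax phantoms with beam bouquets and
# synthesized plan doses, spanning the easy/intermediate/hard spectrum.

#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Cohort specification
#'
#' @param n number of cases (`>= 1`).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the spec.
#' @param mix proportions of easy / intermediate / hard cases (sum to 1);
#'   counts are assigned by largest remainder.
#' @param spacing_mm grid spacing of the generated phantoms.
#' @param n_beams beams per synthesized plan (default 9).
#' @param with_dose synthesize plan doses (`TRUE`) or geometry only.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 0L, mix = c(easy = 0.4, intermediate = 0.2,
                                              hard = 0.4),
                        spacing_mm = 2.5, n_beams = 9L, with_dose = TRUE) {
  stopifnot(n >= 1, length(mix) == 3L, abs(sum(mix) - 1) < 1e-9, all(mix >= 0))
  names(mix) <- c("easy", "intermediate", "hard")
  structure(list(n = as.integer(n), seed = as.integer(seed), mix = mix,
                 spacing_mm = spacing_mm, n_beams = as.integer(n_beams),
                 with_dose = isTRUE(with_dose)),
            class = "cohort_spec")
}

#' @keywords internal
difficulty_counts <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# per-difficulty sampling of phantom parameters; volumes are log-normal
# around the reference case volumes, prescriptions follow the reference cases
#' @keywords internal
sample_phantom_spec <- function(difficulty, spacing_mm, label) {
  par <- switch(difficulty,
    easy = list(vol = 113.8, sdlog = 0.25, rx = 40),
    intermediate = list(vol = 453.0, sdlog = 0.15, rx = 60),
    hard = list(vol = 845.7, sdlog = 0.10, rx = 60))
  vol <- stats::rlnorm(1, meanlog = log(par$vol), sdlog = par$sdlog)
  r <- (3 * vol * 1000 / (4 * pi))^(1 / 3)
  a <- 170; b <- 110; zh <- 110
  # jitter the centroid within the feasible envelope
  xmax <- max(0, 0.92 * a - r); ymax <- max(0, 0.92 * b - r)
  zmax <- max(0, zh - r - 10)
  ctr <- c(stats::runif(1, -min(xmax, 90), min(xmax, 90)),
           stats::runif(1, -min(ymax, 35), min(ymax, 35)),
           stats::runif(1, -min(zmax, 40), min(zmax, 40)))
  phantom_spec(vol, par$rx, ptv_center_mm = ctr, spacing_mm = spacing_mm,
               label = label, difficulty = difficulty)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec: each case gets a sampled phantom, a beam
#' bouquet selected by the efficiency-index model, and a synthesized plan
#' dose.  The seed is recorded in each case's metadata.
#'
#' @param spec a [cohort_spec()].
#' @param beam_cfg a [beam_config()]; default caps the per-angle ray count
#'   for speed.
#' @param dose_cfg a [dose_synth_config()].
#' @return list of [rt_case()] objects.
#' @export
generate_cohort <- function(spec,
                            beam_cfg = beam_config(max_ptv_rays = 2000),
                            dose_cfg = dose_synth_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- difficulty_counts(spec$n, spec$mix)
  difficulties <- rep(names(counts), counts)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      ps <- sample_phantom_spec(difficulties[i], spec$spacing_mm,
                                label = sprintf("case%03d", i))
      cs <- make_thorax_phantom(ps)
      cs$meta$cohort_seed <- spec$seed
      if (spec$with_dose) {
        bouquet <- select_bouquet(cs, spec$n_beams, config = beam_cfg,
                                  mode = "clinical")
        cs$dose <- synthesize_plan_dose(cs, bouquet, dose_cfg)
        cs$meta$beam_angles <- bouquet$beams$gantry_angle
      }
      cs
    })
  })
}

# ---- linear-structure validation cohort for the DVH model ---------------

#' Synthetic cohort with known linear feature-to-DVH structure
#'
#' Generates thorax phantom geometries with varying PTV volume and position,
#' then *constructs* each OAR's dose so that its prescription-normalized DVH
#' is an exact affine function of two model features (measured PTV volume
#' and out-of-field fraction): a convex combination of three fixed monotone
#' anchor curves.  Voxel doses are painted by inverse-CDF assignment, so the
#' empirical DVH matches the target curve up to 1/(2 N_voxels).  With
#' `noise_sd = 0` the feature-to-DVH-PC map is exactly linear and the
#' prediction model should recover held-out DVHs almost perfectly; with
#' noise the curves are perturbed bin-wise (then re-monotonized) before
#' painting.
#'
#' Intended for model validation, not as realistic plans.
#'
#' @param n number of cases.
#' @param seed RNG seed.
#' @param noise_sd bin-wise Gaussian noise on the target curves, volume-%.
#' @param spacing_mm grid spacing (default 4 mm; tube OARs are widened so
#'   every OAR has enough voxels for accurate painting).
#' @return list of [rt_case()] objects with painted doses.
#' @export
simulate_kbp_cohort <- function(n, seed = 0L, noise_sd = 0, spacing_mm = 4) {
  grid <- seq(0, 1.2, by = 0.01)
  anchor <- function(mid, width) 100 * (1 - stats::pnorm(grid, mid, width))
  # per-OAR anchor curves (base, shifted-up, broadened)
  anchors <- list(
    lungs = list(anchor(0.40, 0.12), anchor(0.55, 0.12), anchor(0.40, 0.22)),
    heart = list(anchor(0.35, 0.10), anchor(0.50, 0.10), anchor(0.35, 0.20)),
    esophagus = list(anchor(0.45, 0.12), anchor(0.60, 0.12), anchor(0.45, 0.22)),
    cord = list(anchor(0.30, 0.10), anchor(0.45, 0.10), anchor(0.30, 0.18)))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      vol <- stats::runif(1, 150, 700)
      r <- (3 * vol * 1000 / (4 * pi))^(1 / 3)
      ctr <- c(stats::runif(1, -60, 60), stats::runif(1, -20, 20),
               stats::runif(1, -35, 35))
      rx <- stats::runif(1, 40, 62)
      ps <- phantom_spec(vol, rx, ptv_center_mm = ctr,
                         spacing_mm = spacing_mm,
                         esophagus_radius_mm = 8, cord_radius_mm = 6,
                         label = sprintf("kbp%03d", i))
      cs <- make_thorax_phantom(ps)
      g <- case_geometry(cs)
      zs <- grid_axis_mm(g, 3)
      ptv <- cs$structures[["ptv"]]
      # painted OARs must be pairwise disjoint and PTV-free, or overlapping
      # voxels would belong to two target curves at once
      for (nm in names(anchors))
        cs$structures[[nm]] <- volume_mask(
          g, cs$structures[[nm]]$inside & !ptv$inside)
      cs$structures[["heart"]] <- volume_mask(
        g, cs$structures[["heart"]]$inside &
          !cs$structures[["esophagus"]]$inside &
          !cs$structures[["cord"]]$inside)
      ptv_cc <- mask_volume_cc(ptv)
      ptv_z <- apply(ptv$inside, 3, any)
      zr <- range(zs[ptv_z]) + c(-20, 20)
      in_band <- zs >= zr[1] & zs <= zr[2]
      dose_vals <- array(0, dim = g$dims)
      dose_vals[ptv$inside] <- rx
      for (nm in names(anchors)) {
        oar <- cs$structures[[nm]]
        sel <- oar$inside
        nvox <- sum(sel)
        if (nvox == 0L) next
        n_out <- sum(oar$inside[, , !in_band, drop = FALSE])
        oof <- n_out / sum(oar$inside)
        a1 <- 0.05 + 0.5 * (ptv_cc - 100) / 700     # affine in a model feature
        a2 <- 0.05 + 0.35 * oof                     # affine in a model feature
        cv <- (1 - a1 - a2) * anchors[[nm]][[1]] +
          a1 * anchors[[nm]][[2]] + a2 * anchors[[nm]][[3]]
        if (noise_sd > 0) {
          cv <- cv + stats::rnorm(length(cv), sd = noise_sd)
          cv <- pmin(pmax(cv, 0), 100)
          cv <- -stats::isoreg(seq_along(cv), -cv)$yf
          cv[1] <- 100
        }
        # inverse-CDF painting: voxel i gets the dose where the cumulative
        # curve crosses (i - 0.5)/n; a vanishing ramp breaks plateau ties
        cvs <- cv + seq(length(cv), 1) * 1e-9
        q <- (seq_len(nvox) - 0.5) / nvox * 100
        doses <- stats::approx(x = rev(cvs), y = rev(grid), xout = q,
                               ties = "ordered", rule = 2)$y * rx
        dose_vals[sel] <- doses
      }
      cs$dose <- dose_grid(g, dose_vals)
      cs$meta$cohort_seed <- seed
      cs
    })
  })
}
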