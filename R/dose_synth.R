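# Simplified plan-dose synthesizer: divergent beams with exponential
# attenuation in a two-density body, a BEV+margin aperture, Gaussian
# penumbra blur and PTV-D95 normalization.  Stands in for a treatment
# planning system's fluence optimization; it is geometrically faithful but
# makes no claim of dosimetric accuracy.

#' Dose-synthesis configuration
#'
#' @param mu effective linear attenuation per mm water-equivalent depth.
#' @param step_mm ray-marching step.
#' @param sad source-axis distance, mm.
#' @param aperture_margin_mm margin added around the PTV beam's-eye view.
#' @param penumbra_sigma_mm Gaussian penumbra blur (0 disables).
#' @param lung_density relative lung density.
#' @param normalize rescale so PTV D95% equals the prescription.
#' @param bin_width_gy DVH bin width used for the D95 normalization.
#' @return named list.
#' @export
dose_synth_config <- function(mu = 0.005, step_mm = 1, sad = 1000,
                              aperture_margin_mm = 5, penumbra_sigma_mm = 3,
                              lung_density = 0.25, normalize = TRUE,
                              bin_width_gy = 0.05) {
  as.list(environment())
}

# separable Gaussian blur along one array dimension via a banded matrix
#' @keywords internal
.blur_axis <- function(arr, axis, sigma_vox) {
  n <- dim(arr)[axis]
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- B[cbind(i[ok], j[ok])] + k[o + r + 1]
  }
  # renormalize rows (edge truncation)
  B <- B / rowSums(B)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  out <- B %*% m
  a2 <- array(out, dim = d[perm])
  aperm(a2, order(perm))
}

#' @keywords internal
gaussian_blur3d <- function(arr, sigma_mm, spacing) {
  for (ax in 1:3) {
    s <- sigma_mm / spacing[ax]
    if (s > 1e-6) arr <- .blur_axis(arr, ax, s)
  }
  arr
}

#' Synthesize a plan dose for a beam bouquet
#'
#' Per beam: a divergent field from a virtual source at `sad` from the
#' isocenter (the PTV centroid), collimated to the PTV beam's-eye view plus
#' a margin, with voxel dose proportional to the beam weight times
#' `exp(-mu * WED)` (water-equivalent depth from body entry, two-density
#' model).  Beam doses are summed, blurred by a Gaussian penumbra, zeroed
#' outside the body, and finally scaled so the PTV D95% equals the
#' prescription.
#'
#' @param case an [rt_case()] with body and PTV.
#' @param bouquet a `beam_bouquet` (non-empty).
#' @param config a [dose_synth_config()].
#' @return A [dose_grid()] on the case geometry.
#' @export
synthesize_plan_dose <- function(case, bouquet, config = dose_synth_config()) {
  stopifnot(inherits(case, "rt_case"), inherits(bouquet, "beam_bouquet"))
  if (nrow(bouquet$beams) == 0L) stop("empty beam bouquet")
  g <- case_geometry(case)
  body <- case$structures[["body"]]
  ptv <- case$structures[["ptv"]]
  dens <- case_density(case, config$lung_density)
  iso <- mask_centroid_mm(ptv)
  ptv_idx <- which(ptv$inside, arr.ind = TRUE)
  ptv_pts <- sweep(sweep(ptv_idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  body_lin <- which(body$inside)
  body_idx <- arrayInd(body_lin, g$dims)
  body_pts <- sweep(sweep(body_idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  total <- array(0, dim = g$dims)
  ap_h <- min(g$spacing[1:2])              # aperture grid spacing
  for (bi in seq_len(nrow(bouquet$beams))) {
    ang <- bouquet$beams$gantry_angle[bi]
    w <- bouquet$beams$weight[bi]
    src <- beam_source_position(ang, iso, config$sad)
    axis <- (iso - src) / config$sad       # unit beam direction
    uhat <- c(-axis[2], axis[1], 0)        # in-plane transverse
    # divergent projection of points onto the isocenter plane
    proj <- function(pts) {
      rel <- sweep(pts, 2, iso)
      wd <- rel %*% axis                   # along-beam offset from iso
      mag <- config$sad / (config$sad + as.numeric(wd))
      cbind(u = as.numeric(rel %*% uhat) * mag,
            v = (rel[, 3]) * mag)
    }
    pp <- proj(ptv_pts)
    margin <- config$aperture_margin_mm
    # aperture cells anchored at the beam axis (u = v = 0) so mirrored
    # geometries bin to mirrored cells
    ci <- round(pp[, 1] / ap_h); cj <- round(pp[, 2] / ap_h)
    pad <- ceiling(margin / ap_h) + 2L
    iu0 <- min(ci) - pad; iv0 <- min(cj) - pad
    nu <- as.integer(max(ci) - iu0 + pad + 1L)
    nv <- as.integer(max(cj) - iv0 + pad + 1L)
    ap <- matrix(FALSE, nu, nv)
    ap[cbind(ci - iu0 + 1L, cj - iv0 + 1L)] <- TRUE
    # dilate the BEV by the margin (2D distance transform on the u-v grid)
    dm <- .edt_cpp(as.vector(ap), c(nu, nv, 1L), c(ap_h, ap_h, 1))
    ap <- matrix(dm <= margin + 1e-9, nu, nv)
    bp <- proj(body_pts)
    ju <- round(bp[, 1] / ap_h) - iu0 + 1L
    jv <- round(bp[, 2] / ap_h) - iv0 + 1L
    inside_ap <- ju >= 1 & ju <= nu & jv >= 1 & jv <= nv
    inside_ap[inside_ap] <- ap[cbind(ju[inside_ap], jv[inside_ap])]
    if (!any(inside_ap))
      stop("empty aperture for beam at ", ang, " degrees")
    pts_in <- body_pts[inside_ap, , drop = FALSE]
    wed <- .wed_cpp(as.vector(dens), as.vector(body$inside), pts_in, src,
                    g$origin, g$spacing, g$dims, config$step_mm)
    beam_dose <- numeric(length(body_lin))
    beam_dose[inside_ap] <- exp(-config$mu * wed)
    contrib <- array(0, dim = g$dims)
    contrib[body_lin] <- w * beam_dose
    total <- total + contrib
  }
  if (config$penumbra_sigma_mm > 0)
    total <- gaussian_blur3d(total, config$penumbra_sigma_mm, g$spacing)
  total[!body$inside] <- 0
  total[total < 0] <- 0
  dose <- dose_grid(g, total)
  if (config$normalize) {
    dvh <- compute_dvh(dose, ptv, bin_width_gy = config$bin_width_gy,
                       structure = "ptv")
    d95 <- dose_at_volume(dvh, 95)
    if (d95 <= 0) stop("degenerate plan: PTV D95% is zero, cannot normalize")
    dose <- dose_grid(g, total * (case$prescription_gy / d95))
  }
  dose
}
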