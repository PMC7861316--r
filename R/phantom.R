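# Parametric thorax phantom: schematic ellipsoid/tube anatomy whose
# statistical structure (volumes, distances, overlaps) spans the easy-to-hard
# lung/mediastinum case spectrum.  Not an anatomical model.

#' Specification of a synthetic thorax phantom
#'
#' @param ptv_volume_cc requested PTV volume, cc (`> 0`); the PTV radius is
#'   solved from this volume and shape.
#' @param prescription_gy prescription, Gy.
#' @param ptv_center_mm PTV centroid, mm, relative to the body axis center.
#' @param ptv_shape `"sphere"` or `"ellipsoid"`.
#' @param ptv_axis_ratios length-3 relative axis ratios for the ellipsoid
#'   shape (scaled to the requested volume).
#' @param spacing_mm isotropic grid spacing, mm (default 2.5).
#' @param body_semi_axes_mm in-plane semi-axes of the elliptic-cylinder
#'   body, mm.
#' @param z_extent_mm superior-inferior phantom length, mm.
#' @param lung_semi_axes_mm,lung_offset_x_mm lung ellipsoid geometry (left
#'   and right lungs mirrored at `+/- lung_offset_x_mm`).
#' @param heart_center_mm,heart_semi_axes_mm heart ellipsoid geometry.
#' @param esophagus_radius_mm,esophagus_center_mm esophagus tube.
#' @param cord_radius_mm,cord_center_mm spinal cord tube (posterior).
#' @param gtv_margin_mm PTV-to-GTV erosion margin (default 5 mm).
#' @param label,difficulty case metadata.
#' @return An object of class `phantom_spec` (named list).
#' @export
phantom_spec <- function(ptv_volume_cc, prescription_gy,
                         ptv_center_mm = c(30, 0, 0),
                         ptv_shape = c("sphere", "ellipsoid"),
                         ptv_axis_ratios = c(1, 1, 1),
                         spacing_mm = 2.5,
                         body_semi_axes_mm = c(170, 110),
                         z_extent_mm = 220,
                         lung_semi_axes_mm = c(58, 80, 95),
                         lung_offset_x_mm = 85,
                         heart_center_mm = c(15, 15, -40),
                         heart_semi_axes_mm = c(45, 40, 50),
                         esophagus_radius_mm = 5,
                         esophagus_center_mm = c(0, 30),
                         cord_radius_mm = 4,
                         cord_center_mm = c(0, 72),
                         gtv_margin_mm = 5,
                         label = "phantom", difficulty = NULL) {
  ptv_shape <- match.arg(ptv_shape)
  stopifnot(ptv_volume_cc > 0, prescription_gy > 0, spacing_mm > 0,
            all(ptv_axis_ratios > 0))
  spec <- as.list(environment())
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec '%s': PTV %.4g cc %s at (%g, %g, %g) mm, Rx %g Gy, %g mm grid>\n",
              x$label, x$ptv_volume_cc, x$ptv_shape, x$ptv_center_mm[1],
              x$ptv_center_mm[2], x$ptv_center_mm[3], x$prescription_gy,
              x$spacing_mm))
  invisible(x)
}

#' Build a voxelized thorax phantom case
#'
#' Voxelizes body, lungs, heart, esophagus, cord, PTV, the GTV (PTV eroded
#' by the spec's margin) and cord+3mm (cord dilated 3 mm via the distance
#' transform) onto one isotropic grid.  The PTV radius is solved
#' analytically from the requested volume; lungs exclude the PTV.
#'
#' @param spec a [phantom_spec()].
#' @return An [rt_case()] (without dose).
#' @export
make_thorax_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$spacing_mm
  nx <- ceiling((2 * spec$body_semi_axes_mm[1] + 20) / h)
  ny <- ceiling((2 * spec$body_semi_axes_mm[2] + 20) / h)
  nz <- ceiling(spec$z_extent_mm / h)
  dims <- c(nx, ny, nz)
  origin <- -(dims - 1) / 2 * h              # grid centered at (0,0,0)
  g <- grid_geometry(origin, c(h, h, h), dims)

  ctr <- spec$ptv_center_mm
  # solve the shape's radius from the requested volume
  r0 <- (3 * spec$ptv_volume_cc * 1000 / (4 * pi * prod(spec$ptv_axis_ratios)))^(1 / 3)
  semi <- r0 * spec$ptv_axis_ratios
  # feasibility: PTV must fit inside the body ellipse (in-plane) and z extent
  a <- spec$body_semi_axes_mm[1]; b <- spec$body_semi_axes_mm[2]
  edge <- (ctr[1] / a)^2 + (ctr[2] / b)^2
  if (edge >= 1)
    stop("infeasible phantom: PTV centroid lies outside the body")
  if ((abs(ctr[1]) + semi[1]) / a > 1 || (abs(ctr[2]) + semi[2]) / b > 1 ||
      abs(ctr[3]) + semi[3] > spec$z_extent_mm / 2)
    stop("infeasible phantom: PTV of ", spec$ptv_volume_cc,
         " cc does not fit inside the body at this centroid")

  xs <- grid_axis_mm(g, 1); ys <- grid_axis_mm(g, 2)
  body2d <- outer((xs / a)^2, (ys / b)^2, "+") <= 1
  body <- volume_mask(g, array(body2d, dim = dims))

  ptv <- voxelize_ellipsoid(g, ctr, semi)
  ptv <- volume_mask(g, ptv$inside & body$inside)
  gtv <- erode_mask(ptv, spec$gtv_margin_mm)

  lungL <- voxelize_ellipsoid(g, c(spec$lung_offset_x_mm, 0, 0),
                              spec$lung_semi_axes_mm)
  lungR <- voxelize_ellipsoid(g, c(-spec$lung_offset_x_mm, 0, 0),
                              spec$lung_semi_axes_mm)
  lungs <- volume_mask(g, (lungL$inside | lungR$inside) & body$inside &
                            !ptv$inside)
  heart <- voxelize_ellipsoid(g, spec$heart_center_mm, spec$heart_semi_axes_mm)
  heart <- volume_mask(g, heart$inside & body$inside & !lungs$inside)
  eso <- voxelize_tube(g, function(z) spec$esophagus_center_mm,
                       spec$esophagus_radius_mm)
  eso <- volume_mask(g, eso$inside & body$inside)
  cord <- voxelize_tube(g, function(z) spec$cord_center_mm,
                        spec$cord_radius_mm)
  cord <- volume_mask(g, cord$inside & body$inside)
  cord3 <- dilate_mask(cord, 3)
  cord3 <- volume_mask(g, cord3$inside & body$inside)

  rt_case(list(body = body, ptv = ptv, gtv = gtv, lungs = lungs,
               heart = heart, esophagus = eso, cord = cord,
               `cord+3mm` = cord3),
          prescription_gy = spec$prescription_gy,
          label = spec$label, difficulty = spec$difficulty,
          meta = list(ptv_volume_requested_cc = spec$ptv_volume_cc,
                      spacing_mm = spec$spacing_mm))
}

#' Reference case presets
#'
#' Six presets mirroring the training-program case spectrum: one
#' intermediate-to-hard benchmark case (762.8 cc PTV, 62 Gy), two easy
#' cases (113.8 cc, 40 Gy each), one intermediate case (453.0 cc, 60 Gy)
#' and two hard cases (845.7 cc, 60 Gy each).  The two members of the easy
#' and hard pairs share the pair-average volume and differ in PTV location
#' and shape.
#'
#' @param spacing_mm grid spacing for all presets (default 2.5 mm).
#' @return named list of six [phantom_spec()] objects (`benchmark`,
#'   `easy1`, `easy2`, `intermediate`, `hard1`, `hard2`).
#' @export
reference_case_specs <- function(spacing_mm = 2.5) {
  list(
    benchmark = phantom_spec(762.8, 62, ptv_center_mm = c(35, 5, 0),
                             spacing_mm = spacing_mm, label = "benchmark",
                             difficulty = "intermediate-to-hard"),
    easy1 = phantom_spec(113.8, 40, ptv_center_mm = c(80, -20, 25),
                         spacing_mm = spacing_mm, label = "easy1",
                         difficulty = "easy"),
    easy2 = phantom_spec(113.8, 40, ptv_center_mm = c(-75, -15, -20),
                         spacing_mm = spacing_mm, label = "easy2",
                         difficulty = "easy"),
    intermediate = phantom_spec(453.0, 60, ptv_center_mm = c(55, 0, 10),
                                ptv_shape = "ellipsoid",
                                ptv_axis_ratios = c(1, 0.85, 1.15),
                                spacing_mm = spacing_mm,
                                label = "intermediate",
                                difficulty = "intermediate"),
    hard1 = phantom_spec(845.7, 60, ptv_center_mm = c(25, 10, 0),
                         ptv_shape = "ellipsoid",
                         ptv_axis_ratios = c(1.1, 0.9, 1.05),
                         spacing_mm = spacing_mm, label = "hard1",
                         difficulty = "hard"),
    hard2 = phantom_spec(845.7, 60, ptv_center_mm = c(-20, 15, 5),
                         spacing_mm = spacing_mm, label = "hard2",
                         difficulty = "hard"))
}
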