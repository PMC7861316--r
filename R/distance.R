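#' Euclidean distance map to a mask
#'
#' Exact Euclidean distance (mm) from every voxel center to the nearest
#' voxel center belonging to `mask`, honouring anisotropic spacing.
#'
#' @param mask a non-empty [volume_mask()].
#' @return 3D numeric array of distances in mm (0 inside the mask).
#' @export
mask_distance_mm <- function(mask) {
  stopifnot(inherits(mask, "volume_mask"))
  if (!any(mask$inside)) stop("distance map of an empty mask is undefined")
  g <- mask$geometry
  d <- .edt_cpp(as.vector(mask$inside), g$dims, g$spacing)
  array(d, dim = g$dims)
}

#' Morphological dilation / erosion by a Euclidean radius
#'
#' `dilate_mask` adds every voxel within `radius_mm` of the mask;
#' `erode_mask` keeps voxels at least `radius_mm` from the complement.
#' Both use the exact Euclidean distance transform.
#'
#' @param mask a [volume_mask()].
#' @param radius_mm radius in mm (`>= 0`).
#' @return A [volume_mask()].
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(radius_mm >= 0)
  if (!any(mask$inside)) return(mask)
  d <- mask_distance_mm(mask)
  volume_mask(mask$geometry, d <= radius_mm + 1e-9)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(radius_mm >= 0)
  g <- mask$geometry
  if (all(mask$inside))
    return(mask)  # no complement: erosion undefined at boundary, keep as-is
  comp <- volume_mask(g, !mask$inside)
  d <- mask_distance_mm(comp)
  volume_mask(g, mask$inside & d >= radius_mm - 1e-9)
}

#' Signed distance to the PTV surface
#'
#' Euclidean distance (mm) of every voxel center to the nearest PTV
#' *surface* voxel (a PTV voxel with at least one 6-neighbour outside),
#' negated inside the PTV.
#'
#' @param ptv a non-empty PTV [volume_mask()].
#' @return 3D numeric array of signed distances in mm.
#' @export
signed_distance_to_surface <- function(ptv) {
  stopifnot(inherits(ptv, "volume_mask"))
  m <- ptv$inside
  if (!any(m)) stop("empty PTV: no surface")
  dm <- dim(m)
  pad <- function(shift_axis, dir) {
    out <- array(FALSE, dm)
    if (shift_axis == 1) {
      if (dir > 0) out[-dm[1], , ] <- m[-1, , ] else out[-1, , ] <- m[-dm[1], , ]
    } else if (shift_axis == 2) {
      if (dir > 0) out[, -dm[2], ] <- m[, -1, ] else out[, -1, ] <- m[, -dm[2], ]
    } else {
      if (dir > 0) out[, , -dm[3]] <- m[, , -1] else out[, , -1] <- m[, , -dm[3]]
    }
    out
  }
  # neighbour count; grid border counts as outside
  all_in <- pad(1, 1) & pad(1, -1) & pad(2, 1) & pad(2, -1) & pad(3, 1) & pad(3, -1)
  surf <- m & !all_in
  d <- mask_distance_mm(volume_mask(ptv$geometry, surf))
  d[m] <- -d[m]
  d
}
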