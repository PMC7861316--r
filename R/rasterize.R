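#' Rasterize planar contours onto a voxel grid
#'
#' Converts per-slice closed polygons (axial contours in mm, as produced by
#' an RTSTRUCT) into a binary voxel mask.  A voxel is included when at least
#' half of its in-plane subcenters fall inside the polygons of its slice
#' under the even-odd rule (so overlapping contours cut holes).  With
#' `supersample = 1` this reduces to the plain voxel-center test.
#'
#' @param contours list of contours; each a list with `z` (slice position,
#'   mm) and `xy` (N x 2 matrix of polygon vertices in mm, implicitly
#'   closed).  Degenerate polygons (fewer than 3 vertices) are an error;
#'   an empty contour list yields an empty mask.
#' @param geometry target [grid_geometry()].
#' @param supersample in-plane subdivision per axis (default 4, i.e. 4x4
#'   subcenters per voxel).
#' @return A [volume_mask()].
#' @export
rasterize_contours <- function(contours, geometry, supersample = 4L) {
  stopifnot(inherits(geometry, "grid_geometry"), supersample >= 1L)
  inside <- array(FALSE, dim = geometry$dims)
  if (length(contours) == 0L)
    return(volume_mask(geometry, inside))
  zs <- grid_axis_mm(geometry, 3)
  slice_of <- function(z) {
    k <- which.min(abs(zs - z))
    if (abs(zs[k] - z) > geometry$spacing[3] / 2 + 1e-9)
      stop(sprintf("contour plane z = %.3f mm matches no grid slice (nearest %.3f mm)",
                   z, zs[k]))
    k
  }
  by_slice <- list()
  for (ct in contours) {
    xy <- ct$xy
    if (is.null(dim(xy)) || nrow(xy) < 3L)
      stop("open or degenerate contour: polygons need at least 3 vertices")
    k <- slice_of(ct$z)
    key <- as.character(k)
    by_slice[[key]] <- c(by_slice[[key]], list(xy))
  }
  xs <- grid_axis_mm(geometry, 1)
  ys <- grid_axis_mm(geometry, 2)
  ss <- as.integer(supersample)
  # subcenter offsets within a voxel, per axis
  offs <- ((seq_len(ss) - 0.5) / ss - 0.5)
  for (key in names(by_slice)) {
    k <- as.integer(key)
    polys <- by_slice[[key]]
    # candidate voxels: bounding box of all polygons on this slice
    bx <- range(vapply(polys, function(p) range(p[, 1]), numeric(2)))
    by <- range(vapply(polys, function(p) range(p[, 2]), numeric(2)))
    ix <- which(xs >= bx[1] - geometry$spacing[1] & xs <= bx[2] + geometry$spacing[1])
    iy <- which(ys >= by[1] - geometry$spacing[2] & ys <= by[2] + geometry$spacing[2])
    if (!length(ix) || !length(iy)) next
    # all subcenter points for the candidate voxels
    cx <- as.vector(outer(xs[ix], offs * geometry$spacing[1], "+"))
    cy <- as.vector(outer(ys[iy], offs * geometry$spacing[2], "+"))
    px <- rep(cx, times = length(cy))
    py <- rep(cy, each = length(cx))
    crossings <- integer(length(px))
    for (p in polys)
      crossings <- crossings + .pip_crossings(px, py, p)
    inside_pt <- crossings %% 2L == 1L
    # fraction of subcenters inside, per voxel
    m <- array(inside_pt, dim = c(length(ix), ss, length(iy), ss))
    frac <- apply(m, c(1, 3), mean)
    sel <- which(frac >= 0.5, arr.ind = TRUE)
    if (nrow(sel))
      inside[cbind(ix[sel[, 1]], iy[sel[, 2]], k)] <- TRUE
  }
  volume_mask(geometry, inside)
}

# even-odd crossing counts of points against one polygon (vectorized over points)
#' @keywords internal
.pip_crossings <- function(px, py, poly) {
  n <- nrow(poly)
  cross <- integer(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    hits <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    cross <- cross + as.integer(hits)
    j <- i
  }
  cross
}

#' Voxelize an analytic ellipsoid
#'
#' Includes a voxel when at least half of its subcenters (supersampled per
#' axis) fall inside the ellipsoid.  Used by the phantom generator.
#'
#' @param geometry a [grid_geometry()].
#' @param center ellipsoid center, mm (length 3).
#' @param semi_axes semi-axis lengths, mm (length 3).
#' @param supersample subdivision per axis (default 3, i.e. 27 subcenters;
#'   odd values include the voxel center and give markedly better volume
#'   accuracy).
#' @return A [volume_mask()].
#' @export
voxelize_ellipsoid <- function(geometry, center, semi_axes, supersample = 3L) {
  stopifnot(inherits(geometry, "grid_geometry"), all(semi_axes > 0))
  ss <- as.integer(supersample)
  offs <- ((seq_len(ss) - 0.5) / ss - 0.5)
  frac <- array(0, dim = geometry$dims)
  xs <- grid_axis_mm(geometry, 1); ys <- grid_axis_mm(geometry, 2)
  zs <- grid_axis_mm(geometry, 3)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    u <- (xs + ox * geometry$spacing[1] - center[1]) / semi_axes[1]
    v <- (ys + oy * geometry$spacing[2] - center[2]) / semi_axes[2]
    w <- (zs + oz * geometry$spacing[3] - center[3]) / semi_axes[3]
    q <- outer(outer(u^2, v^2, "+"), w^2, "+")
    frac <- frac + (q <= 1)
  }
  volume_mask(geometry, frac >= ss^3 / 2)
}

#' Voxelize a vertical tube (e.g. cord, esophagus)
#'
#' A circular tube of radius `radius_mm` whose in-plane center follows
#' `path(z)` over the slices in `z_range`.
#'
#' @param geometry a [grid_geometry()].
#' @param path function of z (mm) returning the in-plane center `c(x, y)`.
#' @param radius_mm tube radius, mm.
#' @param z_range length-2 z extent, mm (default: whole grid).
#' @return A [volume_mask()].
#' @export
voxelize_tube <- function(geometry, path, radius_mm, z_range = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"), radius_mm > 0)
  xs <- grid_axis_mm(geometry, 1); ys <- grid_axis_mm(geometry, 2)
  zs <- grid_axis_mm(geometry, 3)
  if (is.null(z_range)) z_range <- range(zs)
  inside <- array(FALSE, dim = geometry$dims)
  for (k in seq_along(zs)) {
    if (zs[k] < z_range[1] || zs[k] > z_range[2]) next
    ctr <- path(zs[k])
    d2 <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+")
    inside[, , k] <- d2 <= radius_mm^2
  }
  volume_mask(geometry, inside)
}
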