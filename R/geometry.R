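#' Grid geometry for dose grids and structure masks
#'
#' An axis-aligned voxel grid in DICOM patient (LPS) coordinates.  `origin`
#' is the physical position (mm) of the *center* of voxel `(1,1,1)`,
#' `spacing` the per-axis voxel size (mm, x/y/z) and `dims` the voxel counts.
#' Voxel indices are 1-based in R; voxel extents are half-open.
#'
#' @param origin numeric length-3, mm (center of the first voxel).
#' @param spacing numeric length-3, mm; all `> 0`.
#' @param dims integer length-3 voxel counts; all `>= 1`.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(0, 0, 0), c(2.5, 2.5, 2.5), c(10, 10, 10))
#' voxel_volume_cc(g) * prod(g$dims)  # total grid volume in cc
#' @export
grid_geometry <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be positive and finite")
  if (any(is.na(dims)) || any(dims < 1L)) stop("grid dims must all be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_geometry")
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("<grid_geometry %dx%dx%d @ %.3gx%.3gx%.3g mm, origin (%.4g, %.4g, %.4g)>",
          x$dims[1], x$dims[2], x$dims[3],
          x$spacing[1], x$spacing[2], x$spacing[3],
          x$origin[1], x$origin[2], x$origin[3])
}

#' @export
print.grid_geometry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Volume of a single voxel in cc
#' @param geometry a [grid_geometry()].
#' @return numeric scalar, cubic centimeters.
#' @export
voxel_volume_cc <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  prod(geometry$spacing) / 1000
}

#' Physical coordinates of voxel centers along one axis
#' @param geometry a [grid_geometry()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel-center positions in mm.
#' @export
grid_axis_mm <- function(geometry, axis) {
  stopifnot(inherits(geometry, "grid_geometry"), axis %in% 1:3)
  geometry$origin[axis] + (seq_len(geometry$dims[axis]) - 1) * geometry$spacing[axis]
}

#' @keywords internal
same_geometry <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

#' A 3D dose field on a grid
#'
#' @param geometry a [grid_geometry()].
#' @param values 3D numeric array of doses in Gy, dimensions equal to
#'   `geometry$dims`; all values finite and `>= 0`.
#' @return An object of class `dose_grid` with fields `geometry`, `values`.
#' @export
dose_grid <- function(geometry, values) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geometry$dims)))
    stop("dose array dimensions do not match geometry dims")
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("dose values must be finite")
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(geometry = geometry, values = values), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid max %.3g Gy> %s\n", max(x$values), format(x$geometry)))
  invisible(x)
}

#' A binary structure mask on a grid
#'
#' @param geometry a [grid_geometry()].
#' @param inside 3D logical array matching `geometry$dims`.
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(geometry, inside) {
  stopifnot(inherits(geometry, "grid_geometry"))
  inside <- as.array(inside)
  if (!identical(dim(inside), as.integer(geometry$dims)))
    stop("mask array dimensions do not match geometry dims")
  storage.mode(inside) <- "logical"
  if (any(is.na(inside))) stop("mask must not contain NA")
  structure(list(geometry = geometry, inside = inside), class = "volume_mask")
}

#' Structure volume in cc (voxel count times voxel volume)
#' @param mask a [volume_mask()].
#' @return numeric scalar, cc.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "volume_mask"))
  sum(mask$inside) * voxel_volume_cc(mask$geometry)
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask %.4g cc> %s\n", mask_volume_cc(x), format(x$geometry)))
  invisible(x)
}

#' Resample a dose grid onto a target geometry
#'
#' Nearest-neighbour or trilinear interpolation of the dose field at the
#' target voxel centers.  Target voxels outside the source extent are filled
#' with 0 Gy.  Trilinear interpolation reproduces affine dose fields exactly
#' within the source extent.
#'
#' @param dose a [dose_grid()].
#' @param target a [grid_geometry()]; must overlap the source extent.
#' @param mode `"trilinear"` (default) or `"nearest"`.
#' @return A [dose_grid()] on `target`.
#' @export
resample_dose <- function(dose, target, mode = c("trilinear", "nearest")) {
  stopifnot(inherits(dose, "dose_grid"), inherits(target, "grid_geometry"))
  mode <- match.arg(mode)
  src <- dose$geometry
  # fractional (0-based) source indices of target voxel centers, per axis
  fx <- (grid_axis_mm(target, 1) - src$origin[1]) / src$spacing[1]
  fy <- (grid_axis_mm(target, 2) - src$origin[2]) / src$spacing[2]
  fz <- (grid_axis_mm(target, 3) - src$origin[3]) / src$spacing[3]
  inx <- fx >= -0.5 & fx <= src$dims[1] - 0.5
  iny <- fy >= -0.5 & fy <= src$dims[2] - 0.5
  inz <- fz >= -0.5 & fz <= src$dims[3] - 0.5
  if (!any(inx) || !any(iny) || !any(inz))
    stop("target geometry does not overlap the dose extent")
  nd <- target$dims
  out <- array(0, dim = nd)
  if (mode == "nearest") {
    ix <- pmin(pmax(round(fx), 0), src$dims[1] - 1)
    iy <- pmin(pmax(round(fy), 0), src$dims[2] - 1)
    iz <- pmin(pmax(round(fz), 0), src$dims[3] - 1)
    vals <- dose$values[cbind(
      rep(ix + 1, times = nd[2] * nd[3]),
      rep(rep(iy + 1, each = nd[1]), times = nd[3]),
      rep(iz + 1, each = nd[1] * nd[2]))]
    out[] <- vals
    keep <- outer(outer(inx, iny, "&"), inz, "&")
    out[!keep] <- 0
  } else {
    # trilinear: clamp corner indices to the grid; weights from fractional part
    tri <- function(f, n) {
      i0 <- floor(f); w <- f - i0
      i0c <- pmin(pmax(i0, 0), n - 1)
      i1c <- pmin(pmax(i0 + 1, 0), n - 1)
      list(i0 = i0c + 1, i1 = i1c + 1, w = w)
    }
    tx <- tri(fx, src$dims[1]); ty <- tri(fy, src$dims[2]); tz <- tri(fz, src$dims[3])
    n1 <- nd[1]; n2 <- nd[2]; n3 <- nd[3]
    rep_x <- function(v) rep(v, times = n2 * n3)
    rep_y <- function(v) rep(rep(v, each = n1), times = n3)
    rep_z <- function(v) rep(v, each = n1 * n2)
    wx <- rep_x(tx$w); wy <- rep_y(ty$w); wz <- rep_z(tz$w)
    acc <- numeric(n1 * n2 * n3)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ii <- rep_x(if (cx == 0) tx$i0 else tx$i1)
      jj <- rep_y(if (cy == 0) ty$i0 else ty$i1)
      kk <- rep_z(if (cz == 0) tz$i0 else tz$i1)
      w <- (if (cx == 0) 1 - wx else wx) *
           (if (cy == 0) 1 - wy else wy) *
           (if (cz == 0) 1 - wz else wz)
      acc <- acc + w * dose$values[cbind(ii, jj, kk)]
    }
    out[] <- acc
    keep <- outer(outer(inx, iny, "&"), inz, "&")
    out[!keep] <- 0
  }
  out[out < 0] <- 0
  dose_grid(target, out)
}
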