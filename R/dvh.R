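#' Cumulative dose-volume histogram
#'
#' Exact full-voxel cumulative DVH of the dose values inside a mask: for
#' every bin edge `e`, the percent of structure volume receiving at least
#' `e` Gy.  The curve starts at exactly 100% at 0 Gy, is monotone
#' non-increasing, and reaches 0 at a bin edge above the maximum dose.
#' Doses within a relative tolerance of `1e-9` of a bin edge count as on
#' the edge, so edge-aligned queries are exact.
#'
#' @param dose a [dose_grid()].
#' @param mask a [volume_mask()] on the same geometry; must be non-empty.
#' @param bin_width_gy histogram bin width in Gy (default 0.05).
#' @param structure optional structure name carried in the result.
#' @return An object of class `dvh_curve` with fields `bin_edges` (Gy),
#'   `cumulative_volume` (percent), `structure_volume_cc`, `structure`.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.05, structure = NA_character_) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "volume_mask"),
            bin_width_gy > 0)
  if (!same_geometry(dose$geometry, mask$geometry))
    stop("dose and mask geometries differ")
  d <- dose$values[mask$inside]
  if (length(d) == 0L)
    stop("empty mask for structure '", structure, "': cannot compute DVH")
  n <- length(d)
  # one empty bin beyond the max so the curve reaches 0
  nb <- floor(max(d) / bin_width_gy + 1e-9) + 2L
  edges <- (0:(nb + 1L)) * bin_width_gy
  # bin index with edge tolerance: dose within 1e-9*bin of an edge counts as >= edge
  idx <- floor(d / bin_width_gy + 1e-9) + 1L
  counts <- tabulate(idx, nbins = nb + 1L)
  at_least <- rev(cumsum(rev(counts)))          # voxels with dose >= edges[i]
  cum <- 100 * c(at_least, 0) / n
  cum[1] <- 100
  structure(list(bin_edges = edges, cumulative_volume = cum,
                 structure_volume_cc = n * voxel_volume_cc(mask$geometry),
                 structure = structure, bin_width_gy = bin_width_gy),
            class = "dvh_curve")
}

#' @keywords internal
new_dvh_curve <- function(bin_edges, cumulative_volume, structure_volume_cc = NA_real_,
                          structure = NA_character_) {
  stopifnot(length(bin_edges) == length(cumulative_volume))
  structure(list(bin_edges = as.numeric(bin_edges),
                 cumulative_volume = as.numeric(cumulative_volume),
                 structure_volume_cc = structure_volume_cc,
                 structure = structure,
                 bin_width_gy = if (length(bin_edges) > 1) diff(bin_edges[1:2]) else NA_real_),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve%s, %d edges to %.4g Gy, volume %.4g cc>\n",
              if (is.na(x$structure)) "" else paste0(" ", x$structure),
              length(x$bin_edges), max(x$bin_edges), x$structure_volume_cc))
  invisible(x)
}

#' @export
as.data.frame.dvh_curve <- function(x, ...) {
  data.frame(dose_gy = x$bin_edges, volume_pct = x$cumulative_volume)
}

#' Dose received by at least a given percent of the structure (Dx%)
#'
#' Returns the largest dose `d` such that the cumulative volume at `d` is at
#' least `volume_percent`, with linear interpolation between bin edges.
#'
#' @param dvh a `dvh_curve`.
#' @param volume_percent in `(0, 100]`; e.g. 98 for D98%.
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_percent) {
  stopifnot(inherits(dvh, "dvh_curve"),
            volume_percent > 0, volume_percent <= 100)
  e <- dvh$bin_edges; c_ <- dvh$cumulative_volume
  i <- max(which(c_ >= volume_percent))       # exists: c_[1] = 100
  if (i == length(e)) return(e[i])
  if (c_[i] <= c_[i + 1]) return(e[i])        # flat (only possible at equal values)
  e[i] + (e[i + 1] - e[i]) * (c_[i] - volume_percent) / (c_[i] - c_[i + 1])
}

#' Percent of the structure receiving at least a given dose (VxGy)
#'
#' @param dvh a `dvh_curve`.
#' @param dose_gy dose level in Gy (`>= 0`).
#' @return percent of structure volume, in `[0, 100]`.
#' @export
volume_at_dose <- function(dvh, dose_gy) {
  stopifnot(inherits(dvh, "dvh_curve"), dose_gy >= 0)
  e <- dvh$bin_edges; c_ <- dvh$cumulative_volume
  if (dose_gy >= e[length(e)]) return(c_[length(e)])
  stats::approx(e, c_, xout = dose_gy, rule = 2)$y
}

#' Voxelwise min / max / mean dose inside a mask
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [volume_mask()] on the same geometry.
#' @return named list `Dmin`, `Dmax`, `Dmean` in Gy.
#' @export
summary_stats <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "volume_mask"))
  if (!same_geometry(dose$geometry, mask$geometry))
    stop("dose and mask geometries differ")
  d <- dose$values[mask$inside]
  if (length(d) == 0L) stop("empty mask: cannot compute dose statistics")
  list(Dmin = min(d), Dmax = max(d), Dmean = mean(d))
}

#' Conformity index (isodose spill ratio)
#'
#' `CI = V(dose >= iso_fraction * prescription, within body) / V(ptv)`.
#' With the default `iso_fraction = 0.5` this is the R50-style "CI 50%"
#' spill metric: lower is better.
#'
#' @param dose a [dose_grid()].
#' @param ptv PTV [volume_mask()] (non-empty).
#' @param prescription_gy prescription in Gy (`> 0`).
#' @param iso_fraction isodose level as a fraction of prescription.
#' @param body optional body [volume_mask()]; when given, the isodose volume
#'   is restricted to the body.
#' @return ratio (dimensionless).
#' @export
conformity_index <- function(dose, ptv, prescription_gy, iso_fraction = 0.5,
                             body = NULL) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "volume_mask"),
            prescription_gy > 0, iso_fraction > 0)
  n_ptv <- sum(ptv$inside)
  if (n_ptv == 0L) stop("empty PTV: cannot compute conformity index")
  iso <- dose$values >= iso_fraction * prescription_gy
  if (!is.null(body)) iso <- iso & body$inside
  sum(iso) / n_ptv
}

#' Conformation number (Paddick conformity index)
#'
#' With `PIV` the volume receiving at least `iso_fraction * prescription` and
#' `TV` the PTV volume: `CN = overlap(PIV, TV)^2 / (TV * PIV)`, in `[0, 1]`
#' (1 = perfect conformity).  Returns 0 when the isodose volume is empty.
#'
#' @inheritParams conformity_index
#' @export
conformation_number <- function(dose, ptv, prescription_gy, iso_fraction = 0.95,
                                body = NULL) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "volume_mask"),
            prescription_gy > 0, iso_fraction > 0)
  tv <- sum(ptv$inside)
  if (tv == 0L) stop("empty PTV: cannot compute conformation number")
  iso <- dose$values >= iso_fraction * prescription_gy
  if (!is.null(body)) iso <- iso & body$inside
  piv <- sum(iso)
  if (piv == 0L) return(0)
  tvpiv <- as.numeric(sum(iso & ptv$inside))
  (tvpiv * tvpiv) / (as.numeric(tv) * as.numeric(piv))
}

#' Location of the global maximum dose
#'
#' Finds the hottest voxel (within the body mask when supplied, otherwise in
#' the whole grid) and reports whether it lies inside the PTV.  Ties are
#' broken by the lowest linear voxel index (column-major scan order).
#'
#' @param dose a [dose_grid()].
#' @param ptv PTV [volume_mask()].
#' @param body optional body [volume_mask()].
#' @return list with `inside_ptv` (logical), `position_mm` (length-3),
#'   `value_gy`.
#' @export
max_dose_location <- function(dose, ptv, body = NULL) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "volume_mask"))
  v <- dose$values
  if (!is.null(body)) {
    v <- v + 0          # copy
    v[!body$inside] <- -Inf
  }
  i <- which.max(v)     # first max in scan order
  g <- dose$geometry
  ijk <- arrayInd(i, g$dims)
  pos <- g$origin + (as.numeric(ijk) - 1) * g$spacing
  list(inside_ptv = as.logical(ptv$inside[i]),
       position_mm = pos, value_gy = dose$values[i])
}
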