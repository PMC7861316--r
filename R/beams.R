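# Coplanar beam ranking by an efficiency index, and greedy selection of a
# separated beam bouquet.

#' Beam-model configuration
#'
#' @param sad source-axis distance, mm.
#' @param mu effective linear attenuation, per mm of water-equivalent depth.
#' @param step_mm ray-marching step, mm.
#' @param lung_density relative density of lung tissue in the two-density
#'   model (body = 1).
#' @param angles candidate gantry angles, degrees (IEC: 0 = anterior,
#'   clockwise viewed from the patient's feet).
#' @param oar_weights named per-OAR penalty weights.
#' @param max_ptv_rays cap on the number of PTV target voxels per angle
#'   (deterministic stride subsample); `Inf` uses every PTV voxel.
#' @return named list of configuration values.
#' @export
beam_config <- function(sad = 1000, mu = 0.005, step_mm = 1,
                        lung_density = 0.25,
                        angles = seq(0, 355, by = 5),
                        oar_weights = c(cord = 1.0, esophagus = 0.4,
                                        heart = 0.5, lungs = 0.3),
                        max_ptv_rays = Inf) {
  list(sad = sad, mu = mu, step_mm = step_mm, lung_density = lung_density,
       angles = angles, oar_weights = oar_weights,
       max_ptv_rays = max_ptv_rays)
}

#' @keywords internal
case_density <- function(case, lung_density = 0.25) {
  body <- case$structures[["body"]]
  dens <- array(0, dim = body$geometry$dims)
  dens[body$inside] <- 1
  lungs <- case$structures[["lungs"]]
  if (!is.null(lungs)) dens[lungs$inside & body$inside] <- lung_density
  ptv <- case$structures[["ptv"]]
  dens[ptv$inside & body$inside] <- 1        # tumour is soft tissue
  dens
}

#' @keywords internal
mask_centroid_mm <- function(mask) {
  idx <- which(mask$inside, arr.ind = TRUE)
  g <- mask$geometry
  g$origin + (colMeans(idx) - 1) * g$spacing
}

#' @keywords internal
beam_source_position <- function(angle_deg, isocenter, sad) {
  th <- angle_deg * pi / 180
  # IEC: 0 deg anterior (source at -y in LPS), 90 deg at the patient's left (+x)
  isocenter + sad * c(sin(th), -cos(th), 0)
}

#' @keywords internal
ptv_target_points <- function(case, max_rays = Inf) {
  ptv <- case$structures[["ptv"]]
  idx <- which(ptv$inside, arr.ind = TRUE)
  g <- ptv$geometry
  pts <- sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  if (is.finite(max_rays) && nrow(pts) > max_rays) {
    stride <- ceiling(nrow(pts) / max_rays)
    pts <- pts[seq(1, nrow(pts), by = stride), , drop = FALSE]
  }
  pts
}

#' Beam efficiency index of one gantry angle
#'
#' Casts divergent rays from a virtual source (at `sad` from the isocenter,
#' the PTV centroid) to each PTV voxel and marches them through the
#' two-density body until they exit.  The benefit is the summed attenuated
#' fluence reaching the PTV voxels, `sum(exp(-mu * WED))`; the penalty is
#' the per-OAR attenuation-weighted path length through each OAR, combined
#' with the configured weights.  The index is
#' `benefit / (1e-6 + sum(w_o * penalty_o))`: deterministic, higher is
#' better.
#'
#' @param angle_deg gantry angle, degrees IEC.
#' @param case an [rt_case()] with body and PTV.
#' @param config a [beam_config()].
#' @return list with `index`, `benefit`, `penalty` (named per OAR),
#'   `angle_deg`.
#' @export
beam_efficiency_index <- function(angle_deg, case, config = beam_config()) {
  prof <- rank_beams(case, config = within_angles(config, angle_deg))
  list(index = prof$profile$index[1], benefit = prof$profile$benefit[1],
       penalty = unlist(prof$profile[1, grep("^penalty_", names(prof$profile))]),
       angle_deg = angle_deg)
}

#' @keywords internal
within_angles <- function(config, angles) { config$angles <- angles; config }

#' Evaluate and rank all candidate gantry angles
#'
#' @param case an [rt_case()] with body and PTV.
#' @param config a [beam_config()].
#' @return An object of class `efficiency_profile`: `profile` data frame
#'   (angle, index, benefit, per-OAR penalties) in descending index order
#'   (ties broken by the smaller angle), plus the isocenter used.
#' @export
rank_beams <- function(case, config = beam_config()) {
  stopifnot(inherits(case, "rt_case"))
  body <- case$structures[["body"]]
  g <- body$geometry
  iso <- mask_centroid_mm(case$structures[["ptv"]])
  iso_idx <- round((iso - g$origin) / g$spacing) + 1
  if (any(iso_idx < 1) || any(iso_idx > g$dims) ||
      !body$inside[iso_idx[1], iso_idx[2], iso_idx[3]])
    stop("PTV centroid lies outside the body: cannot place the isocenter")
  dens <- case_density(case, config$lung_density)
  oar_names <- intersect(names(config$oar_weights), names(case$structures))
  oar_masks <- lapply(oar_names, function(nm) as.vector(case$structures[[nm]]$inside))
  targets <- ptv_target_points(case, config$max_ptv_rays)
  rows <- lapply(config$angles, function(a) {
    src <- beam_source_position(a, iso, config$sad)
    tr <- .ray_trace_cpp(as.vector(dens), as.vector(body$inside), oar_masks,
                         targets, src, g$origin, g$spacing, g$dims,
                         config$mu, config$step_mm)
    pen <- as.numeric(tr$penalty)
    wsum <- sum(config$oar_weights[oar_names] * pen)
    row <- data.frame(angle = a, index = tr$benefit / (1e-6 + wsum),
                      benefit = tr$benefit)
    for (i in seq_along(oar_names))
      row[[paste0("penalty_", oar_names[i])]] <- pen[i]
    row
  })
  profile <- do.call(rbind, rows)
  ord <- order(-profile$index, profile$angle)
  structure(list(profile = profile[ord, , drop = FALSE],
                 isocenter_mm = iso, config = config),
            class = "efficiency_profile")
}

#' @export
print.efficiency_profile <- function(x, ...) {
  best <- x$profile[1, ]
  cat(sprintf("<efficiency_profile: %d angles, best %g deg (index %.4g)>\n",
              nrow(x$profile), best$angle, best$index))
  invisible(x)
}

#' @keywords internal
circular_separation_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Select a separated beam bouquet
#'
#' Greedy selection on the efficiency profile: repeatedly take the
#' highest-index angle whose circular distance to every already-selected
#' angle is at least `min_separation_deg` (forced separation so the bouquet
#' covers sufficient coplanar space).  In clinical mode the bouquet size is
#' restricted to 7--11 beams.
#'
#' @param case an [rt_case()], or a precomputed `efficiency_profile`.
#' @param n_beams number of beams to select.
#' @param min_separation_deg minimum pairwise circular separation (default
#'   20 degrees).
#' @param config a [beam_config()] (ignored when a profile is supplied).
#' @param mode `"clinical"` (enforces 7--11 beams) or `"free"`.
#' @param energy_mv beam energy metadata, 6 or 10 MV.
#' @return An object of class `beam_bouquet`: `beams` data frame
#'   (gantry_angle, energy_mv, weight, index, pick_order),
#'   `min_separation_deg` and the profile used.
#' @export
select_bouquet <- function(case, n_beams, min_separation_deg = 20,
                           config = beam_config(),
                           mode = c("clinical", "free"), energy_mv = 6) {
  mode <- match.arg(mode)
  if (mode == "clinical" && (n_beams < 7 || n_beams > 11))
    stop("clinical mode requires 7 to 11 beams (got ", n_beams, ")")
  if (n_beams < 1) stop("n_beams must be >= 1")
  if (!energy_mv %in% c(6, 10)) stop("energy_mv must be 6 or 10")
  if (n_beams * min_separation_deg > 360)
    stop("infeasible: ", n_beams, " beams cannot be separated by ",
         min_separation_deg, " degrees on a circle")
  profile <- if (inherits(case, "efficiency_profile")) case
             else rank_beams(case, config)
  pr <- profile$profile        # already sorted: index desc, angle asc
  chosen <- numeric(0); chosen_idx <- integer(0)
  for (r in seq_len(nrow(pr))) {
    a <- pr$angle[r]
    if (length(chosen) == 0 ||
        all(circular_separation_deg(a, chosen) >= min_separation_deg)) {
      chosen <- c(chosen, a)
      chosen_idx <- c(chosen_idx, r)
      if (length(chosen) == n_beams) break
    }
  }
  if (length(chosen) < n_beams)
    stop("infeasible: only ", length(chosen), " of ", n_beams,
         " beams selectable at ", min_separation_deg, " degree separation ",
         "on this angle grid")
  beams <- data.frame(gantry_angle = chosen %% 360,
                      energy_mv = energy_mv, weight = 1,
                      index = pr$index[chosen_idx],
                      pick_order = seq_along(chosen))
  structure(list(beams = beams, min_separation_deg = min_separation_deg,
                 isocenter_mm = profile$isocenter_mm),
            class = "beam_bouquet")
}

#' @export
print.beam_bouquet <- function(x, ...) {
  cat(sprintf("<beam_bouquet: %d beams at >=%g deg separation: %s>\n",
              nrow(x$beams), x$min_separation_deg,
              paste(x$beams$gantry_angle, collapse = ", ")))
  invisible(x)
}

#' @keywords internal
bouquet_to_json <- function(bouquet, path) {
  payload <- list(format = "rtplanscore_bouquet", version = 1L,
                  min_separation_deg = bouquet$min_separation_deg,
                  isocenter_mm = bouquet$isocenter_mm,
                  beams = bouquet$beams)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"), path)
  invisible(path)
}
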