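# Knowledge-based achievable-DVH prediction for OARs:
# DTH principal components + volumetric features -> DVH principal components
# via ordinary least squares, per OAR.

#' Default model configuration for the DVH prediction model
#'
#' @param oars OARs to model (subset of cord, cord+3mm, lungs, heart,
#'   esophagus).
#' @param n_dth_pc,n_dvh_pc number of principal components retained for the
#'   distance-to-target histograms and the DVHs (default 3 each).
#' @param dth_edges_mm DTH bin edges, mm (default -50 to 300, 2 mm step);
#'   shared across all cases.
#' @param dvh_grid relative-dose grid for DVH PCA (default 0 to 1.2, 0.01).
#' @param out_of_field_margin_mm superior-inferior margin beyond the PTV
#'   extent defining "in field" for the out-of-field volume feature.
#' @return named list of configuration values.
#' @export
kbp_config <- function(oars = c("lungs", "heart", "esophagus", "cord", "cord+3mm"),
                       n_dth_pc = 3L, n_dvh_pc = 3L,
                       dth_edges_mm = seq(-50, 300, by = 2),
                       dvh_grid = seq(0, 1.2, by = 0.01),
                       out_of_field_margin_mm = 20) {
  allowed <- c("cord", "cord+3mm", "lungs", "heart", "esophagus")
  if (!all(oars %in% allowed))
    stop("unsupported OARs: ", paste(setdiff(oars, allowed), collapse = ", "))
  list(oars = oars, n_dth_pc = as.integer(n_dth_pc),
       n_dvh_pc = as.integer(n_dvh_pc),
       dth_edges_mm = dth_edges_mm, dvh_grid = dvh_grid,
       out_of_field_margin_mm = out_of_field_margin_mm)
}

#' Distance-to-target histogram (DTH)
#'
#' Cumulative distribution of the signed Euclidean distance of OAR voxel
#' centers to the PTV surface (negative inside the PTV), evaluated on a
#' fixed bin-edge grid so DTHs are comparable across cases.
#'
#' @param oar,ptv non-empty [volume_mask()] objects on one geometry.
#' @param edges_mm bin edges in mm.
#' @param signed_dist optional precomputed [signed_distance_to_surface()]
#'   array for this PTV (to reuse across OARs).
#' @return An object of class `dth_curve`: `bin_edges_mm` and `cumulative`
#'   (fraction of OAR volume within distance <= edge; non-decreasing, 0 to 1).
#' @export
compute_dth <- function(oar, ptv, edges_mm = seq(-50, 300, by = 2),
                        signed_dist = NULL) {
  stopifnot(inherits(oar, "volume_mask"), inherits(ptv, "volume_mask"))
  if (!same_geometry(oar$geometry, ptv$geometry))
    stop("OAR and PTV geometries differ")
  if (!any(oar$inside)) stop("empty OAR mask: cannot compute DTH")
  if (!any(ptv$inside)) stop("empty PTV mask: cannot compute DTH")
  if (is.null(signed_dist)) signed_dist <- signed_distance_to_surface(ptv)
  d <- sort(signed_dist[oar$inside])
  cum <- findInterval(edges_mm, d) / length(d)   # fraction with distance <= edge
  structure(list(bin_edges_mm = edges_mm, cumulative = cum),
            class = "dth_curve")
}

#' @export
print.dth_curve <- function(x, ...) {
  cat(sprintf("<dth_curve %d edges [%g, %g] mm>\n", length(x$bin_edges_mm),
              min(x$bin_edges_mm), max(x$bin_edges_mm)))
  invisible(x)
}

#' @keywords internal
relative_dvh_curve <- function(dose, mask, prescription_gy, grid) {
  d <- sort(dose$values[mask$inside]) / prescription_gy
  n <- length(d)
  # percent of volume receiving >= g (relative dose), with edge tolerance
  100 * (n - findInterval(grid - 1e-12, d, left.open = TRUE)) / n
}

#' Anatomical features of a case for the DVH prediction model
#'
#' Per configured OAR: the DTH principal-component scores under the model's
#' trained DTH basis, OAR volume (cc), PTV volume (cc), OAR-PTV overlap
#' volume (cc), and the fraction of OAR volume outside the PTV's
#' superior-inferior extent expanded by the configured margin.  All features
#' depend only on relative geometry, so they are invariant to translating
#' the whole case.
#'
#' @param case an [rt_case()].
#' @param model a trained `dvh_model` (provides the DTH bases); or `NULL`
#'   to return raw curves plus volumetric features (used during fitting).
#' @param config a [kbp_config()]; taken from `model` when supplied.
#' @return named list per OAR; missing OARs are marked `absent = TRUE`.
#' @export
extract_features <- function(case, model = NULL, config = NULL) {
  stopifnot(inherits(case, "rt_case"))
  if (!is.null(model)) config <- model$config
  if (is.null(config)) config <- kbp_config()
  ptv <- case$structures[["ptv"]]
  vox_cc <- voxel_volume_cc(case_geometry(case))
  sd <- signed_distance_to_surface(ptv)
  zs <- grid_axis_mm(case_geometry(case), 3)
  ptv_z <- apply(ptv$inside, 3, any)
  zr <- range(zs[ptv_z]) + c(-1, 1) * config$out_of_field_margin_mm
  out <- list()
  for (nm in config$oars) {
    oar <- case$structures[[nm]]
    if (is.null(oar) || !any(oar$inside)) {
      out[[nm]] <- list(absent = TRUE)
      next
    }
    dth <- compute_dth(oar, ptv, edges_mm = config$dth_edges_mm,
                       signed_dist = sd)
    oar_cc <- mask_volume_cc(oar)
    overlap_cc <- sum(oar$inside & ptv$inside) * vox_cc
    in_band <- zs >= zr[1] & zs <= zr[2]
    n_oar <- sum(oar$inside)
    n_out <- sum(oar$inside[, , !in_band, drop = FALSE])
    feat <- list(absent = FALSE, dth = dth,
                 oar_volume_cc = oar_cc,
                 ptv_volume_cc = mask_volume_cc(ptv),
                 overlap_volume_cc = overlap_cc,
                 out_of_field_fraction = n_out / n_oar)
    if (!is.null(model)) {
      basis <- model$per_oar[[nm]]
      if (is.null(basis)) stop("OAR '", nm, "' is not in the trained model")
      feat$dth_pc <- as.numeric(
        (dth$cumulative - basis$dth_mean) %*% basis$dth_components)
      feat$vector <- c(feat$dth_pc, feat$oar_volume_cc, feat$ptv_volume_cc,
                       feat$overlap_volume_cc, feat$out_of_field_fraction)
    }
    out[[nm]] <- feat
  }
  structure(out, class = "anatomy_features")
}

#' @keywords internal
.pca_basis <- function(X, k) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(k, ncol(Xc), nrow(Xc)))
  V <- sv$v
  # canonical sign: largest-|.| loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(mean = mu, components = V,
       sdev = sv$d[seq_len(ncol(V))] / sqrt(max(1, nrow(X) - 1)))
}

#' Fit the achievable-DVH prediction model
#'
#' Per OAR: principal component analysis of the training DTHs and of the
#' prescription-normalized cumulative DVHs (fixed relative-dose grid), then
#' ordinary-least-squares regression of the DVH PC scores on the
#' standardized anatomical features.  Deterministic given the training set.
#'
#' @param training_cases list of [rt_case()] objects with doses.
#' @param config a [kbp_config()].
#' @return An object of class `dvh_model`.
#' @export
fit_dvh_model <- function(training_cases, config = kbp_config()) {
  k <- config$n_dth_pc
  n_min <- 2L * (k + 4L)
  per_case <- lapply(training_cases, function(cs) {
    if (is.null(cs$dose)) stop("training case '", cs$label, "' has no dose")
    extract_features(cs, model = NULL, config = config)
  })
  per_oar <- list()
  for (nm in config$oars) {
    have <- which(vapply(per_case, function(f) !isTRUE(f[[nm]]$absent),
                         logical(1)))
    if (length(have) < n_min)
      stop("OAR '", nm, "': ", length(have), " usable training cases, ",
           "need at least ", n_min)
    dth_mat <- t(vapply(per_case[have],
                        function(f) f[[nm]]$dth$cumulative,
                        numeric(length(config$dth_edges_mm))))
    dvh_mat <- t(vapply(have, function(i) {
      cs <- training_cases[[i]]
      relative_dvh_curve(cs$dose, cs$structures[[nm]], cs$prescription_gy,
                         config$dvh_grid)
    }, numeric(length(config$dvh_grid))))
    dth_basis <- .pca_basis(dth_mat, k)
    dvh_basis <- .pca_basis(dvh_mat, config$n_dvh_pc)
    dth_pc <- sweep(dth_mat, 2, dth_basis$mean) %*% dth_basis$components
    vols <- t(vapply(per_case[have], function(f) {
      x <- f[[nm]]
      c(x$oar_volume_cc, x$ptv_volume_cc, x$overlap_volume_cc,
        x$out_of_field_fraction)
    }, numeric(4)))
    feats <- cbind(dth_pc, vols)
    colnames(feats) <- c(paste0("dth_pc", seq_len(ncol(dth_pc))),
                         "oar_volume_cc", "ptv_volume_cc",
                         "overlap_volume_cc", "out_of_field_fraction")
    mu <- colMeans(feats)
    sd_ <- apply(feats, 2, stats::sd)
    sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1    # constant features pass through
    Z <- sweep(sweep(feats, 2, mu), 2, sd_, "/")
    scores <- sweep(dvh_mat, 2, dvh_basis$mean) %*% dvh_basis$components
    fit <- stats::lm.fit(cbind(1, Z), scores)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0          # rank-deficient (e.g. constant) features
    per_oar[[nm]] <- list(
      dth_mean = dth_basis$mean, dth_components = dth_basis$components,
      dvh_mean = dvh_basis$mean, dvh_components = dvh_basis$components,
      feature_mean = mu, feature_sd = sd_,
      coefficients = coefs,                   # (1 + p) x n_dvh_pc
      n_cases = length(have))
  }
  structure(list(config = config, per_oar = per_oar,
                 n_cases = length(training_cases), version = 1L),
            class = "dvh_model")
}

#' @export
print.dvh_model <- function(x, ...) {
  cat(sprintf("<dvh_model: %d OARs (%s), %d training cases, %d DTH + %d DVH PCs>\n",
              length(x$per_oar), paste(names(x$per_oar), collapse = ", "),
              x$n_cases, x$config$n_dth_pc, x$config$n_dvh_pc))
  invisible(x)
}

#' Predict achievable OAR DVHs
#'
#' Reconstructs each OAR's DVH as mean + predicted-score x component on the
#' model's relative-dose grid, then clips to `[0, 100]`, projects to the
#' nearest monotone non-increasing curve (pool-adjacent-violators), anchors
#' the curve at 100% at zero dose, and rescales the dose axis by the
#' prescription.
#'
#' @param model a `dvh_model`.
#' @param features an `anatomy_features` from [extract_features()] with this
#'   model, or an [rt_case()] (features are then extracted here).
#' @param prescription_gy prescription used to scale the dose axis.
#' @return named list of `dvh_curve` objects, one per modelled OAR present.
#' @export
predict_dvh <- function(model, features, prescription_gy) {
  stopifnot(inherits(model, "dvh_model"))
  if (inherits(features, "rt_case")) {
    prescription_gy <- features$prescription_gy
    features <- extract_features(features, model = model)
  }
  out <- list()
  for (nm in names(model$per_oar)) {
    f <- features[[nm]]
    if (is.null(f)) stop("features are missing modelled OAR '", nm, "'")
    if (isTRUE(f$absent)) next
    b <- model$per_oar[[nm]]
    z <- (f$vector - b$feature_mean) / b$feature_sd
    scores <- as.numeric(c(1, z) %*% b$coefficients)
    curve <- b$dvh_mean + as.numeric(b$dvh_components %*% scores)
    curve <- pmin(pmax(curve, 0), 100)
    curve <- -stats::isoreg(seq_along(curve), -curve)$yf   # monotone non-increasing
    curve[1] <- 100
    out[[nm]] <- new_dvh_curve(model$config$dvh_grid * prescription_gy, curve,
                               structure = nm)
  }
  out
}

#' Save / load a DVH prediction model
#'
#' Single-file JSON container (versioned) holding the configuration, PCA
#' bases, standardization parameters and regression coefficients.
#'
#' @param model a `dvh_model`.
#' @param path file path.
#' @return `load_dvh_model` returns the `dvh_model`.
#' @export
save_dvh_model <- function(model, path) {
  stopifnot(inherits(model, "dvh_model"))
  payload <- list(format = "rtplanscore_dvh_model", version = model$version,
                  config = model$config, n_cases = model$n_cases,
                  per_oar = lapply(model$per_oar, function(b) {
                    b$dth_components <- as.list(as.data.frame(b$dth_components))
                    b$dvh_components <- as.list(as.data.frame(b$dvh_components))
                    b$coefficients <- as.list(as.data.frame(b$coefficients))
                    b
                  }))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_dvh_model
#' @export
load_dvh_model <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyVector = TRUE)
  if (!identical(p$format, "rtplanscore_dvh_model"))
    stop("not a DVH model file")
  if (!identical(as.integer(p$version), 1L))
    stop("DVH model version mismatch: file v", p$version, ", reader v1")
  cfg <- kbp_config(oars = p$config$oars, n_dth_pc = p$config$n_dth_pc,
                    n_dvh_pc = p$config$n_dvh_pc,
                    dth_edges_mm = p$config$dth_edges_mm,
                    dvh_grid = p$config$dvh_grid,
                    out_of_field_margin_mm = p$config$out_of_field_margin_mm)
  per_oar <- lapply(p$per_oar, function(b) {
    b$dth_components <- as.matrix(as.data.frame(b$dth_components))
    b$dvh_components <- as.matrix(as.data.frame(b$dvh_components))
    b$coefficients <- as.matrix(as.data.frame(b$coefficients))
    dimnames(b$dth_components) <- NULL; dimnames(b$dvh_components) <- NULL
    b$feature_mean <- unlist(b$feature_mean); b$feature_sd <- unlist(b$feature_sd)
    b
  })
  structure(list(config = cfg, per_oar = per_oar, n_cases = p$n_cases,
                 version = 1L),
            class = "dvh_model")
}
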