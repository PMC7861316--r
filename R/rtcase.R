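#' Canonical structure names
#'
#' Canonical names used throughout the package.  `body` and `ptv` are
#' required in every case; the organs at risk are those scored and modelled
#' for lung/mediastinum IMRT.
#' @return character vector of canonical structure names.
#' @export
canonical_structures <- function() {
  c("body", "ptv", "gtv", "lungs", "heart", "esophagus", "cord", "cord+3mm")
}

#' A planning case: structures, prescription and (optionally) a dose
#'
#' @param structures named list of [volume_mask()] objects sharing one
#'   geometry.  Must contain `"body"` and `"ptv"`.
#' @param prescription_gy prescription dose in Gy (`> 0`).
#' @param dose optional [dose_grid()] on the same geometry.
#' @param label free-text case label.
#' @param difficulty optional free-text difficulty grade
#'   (e.g. `"easy"`, `"intermediate"`, `"hard"`).
#' @param meta optional named list of extra metadata (kept on save/load).
#' @return An object of class `rt_case`.
#' @export
rt_case <- function(structures, prescription_gy, dose = NULL, label = "",
                    difficulty = NULL, meta = list()) {
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("structures must be a named list")
  for (req in c("body", "ptv"))
    if (!req %in% names(structures))
      stop("case is missing required structure: ", req)
  g <- structures[[1]]$geometry
  for (nm in names(structures)) {
    m <- structures[[nm]]
    if (!inherits(m, "volume_mask")) stop("structure '", nm, "' is not a volume_mask")
    if (!same_geometry(m$geometry, g))
      stop("structure '", nm, "' is not on the shared case geometry")
  }
  prescription_gy <- as.numeric(prescription_gy)
  stopifnot(length(prescription_gy) == 1L, is.finite(prescription_gy),
            prescription_gy > 0)
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "dose_grid"))
    if (!same_geometry(dose$geometry, g))
      dose <- resample_dose(dose, g, mode = "trilinear")
  }
  structure(list(structures = structures, prescription_gy = prescription_gy,
                 dose = dose, label = as.character(label),
                 difficulty = if (is.null(difficulty)) NULL else as.character(difficulty),
                 meta = meta),
            class = "rt_case")
}

#' @export
print.rt_case <- function(x, ...) {
  cat(sprintf("<rt_case '%s'%s, Rx %.4g Gy, %d structures%s> %s\n",
              x$label,
              if (is.null(x$difficulty)) "" else paste0(" [", x$difficulty, "]"),
              x$prescription_gy, length(x$structures),
              if (is.null(x$dose)) ", no dose" else ", with dose",
              format(x$structures[[1]]$geometry)))
  invisible(x)
}

#' @keywords internal
case_geometry <- function(case) case$structures[[1]]$geometry

RTCASE_VERSION <- 1L

#' Save / load a case in the native `.rtcase` container
#'
#' The native format is a single file holding a little-endian binary
#' container: a 4-byte unsigned header length, a UTF-8 JSON header
#' (format tag, version, geometry, prescription, label, structure names and
#' array dtypes), then the raw arrays in header order -- `uint8` for masks
#' and `float64` for the dose.  `load_case(save_case(x))` reproduces `x`
#' bit-exactly.
#'
#' @param case an [rt_case()].
#' @param path file path to write / read.
#' @return `save_case` returns `path` invisibly; `load_case` returns the
#'   [rt_case()]; `inspect_case` returns the parsed JSON header only (no
#'   array data is read).
#' @export
save_case <- function(case, path) {
  stopifnot(inherits(case, "rt_case"))
  g <- case_geometry(case)
  header <- list(
    format = "rtcase", version = RTCASE_VERSION,
    geometry = list(origin = g$origin, spacing = g$spacing, dims = g$dims),
    prescription_gy = case$prescription_gy,
    label = case$label,
    difficulty = case$difficulty,
    meta = case$meta,
    structures = as.list(names(case$structures)),
    mask_dtype = "uint8", dose_dtype = "float64",
    has_dose = !is.null(case$dose))
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                   null = "null"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(length(hj), con, size = 4L, endian = "little")
  writeBin(hj, con)
  for (nm in names(case$structures))
    writeBin(as.integer(case$structures[[nm]]$inside), con, size = 1L,
             endian = "little")
  if (!is.null(case$dose))
    writeBin(as.vector(case$dose$values), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_case
#' @export
inspect_case <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n) != 1L || is.na(n) || n <= 0 || n > 1e8)
    stop("not an rtcase file: bad header length")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = n)),
                               simplifyVector = TRUE)
  if (!identical(header$format, "rtcase"))
    stop("not an rtcase file (format tag '", header$format, "')")
  if (!identical(as.integer(header$version), RTCASE_VERSION))
    stop("rtcase version mismatch: file version ", header$version,
         ", reader version ", RTCASE_VERSION)
  header
}

#' @rdname save_case
#' @export
load_case <- function(path) {
  header <- inspect_case(path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  invisible(readBin(con, "raw", n = n))
  g <- grid_geometry(header$geometry$origin, header$geometry$spacing,
                     header$geometry$dims)
  nv <- prod(g$dims)
  snames <- as.character(unlist(header$structures))
  for (req in c("body", "ptv"))
    if (!req %in% snames)
      stop("rtcase file is missing required structure: ", req)
  structures <- list()
  for (nm in snames) {
    raw <- readBin(con, "integer", n = nv, size = 1L, signed = FALSE,
                   endian = "little")
    structures[[nm]] <- volume_mask(g, array(raw > 0L, dim = g$dims))
  }
  dose <- NULL
  if (isTRUE(header$has_dose)) {
    vals <- readBin(con, "double", n = nv, size = 8L, endian = "little")
    dose <- dose_grid(g, array(vals, dim = g$dims))
  }
  meta <- header$meta
  if (is.null(meta) || length(meta) == 0L) meta <- list()
  rt_case(structures, header$prescription_gy, dose = dose,
          label = header$label,
          difficulty = header$difficulty, meta = meta)
}
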