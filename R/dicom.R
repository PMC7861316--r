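# Minimal DICOM support: explicit-VR little-endian read/write of the subset
# of RTDOSE and RTSTRUCT needed here.  Tags are "GGGG,EEEE" uppercase hex.

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' @keywords internal
.dcm_read_elements <- function(con, nbytes = Inf) {
  elements <- list()
  read_so_far <- 0
  repeat {
    if (read_so_far >= nbytes) break
    grp <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                   endian = "little")
    if (length(grp) == 0L) break
    ele <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                   endian = "little")
    read_so_far <- read_so_far + 4
    tag <- sprintf("%04X,%04X", grp, ele)
    if (grp == 0xFFFE) {            # item / delimiter structure
      len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
      read_so_far <- read_so_far + 4
      if (tag %in% c("FFFE,E00D", "FFFE,E0DD"))   # item / sequence delimiter
        return(list(elements = elements, bytes = read_so_far, stop = tag))
      stop("unexpected item tag outside a sequence: ", tag)
    }
    vr <- rawToChar(readBin(con, "raw", n = 2L))
    read_so_far <- read_so_far + 2
    if (vr %in% .LONG_VRS) {
      readBin(con, "raw", n = 2L)   # reserved
      len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
      read_so_far <- read_so_far + 6
    } else {
      len <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                     endian = "little")
      read_so_far <- read_so_far + 2
    }
    if (vr == "SQ") {
      items <- list()
      if (len == -1L) {             # undefined length: until sequence delimiter
        repeat {
          g2 <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                        endian = "little")
          e2 <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                        endian = "little")
          l2 <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
          read_so_far <- read_so_far + 8
          t2 <- sprintf("%04X,%04X", g2, e2)
          if (t2 == "FFFE,E0DD") break
          if (t2 != "FFFE,E000") stop("malformed sequence: expected item, got ", t2)
          res <- if (l2 == -1L) .dcm_read_elements(con)
                 else .dcm_read_elements(con, nbytes = l2)
          items <- c(items, list(res$elements))
          read_so_far <- read_so_far + res$bytes
        }
      } else {
        remaining <- len
        while (remaining > 0) {
          g2 <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                        endian = "little")
          e2 <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                        endian = "little")
          l2 <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
          read_so_far <- read_so_far + 8; remaining <- remaining - 8
          t2 <- sprintf("%04X,%04X", g2, e2)
          if (t2 != "FFFE,E000") stop("malformed sequence: expected item, got ", t2)
          res <- if (l2 == -1L) .dcm_read_elements(con)
                 else .dcm_read_elements(con, nbytes = l2)
          items <- c(items, list(res$elements))
          read_so_far <- read_so_far + res$bytes
          remaining <- remaining - res$bytes
        }
      }
      elements[[tag]] <- list(vr = vr, value = items)
    } else {
      raw <- readBin(con, "raw", n = len)
      read_so_far <- read_so_far + len
      elements[[tag]] <- list(vr = vr, value = .dcm_decode(vr, raw))
    }
  }
  list(elements = elements, bytes = read_so_far, stop = NA_character_)
}

#' @keywords internal
.dcm_decode <- function(vr, raw) {
  if (vr %in% c("DS", "IS")) {
    s <- trimws(rawToChar(raw))
    if (s == "") return(numeric(0))
    as.numeric(strsplit(s, "\\\\")[[1]])
  } else if (vr %in% c("CS", "LO", "SH", "ST", "UI", "PN", "DA", "TM", "LT", "UT", "AE")) {
    trimws(rawToChar(raw))
  } else if (vr == "US") {
    readBin(raw, "integer", n = length(raw) / 2, size = 2L, signed = FALSE,
            endian = "little")
  } else if (vr == "UL") {
    readBin(raw, "integer", n = length(raw) / 4, size = 4L, endian = "little")
  } else if (vr %in% c("FL", "OF")) {
    readBin(raw, "double", n = length(raw) / 4, size = 4L, endian = "little")
  } else if (vr == "FD") {
    readBin(raw, "double", n = length(raw) / 8, size = 8L, endian = "little")
  } else {
    raw   # OW/OB/UN: keep raw; pixel data is decoded by the caller
  }
}

#' @keywords internal
.dcm_parse_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  pre <- readBin(con, "raw", n = 132L)
  if (length(pre) < 132L || rawToChar(pre[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  .dcm_read_elements(con)$elements
}

#' @keywords internal
.dcm_get <- function(ds, tag, required = TRUE) {
  el <- ds[[tag]]
  if (is.null(el)) {
    if (required) stop("missing DICOM attribute (", tag, ")")
    return(NULL)
  }
  el$value
}

# ---- writing -----------------------------------------------------------

#' @keywords internal
.dcm_encode <- function(vr, value) {
  if (vr %in% c("DS", "IS")) {
    s <- paste(vapply(value, function(v) format(v, digits = 15, scientific = FALSE),
                      character(1)), collapse = "\\")
    raw <- charToRaw(s)
  } else if (vr %in% c("CS", "LO", "SH", "ST", "UI", "PN", "DA", "TM", "AE")) {
    raw <- charToRaw(paste(value, collapse = "\\"))
  } else if (vr == "US") {
    raw <- writeBin(as.integer(value), raw(), size = 2L, endian = "little")
  } else if (vr == "UL") {
    raw <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    raw <- value
  } else {
    stop("unsupported VR for writing: ", vr)
  }
  if (length(raw) %% 2 == 1)
    raw <- c(raw, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  raw
}

#' @keywords internal
.dcm_element_raw <- function(tag, vr, value) {
  ge <- strtoi(strsplit(tag, ",")[[1]], 16L)
  head <- writeBin(as.integer(ge), raw(), size = 2L, endian = "little")
  if (vr == "SQ") {
    body <- raw()
    for (item in value) {
      ib <- raw()
      for (nm in names(item))
        ib <- c(ib, .dcm_element_raw(nm, item[[nm]]$vr, item[[nm]]$value))
      body <- c(body,
                writeBin(as.integer(c(0xFFFE, 0xE000)), raw(), size = 2L,
                         endian = "little"),
                writeBin(length(ib), raw(), size = 4L, endian = "little"),
                ib)
    }
    c(head, charToRaw("SQ"), as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4L, endian = "little"), body)
  } else {
    body <- .dcm_encode(vr, value)
    if (vr %in% .LONG_VRS) {
      c(head, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(length(body), raw(), size = 4L, endian = "little"), body)
    } else {
      c(head, charToRaw(vr),
        writeBin(length(body), raw(), size = 2L, endian = "little"), body)
    }
  }
}

#' @keywords internal
.dcm_write_file <- function(path, elements, sop_class_uid) {
  # file meta (group 0002), explicit VR little endian
  meta <- list(
    `0002,0002` = list(vr = "UI", value = sop_class_uid),
    `0002,0003` = list(vr = "UI", value = "1.2.826.0.1.3680043.8.498.1"),
    `0002,0010` = list(vr = "UI", value = "1.2.840.10008.1.2.1"))
  meta_raw <- raw()
  for (nm in names(meta))
    meta_raw <- c(meta_raw, .dcm_element_raw(nm, meta[[nm]]$vr, meta[[nm]]$value))
  grouplen <- .dcm_element_raw("0002,0000", "UL", length(meta_raw))
  body <- raw()
  for (nm in names(elements))
    body <- c(body, .dcm_element_raw(nm, elements[[nm]]$vr, elements[[nm]]$value))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(grouplen, con)
  writeBin(meta_raw, con)
  writeBin(body, con)
  invisible(path)
}

# ---- RTDOSE ------------------------------------------------------------

#' Read a DICOM RTDOSE file
#'
#' Supports axis-aligned, explicit-VR little-endian RTDOSE objects with
#' uniform frame offsets.  Stored integers are scaled by Dose Grid Scaling;
#' Dose Units must be `GY`.  Files whose frame offsets decrease are
#' normalized by flipping the slice axis so the returned geometry always has
#' increasing z.
#'
#' @param path file path.
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(path) {
  ds <- .dcm_parse_file(path)
  units <- toupper(.dcm_get(ds, "3004,0002"))
  if (!identical(units, "GY"))
    stop("RTDOSE dose units are '", units, "', only GY is supported")
  scaling <- .dcm_get(ds, "3004,000E")
  if (!length(scaling) || !is.finite(scaling))
    stop("RTDOSE is missing a usable Dose Grid Scaling (3004,000E)")
  rows <- .dcm_get(ds, "0028,0010"); cols <- .dcm_get(ds, "0028,0011")
  nframes <- as.integer(.dcm_get(ds, "0028,0008"))
  ipp <- .dcm_get(ds, "0020,0032")
  iop <- .dcm_get(ds, "0020,0037")
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("RTDOSE orientation is not axis-aligned (ImageOrientationPatient = ",
         paste(iop, collapse = ", "), ")")
  px <- .dcm_get(ds, "0028,0030")     # (row spacing, col spacing) = (dy, dx)
  offsets <- .dcm_get(ds, "3004,000C")
  if (length(offsets) != nframes)
    stop("GridFrameOffsetVector length does not match NumberOfFrames")
  dz <- diff(offsets)
  if (nframes > 1 && (max(dz) - min(dz) > 1e-6 * max(abs(dz)) + 1e-9))
    stop("non-uniform grid frame offsets are not supported")
  bits <- .dcm_get(ds, "0028,0100")
  pix_raw <- .dcm_get(ds, "7FE0,0010")
  n <- as.integer(cols) * as.integer(rows) * nframes
  stored <- if (bits == 16L) {
    readBin(pix_raw, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  } else if (bits == 32L) {
    v <- readBin(pix_raw, "integer", n = n, size = 4L, endian = "little")
    ifelse(v < 0, v + 2^32, as.numeric(v))
  } else stop("unsupported Bits Allocated: ", bits)
  vals <- array(as.numeric(stored) * scaling, dim = c(cols, rows, nframes))
  step <- if (nframes > 1) dz[1] else 1
  origin <- c(ipp[1], ipp[2], ipp[3] + offsets[1])
  if (nframes > 1 && step < 0) {      # normalize reversed slice ordering
    vals <- vals[, , nframes:1, drop = FALSE]
    origin[3] <- origin[3] + (nframes - 1) * step
    step <- -step
  }
  g <- grid_geometry(origin, c(px[2], px[1], step), c(cols, rows, nframes))
  dose_grid(g, vals)
}

#' Write a minimal-valid DICOM RTDOSE fixture
#'
#' Test/fixture writer: stores the dose as 16-bit unsigned integers with a
#' Dose Grid Scaling chosen from the maximum dose (or given explicitly).
#'
#' @param dose a [dose_grid()].
#' @param path output file path.
#' @param scaling optional dose-grid scaling (Gy per stored unit).
#' @param reverse_slices store frames in decreasing-z order (for testing the
#'   reader's geometry normalization).
#' @return `path`, invisibly.
#' @export
write_rtdose_fixture <- function(dose, path, scaling = NULL,
                                 reverse_slices = FALSE) {
  stopifnot(inherits(dose, "dose_grid"))
  g <- dose$geometry
  if (is.null(scaling)) {
    mx <- max(dose$values)
    scaling <- if (mx > 0) mx / 65000 else 1e-3
  }
  vals <- dose$values
  origin <- g$origin
  offsets <- (seq_len(g$dims[3]) - 1) * g$spacing[3]
  if (reverse_slices) {
    vals <- vals[, , g$dims[3]:1, drop = FALSE]
    origin <- c(g$origin[1], g$origin[2], g$origin[3] + (g$dims[3] - 1) * g$spacing[3])
    offsets <- -offsets
  }
  stored <- as.integer(round(as.vector(vals) / scaling))
  if (any(stored > 65535L)) stop("dose too large for 16-bit fixture at this scaling")
  pix <- writeBin(stored, raw(), size = 2L, endian = "little")
  elements <- list(
    `0008,0016` = list(vr = "UI", value = "1.2.840.10008.5.1.4.1.1.481.2"),
    `0008,0018` = list(vr = "UI", value = "1.2.826.0.1.3680043.8.498.2"),
    `0008,0060` = list(vr = "CS", value = "RTDOSE"),
    `0020,0032` = list(vr = "DS", value = origin),
    `0020,0037` = list(vr = "DS", value = c(1, 0, 0, 0, 1, 0)),
    `0028,0002` = list(vr = "US", value = 1L),
    `0028,0008` = list(vr = "IS", value = g$dims[3]),
    `0028,0010` = list(vr = "US", value = g$dims[2]),
    `0028,0011` = list(vr = "US", value = g$dims[1]),
    `0028,0030` = list(vr = "DS", value = c(g$spacing[2], g$spacing[1])),
    `0028,0100` = list(vr = "US", value = 16L),
    `0028,0101` = list(vr = "US", value = 16L),
    `0028,0103` = list(vr = "US", value = 0L),
    `3004,0002` = list(vr = "CS", value = "GY"),
    `3004,0004` = list(vr = "CS", value = "PHYSICAL"),
    `3004,000C` = list(vr = "DS", value = offsets),
    `3004,000E` = list(vr = "DS", value = scaling),
    `7FE0,0010` = list(vr = "OW", value = pix))
  .dcm_write_file(path, elements, "1.2.840.10008.5.1.4.1.1.481.2")
}

# ---- RTSTRUCT ----------------------------------------------------------

#' Read a DICOM RTSTRUCT file and rasterize its ROIs
#'
#' Planar (axial) contours are rasterized onto `geometry` with
#' [rasterize_contours()].  ROI names are normalized to the package's
#' canonical names through the alias table; unknown names are kept verbatim
#' with a warning.
#'
#' @param path file path.
#' @param geometry target [grid_geometry()].
#' @param aliases alias table as returned by [structure_aliases()].
#' @param supersample passed to [rasterize_contours()].
#' @return Named list of [volume_mask()] (a structure set).
#' @export
read_rtstruct <- function(path, geometry, aliases = structure_aliases(),
                          supersample = 4L) {
  ds <- .dcm_parse_file(path)
  rois <- .dcm_get(ds, "3006,0020")   # StructureSetROISequence
  names_by_number <- list()
  for (item in rois) {
    num <- as.character(item[["3006,0022"]]$value)
    names_by_number[[num]] <- item[["3006,0026"]]$value
  }
  contours_seq <- .dcm_get(ds, "3006,0039")  # ROIContourSequence
  out <- list()
  for (item in contours_seq) {
    num <- as.character(item[["3006,0084"]]$value)
    raw_name <- names_by_number[[num]]
    name <- normalize_structure_name(raw_name, aliases)
    cs <- item[["3006,0040"]]
    contours <- list()
    if (!is.null(cs)) {
      for (ct in cs$value) {
        gt <- ct[["3006,0042"]]$value
        if (!is.null(gt) && !identical(toupper(gt), "CLOSED_PLANAR"))
          stop("unsupported contour geometric type: ", gt)
        pts <- matrix(ct[["3006,0050"]]$value, ncol = 3, byrow = TRUE)
        contours <- c(contours, list(list(z = pts[1, 3], xy = pts[, 1:2, drop = FALSE])))
      }
    }
    out[[name]] <- rasterize_contours(contours, geometry, supersample = supersample)
  }
  out
}

#' Write a minimal-valid DICOM RTSTRUCT fixture
#'
#' @param rois named list; each element a list of contours (`z`, `xy` as in
#'   [rasterize_contours()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rtstruct_fixture <- function(rois, path) {
  roi_seq <- list(); contour_seq <- list()
  for (i in seq_along(rois)) {
    roi_seq[[i]] <- list(
      `3006,0022` = list(vr = "IS", value = i),
      `3006,0026` = list(vr = "LO", value = names(rois)[i]))
    cts <- list()
    for (ct in rois[[i]]) {
      pts <- cbind(ct$xy, ct$z)
      cts <- c(cts, list(list(
        `3006,0042` = list(vr = "CS", value = "CLOSED_PLANAR"),
        `3006,0046` = list(vr = "IS", value = nrow(pts)),
        `3006,0050` = list(vr = "DS", value = as.vector(t(pts))))))
    }
    contour_seq[[i]] <- list(
      `3006,0040` = list(vr = "SQ", value = cts),
      `3006,0084` = list(vr = "IS", value = i))
  }
  elements <- list(
    `0008,0016` = list(vr = "UI", value = "1.2.840.10008.5.1.4.1.1.481.3"),
    `0008,0018` = list(vr = "UI", value = "1.2.826.0.1.3680043.8.498.3"),
    `0008,0060` = list(vr = "CS", value = "RTSTRUCT"),
    `3006,0020` = list(vr = "SQ", value = roi_seq),
    `3006,0039` = list(vr = "SQ", value = contour_seq))
  .dcm_write_file(path, elements, "1.2.840.10008.5.1.4.1.1.481.3")
}

#' Structure-name normalization
#'
#' The alias table maps vendor/clinic ROI names to the canonical names used
#' throughout the package.  The default table ships as an editable YAML at
#' `system.file("extdata", "structure_aliases.yaml", package = "rtplanscore")`.
#'
#' @param path optional path to an alias YAML (named map alias -> canonical).
#' @return named character vector (names are lower-cased aliases).
#' @export
structure_aliases <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "structure_aliases.yaml",
                        package = "rtplanscore")
  tab <- yaml::read_yaml(path)
  out <- unlist(tab)
  names(out) <- tolower(names(out))
  out
}

#' @rdname structure_aliases
#' @param name a raw ROI name.
#' @param aliases alias table.
#' @export
normalize_structure_name <- function(name, aliases = structure_aliases()) {
  key <- tolower(trimws(name))
  if (key %in% names(aliases)) return(unname(aliases[[key]]))
  if (key %in% canonical_structures()) return(key)
  warning("unknown ROI name kept verbatim: '", name, "'")
  name
}
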