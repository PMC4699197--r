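# Shared data model: scan metadata, volumes, interfaces, boundary sets,
# enface maps.  All grids are indexed [B-scan y, depth row z, A-scan x],
# 1-based, with depth row 1 on the vitreous (inner) side.

#' The five segmented retinal interfaces, in anatomical depth order
#'
#' Interface identifiers used throughout the package, ordered from the
#' vitreous side down: vitreous/ILM, INL/OPL, ONL/ISe, ISe/RPE, RPE/choroid.
#'
#' @return Character vector of the five interface ids.
#' @export
#' @examples
#' interface_ids()
interface_ids <- function() {
  c("VITREOUS_ILM", "INL_OPL", "ONL_ISE", "ISE_RPE", "RPE_CHOROID")
}

#' Gradient polarity of a layer interface
#'
#' An interface is found either at dark-to-bright transitions (intensity
#' increasing with depth, positive vertical gradient) or bright-to-dark
#' transitions (negative vertical gradient).
#'
#' @return Character vector of the two polarity names.
#' @export
polarities <- function() c("DARK_TO_BRIGHT", "BRIGHT_TO_DARK")

match_polarity <- function(polarity) {
  match.arg(polarity, polarities())
}

match_interface <- function(interface) {
  match.arg(interface, interface_ids())
}

#' Scan geometry and acquisition metadata
#'
#' Describes the raster geometry of an SDOCT macular volume scan.  The
#' defaults reproduce a Spectralis-like high-density protocol: 145 horizontal
#' B-scans of 768 A-scans covering a 15 x 15 degree field centred on the
#' fovea, 3.9 um axial sampling, ~31 um B-scan spacing, 9 frames averaged
#' per B-scan location.
#'
#' @param n_bscans Number of B-scans in the raster (>= 1).
#' @param n_ascans Number of A-scans per B-scan (>= 1).
#' @param n_depth Number of depth rows (pixels) per A-scan (>= 1).
#' @param axial_um_per_px Axial sampling in micrometres per pixel (> 0).
#' @param bscan_spacing_um Spacing between adjacent B-scans, micrometres.
#' @param field_deg Angular extent of the (square) scan field, degrees.
#' @param frames_averaged Frames averaged per B-scan location.
#' @return An object of class `scan_metadata` (a named list).
#' @export
#' @examples
#' scan_metadata()             # default high-density macular profile
#' scan_metadata(n_depth = 160)
scan_metadata <- function(n_bscans = 145L, n_ascans = 768L, n_depth = 496L,
                          axial_um_per_px = 3.9, bscan_spacing_um = 31,
                          field_deg = 15, frames_averaged = 9L) {
  m <- list(
    n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
    n_depth = as.integer(n_depth), axial_um_per_px = as.numeric(axial_um_per_px),
    bscan_spacing_um = as.numeric(bscan_spacing_um),
    field_deg = as.numeric(field_deg),
    frames_averaged = as.integer(frames_averaged)
  )
  counts <- c(m$n_bscans, m$n_ascans, m$n_depth, m$frames_averaged)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("all scan_metadata counts must be >= 1", call. = FALSE)
  if (!is.finite(m$axial_um_per_px) || m$axial_um_per_px <= 0)
    stop("axial_um_per_px must be > 0", call. = FALSE)
  if (m$bscan_spacing_um <= 0 || m$field_deg <= 0)
    stop("bscan_spacing_um and field_deg must be > 0", call. = FALSE)
  structure(m, class = "scan_metadata")
}

#' @export
print.scan_metadata <- function(x, ...) {
  cat(sprintf(
    "SDOCT scan metadata: %d B-scans x %d depth rows x %d A-scans\n",
    x$n_bscans, x$n_depth, x$n_ascans))
  cat(sprintf("  axial sampling %.3g um/px, B-scan spacing %.3g um, %g deg field, %d frames averaged\n",
              x$axial_um_per_px, x$bscan_spacing_um, x$field_deg,
              x$frames_averaged))
  invisible(x)
}

# Lateral A-scan pitch in micrometres, assuming ~288 um per degree of
# visual angle (emmetropic schematic eye).
ascan_pitch_um <- function(meta) {
  288 * meta$field_deg / meta$n_ascans
}

#' Construct an SDOCT intensity volume
#'
#' @param intensity 3-D numeric array with dim `(n_bscans, n_depth, n_ascans)`;
#'   values must lie in `[0, 1]` (normalized reflectance).  Depth row 1 is the
#'   vitreous (inner) side.
#' @param meta A [scan_metadata()] object; its counts must match `dim(intensity)`.
#' @return An object of class `oct_volume`: list with elements `intensity`
#'   and `meta`.
#' @export
oct_volume <- function(intensity, meta) {
  stopifnot(inherits(meta, "scan_metadata"))
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity must be a 3-D array [bscan, depth, ascan]", call. = FALSE)
  expected <- c(meta$n_bscans, meta$n_depth, meta$n_ascans)
  if (!identical(as.integer(dim(intensity)), as.integer(expected)))
    stop(sprintf("intensity dim (%s) does not match metadata (%s)",
                 paste(dim(intensity), collapse = "x"),
                 paste(expected, collapse = "x")), call. = FALSE)
  rng <- range(intensity)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("intensity values must be finite and in [0, 1]", call. = FALSE)
  structure(list(intensity = intensity, meta = meta), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("oct_volume: %d B-scans x %d depth rows x %d A-scans, intensity in [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Extract one B-scan from a volume
#'
#' @param vol An [oct_volume()].
#' @param y B-scan index (1-based).
#' @return Numeric matrix `(n_depth, n_ascans)`.
#' @export
get_bscan <- function(vol, y) {
  stopifnot(inherits(vol, "oct_volume"))
  y <- as.integer(y)
  if (y < 1L || y > vol$meta$n_bscans) stop("B-scan index out of range", call. = FALSE)
  m <- vol$intensity[y, , ]
  dim(m) <- dim(vol$intensity)[2:3]
  m
}

#' Construct a five-interface boundary set
#'
#' Holds, for each of the five retinal interfaces, a `(n_bscans, n_ascans)`
#' matrix of depth rows (pixel units, sub-pixel values allowed) plus a shared
#' validity mask.  Valid entries must respect the anatomical depth ordering
#' `VITREOUS_ILM <= INL_OPL <= ONL_ISE <= ISE_RPE <= RPE_CHOROID`
#' (checked by [validate_boundary_set()], enforced here unless
#' `check = FALSE`).
#'
#' @param rows Named list of five numeric matrices (one per interface id),
#'   all of dim `(n_bscans, n_ascans)`, rows in `[1, n_depth]` where valid.
#' @param meta A [scan_metadata()] object.
#' @param valid Logical matrix `(n_bscans, n_ascans)`; a pixel is usable only
#'   where `TRUE`.  Defaults to all pixels with finite rows in all interfaces.
#' @param check Validate depth ordering on construction (default `TRUE`).
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(rows, meta, valid = NULL, check = TRUE) {
  stopifnot(inherits(meta, "scan_metadata"))
  ids <- interface_ids()
  if (!is.list(rows) || !all(ids %in% names(rows)))
    stop("rows must be a named list with one matrix per interface id", call. = FALSE)
  rows <- rows[ids]
  shp <- c(meta$n_bscans, meta$n_ascans)
  for (id in ids) {
    if (!is.matrix(rows[[id]]) || !identical(as.integer(dim(rows[[id]])), as.integer(shp)))
      stop(sprintf("boundary '%s' must be a %d x %d matrix", id, shp[1], shp[2]),
           call. = FALSE)
    storage.mode(rows[[id]]) <- "double"
  }
  if (is.null(valid)) {
    valid <- Reduce(`&`, lapply(rows, is.finite))
  }
  stopifnot(is.matrix(valid), identical(as.integer(dim(valid)), as.integer(shp)))
  for (id in ids) {
    r <- rows[[id]][valid]
    if (any(!is.finite(r)) || any(r < 1 | r > meta$n_depth))
      stop(sprintf("valid rows of '%s' must lie in [1, n_depth]", id), call. = FALSE)
  }
  bs <- structure(list(rows = rows, valid = valid, meta = meta),
                  class = "boundary_set")
  if (check) {
    v <- validate_boundary_set(bs)
    if (nrow(v) > 0)
      stop(sprintf("depth ordering violated at %d pixel(s), e.g. %s above %s at (y=%d, x=%d)",
                   nrow(v), v$lower[1], v$upper[1], v$bscan[1], v$ascan[1]),
           call. = FALSE)
  }
  bs
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("boundary_set: 5 interfaces on a %d x %d grid, %d/%d pixels valid\n",
              x$meta$n_bscans, x$meta$n_ascans, sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Check the anatomical depth ordering of a boundary set
#'
#' Scans every valid pixel for violations of the interface depth order
#' (each interface must lie at or below the one anatomically above it).
#'
#' @param bs A [boundary_set()] (or a bare list with the same fields, so the
#'   check can be applied before construction).
#' @return A data frame with zero rows iff the ordering holds everywhere;
#'   otherwise one row per violation with columns `upper`, `lower` (the
#'   interface pair), `bscan`, `ascan`.
#' @export
validate_boundary_set <- function(bs) {
  ids <- interface_ids()
  rows <- bs$rows[ids]
  shapes <- unique(lapply(rows, dim))
  if (length(shapes) != 1L)
    stop("boundary grids have mismatched shapes", call. = FALSE)
  valid <- bs$valid
  out <- list()
  for (k in seq_len(length(ids) - 1L)) {
    upper <- rows[[ids[k]]]
    lower <- rows[[ids[k + 1L]]]
    bad <- which(valid & (lower < upper), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        upper = ids[k], lower = ids[k + 1L],
        bscan = as.integer(bad[, 1]), ascan = as.integer(bad[, 2]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(upper = character(), lower = character(),
                      bscan = integer(), ascan = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Construct an enface (C-scan) map
#'
#' A single scalar per (B-scan, A-scan) position: either a layer thickness in
#' micrometres or a mean normalized reflectance in `[0, 1]`.
#'
#' @param values Numeric matrix `(n_bscans, n_ascans)`.
#' @param kind `"thickness_um"` or `"reflectance"`.
#' @param layer Layer tag: `"TR"`, `"IR"`, `"OR"` or `"ISE"`.
#' @param meta A [scan_metadata()] object.
#' @param valid Logical validity matrix; defaults to finite entries.
#' @return An object of class `enface_map`.
#' @export
enface_map <- function(values, kind = c("thickness_um", "reflectance"),
                       layer = c("TR", "IR", "OR", "ISE"), meta,
                       valid = NULL) {
  kind <- match.arg(kind)
  layer <- match.arg(layer)
  stopifnot(inherits(meta, "scan_metadata"))
  if (!is.matrix(values) ||
      !identical(as.integer(dim(values)), c(meta$n_bscans, meta$n_ascans)))
    stop("values must be an (n_bscans x n_ascans) matrix", call. = FALSE)
  storage.mode(values) <- "double"
  if (is.null(valid)) valid <- is.finite(values)
  stopifnot(is.matrix(valid), identical(dim(valid), dim(values)))
  v <- values[valid]
  if (kind == "thickness_um" && any(v < 0))
    stop("thickness values must be >= 0", call. = FALSE)
  if (kind == "reflectance" && (any(v < 0) || any(v > 1)))
    stop("reflectance values must lie in [0, 1]", call. = FALSE)
  values[!valid] <- NA_real_
  structure(list(values = values, kind = kind, layer = layer,
                 valid = valid, meta = meta),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  unit <- if (x$kind == "thickness_um") "um" else "normalized reflectance"
  rng <- range(x$values[x$valid])
  cat(sprintf("enface_map [%s, %s]: %d x %d, range %.2f..%.2f %s, %d/%d valid\n",
              x$layer, x$kind, nrow(x$values), ncol(x$values),
              rng[1], rng[2], unit, sum(x$valid), length(x$valid)))
  invisible(x)
}

#' @export
summary.enface_map <- function(object, ...) {
  v <- object$values[object$valid]
  out <- c(min = min(v), median = median(v), mean = mean(v), max = max(v),
           sd = sd(v), n_valid = sum(object$valid))
  class(out) <- "summary.enface_map"
  out
}

#' @export
print.summary.enface_map <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Display an enface map as a grayscale image
#'
#' @param x An [enface_map()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.enface_map <- function(x, ...) {
  v <- x$values
  # flip y so B-scan 1 is at the top, as in raster display order
  graphics::image(t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = sprintf("%s %s", x$layer, x$kind), ...)
  invisible(x)
}
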