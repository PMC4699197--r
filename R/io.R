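# On-disk formats: volumes (multi-page TIFF or raw + JSON sidecar),
# boundary tables (CSV/JSON), correction polylines, enface maps
# (float TIFF + CSV + plain-text previews), deviation maps (plain-text PPM
# + CSV), run configuration (JSON) and the output manifest.
#
# Conventions, stated in every sidecar: indices are 1-based; depth row 1 is
# the vitreous side; thickness always um; reflectance always normalized to
# [0, 1].

oct_log <- function(..., quiet = FALSE) {
  if (!quiet) message(sprintf(...))
}

meta_to_list <- function(meta) unclass(meta)

meta_from_list <- function(lst) do.call(scan_metadata, lst)

#' Write an SDOCT volume to disk
#'
#' `.tif`/`.tiff` paths get a multi-page grayscale TIFF (one page per
#' B-scan, page rows = depth, page columns = A-scans) in uint16 or uint8;
#' any other path gets raw little-endian unsigned samples in the same
#' order.  A JSON sidecar `<path>.json` always records the shape, sample
#' type, axis order and scan metadata.  Intensities in `[0, 1]` are scaled
#' by the integer type maximum, so a written volume re-read with
#' [read_volume()] reproduces the quantized intensities exactly.
#'
#' @param vol An [oct_volume()].
#' @param path Output path (`.tif`/`.tiff` for TIFF, else raw binary).
#' @param type `"uint16"` (default) or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, type = c("uint16", "uint8")) {
  stopifnot(inherits(vol, "oct_volume"))
  type <- match.arg(type)
  maxval <- if (type == "uint16") 65535 else 255
  meta <- vol$meta
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  q <- round(vol$intensity * maxval)
  if (is_tiff) {
    write_tiff(q, path, type = type)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    for (y in seq_len(meta$n_bscans)) {
      page <- q[y, , ]
      v <- as.integer(as.vector(t(page))) # row-major within page
      if (type == "uint8") writeBin(as.raw(v), con)
      else writeBin(u16le(v), con)
    }
  }
  sidecar <- list(
    format = if (is_tiff) "tiff" else "raw",
    dtype = type, byte_order = "little",
    axis_order = "bscan_page, depth_row, ascan_column (row-major pages)",
    indexing = "1-based; depth row 1 = vitreous side",
    shape = c(meta$n_bscans, meta$n_depth, meta$n_ascans),
    scale = maxval,
    meta = meta_to_list(meta))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an SDOCT volume from disk
#'
#' Reads a multi-page TIFF or a raw binary volume and normalizes the
#' intensities to `[0, 1]` by dividing by the sample type maximum.  Raw
#' input requires the JSON sidecar (shape and metadata); for TIFF the
#' sidecar is used when present and the page shape is cross-checked
#' against it.
#'
#' @param path Volume file path.
#' @param sidecar Path to the JSON sidecar; defaults to `<path>.json`.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, sidecar = paste0(path, ".json")) {
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else NULL
  if (is_tiff) {
    tf <- read_tiff(path)
    shape <- c(length(tf$pages), nrow(tf$pages[[1]]), ncol(tf$pages[[1]]))
    maxval <- if (tf$type == "uint16") 65535 else if (tf$type == "uint8") 255
              else stop("volume TIFF must be uint8 or uint16", call. = FALSE)
    if (!is.null(side) && !identical(as.integer(side$shape), as.integer(shape)))
      stop(sprintf("TIFF shape (%s) does not match sidecar (%s)",
                   paste(shape, collapse = "x"),
                   paste(side$shape, collapse = "x")), call. = FALSE)
    meta <- if (!is.null(side)) meta_from_list(side$meta)
            else scan_metadata(n_bscans = shape[1], n_depth = shape[2],
                               n_ascans = shape[3])
    arr <- array(0, shape)
    for (y in seq_len(shape[1])) arr[y, , ] <- tf$pages[[y]] / maxval
  } else {
    if (is.null(side))
      stop("raw volume input requires the JSON metadata sidecar", call. = FALSE)
    shape <- as.integer(side$shape)
    size <- if (side$dtype == "uint16") 2L else 1L
    maxval <- if (side$dtype == "uint16") 65535 else 255
    n <- prod(shape)
    if (file.size(path) != n * size)
      stop(sprintf("raw volume size (%d bytes) does not match sidecar shape",
                   file.size(path)), call. = FALSE)
    v <- readBin(path, "integer", n = n, size = size, signed = FALSE,
                 endian = "little")
    meta <- meta_from_list(side$meta)
    arr <- array(0, shape)
    per <- shape[2] * shape[3]
    for (y in seq_len(shape[1])) {
      page <- matrix(v[((y - 1) * per + 1):(y * per)], shape[2], shape[3],
                     byrow = TRUE)
      arr[y, , ] <- page / maxval
    }
  }
  oct_volume(arr, meta)
}

#' Write boundary tables
#'
#' Long-format CSV with columns `bscan, ascan, interface, row` (1-based
#' indices, row in pixels, `NA` where invalid) and/or JSON carrying the
#' same table plus the scan metadata.
#'
#' @param bs A [boundary_set()].
#' @param path Output path; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(bs, path) {
  stopifnot(inherits(bs, "boundary_set"))
  meta <- bs$meta
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(meta = meta_to_list(meta),
                indexing = "1-based; depth row 1 = vitreous side",
                valid = bs$valid,
                rows = bs$rows)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    ids <- interface_ids()
    grids <- expand.grid(bscan = seq_len(meta$n_bscans),
                         ascan = seq_len(meta$n_ascans))
    tabs <- lapply(ids, function(id) {
      r <- bs$rows[[id]]
      r[!bs$valid] <- NA_real_
      data.table::data.table(bscan = grids$bscan, ascan = grids$ascan,
                             interface = id, row = as.vector(r))
    })
    data.table::fwrite(data.table::rbindlist(tabs), path)
  }
  invisible(path)
}

#' Read boundary tables written by [write_boundaries()]
#'
#' @param path CSV or JSON boundary table path.
#' @param meta Required for CSV input (the CSV carries no metadata);
#'   ignored for JSON.
#' @return A [boundary_set()].
#' @export
read_boundaries <- function(path, meta = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    meta <- meta_from_list(obj$meta)
    rows <- lapply(obj$rows, function(m) matrix(unlist(m), meta$n_bscans))
    valid <- matrix(unlist(obj$valid), meta$n_bscans)
    return(boundary_set(rows[interface_ids()], meta, valid = valid))
  }
  if (is.null(meta))
    stop("CSV boundary tables need scan metadata (meta =)", call. = FALSE)
  dt <- data.table::fread(path)
  ids <- interface_ids()
  rows <- setNames(lapply(ids, function(id) {
    sub <- dt[dt$interface == id, ]
    m <- matrix(NA_real_, meta$n_bscans, meta$n_ascans)
    m[cbind(sub$bscan, sub$ascan)] <- sub$row
    m
  }), ids)
  boundary_set(rows, meta)
}

#' Read correction polylines
#'
#' CSV columns `bscan, interface, x, row` (one vertex per line) or JSON
#' array of objects `{bscan, interface, vertices: [[x, row], ...]}`.
#'
#' @param path Polyline file path.
#' @return List of corrections, each a list with `bscan`, `interface` and a
#'   two-column `vertices` matrix `(x, row)`.
#' @export
read_polylines <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(obj, function(o) list(
      bscan = as.integer(o$bscan),
      interface = match_interface(o$interface),
      vertices = do.call(rbind, lapply(o$vertices, unlist)))))
  }
  dt <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bscan", "interface", "x", "row")
  if (!all(need %in% names(dt)))
    stop("polyline CSV must have columns bscan, interface, x, row", call. = FALSE)
  keys <- unique(dt[c("bscan", "interface")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- dt[dt$bscan == keys$bscan[i] & dt$interface == keys$interface[i], ]
    list(bscan = as.integer(keys$bscan[i]),
         interface = match_interface(keys$interface[i]),
         vertices = cbind(x = sub$x, row = sub$row))
  })
}

#' Write an enface map as CSV (plus JSON sidecar)
#'
#' The CSV holds the bare `(n_bscans x n_ascans)` value grid (`NA` where
#' invalid); the sidecar `<path>.json` records kind, layer, units and scan
#' metadata.
#'
#' @param map An [enface_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_enface_csv <- function(map, path) {
  stopifnot(inherits(map, "enface_map"))
  data.table::fwrite(data.table::as.data.table(map$values), path,
                     col.names = FALSE)
  jsonlite::write_json(
    list(kind = map$kind, layer = map$layer,
         units = if (map$kind == "thickness_um") "um" else "normalized [0,1]",
         meta = meta_to_list(map$meta)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an enface map written by [write_enface_csv()]
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return An [enface_map()].
#' @export
read_enface_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(v) <- NULL
  enface_map(v, kind = side$kind, layer = side$layer,
             meta = meta_from_list(side$meta))
}

#' Write an enface map as a 32-bit float TIFF
#'
#' Single-page float32 TIFF of the value grid (invalid pixels as NaN), with
#' a JSON sidecar as in [write_enface_csv()].
#'
#' @param map An [enface_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_enface_tiff <- function(map, path) {
  stopifnot(inherits(map, "enface_map"))
  v <- map$values
  v[!map$valid] <- NaN
  write_tiff(v, path, type = "float32")
  jsonlite::write_json(
    list(kind = map$kind, layer = map$layer,
         units = if (map$kind == "thickness_um") "um" else "normalized [0,1]",
         meta = meta_to_list(map$meta)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Grayscale preview of an enface map (plain-text PGM)
#'
#' Min-max scaled to 0..255 over valid pixels (invalid pixels black), with
#' the scale bounds recorded in `<path>.json` (the color-bar bounds).
#'
#' @param map An [enface_map()].
#' @param path Output path (`.pgm`).
#' @return `path`, invisibly.
#' @export
write_map_preview <- function(map, path) {
  stopifnot(inherits(map, "enface_map"))
  v <- map$values
  rng <- range(v[map$valid])
  span <- if (diff(rng) > 0) diff(rng) else 1
  g <- round(255 * (v - rng[1]) / span)
  g[!map$valid] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(g), nrow(g)), "255"), con)
  write(t(g), con, ncolumns = ncol(g))
  jsonlite::write_json(list(scale_min = rng[1], scale_max = rng[2],
                            layer = map$layer, kind = map$kind),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

deviation_codes <- c(invalid = 0L, below = 1L, within = 2L, above = 3L)

#' Write a deviation map (plain-text PPM + integer-label CSV)
#'
#' The PPM (P3) uses the fixed palette: below = blue, within = green,
#' above = red, invalid = gray.  The CSV holds integer labels
#' (0 invalid, 1 below, 2 within, 3 above); the legend is recorded in
#' `<csv_path>.json`.
#'
#' @param dm A [deviation_map()].
#' @param ppm_path Output PPM path (`NULL` to skip).
#' @param csv_path Output CSV path (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_deviation_map <- function(dm, ppm_path = NULL, csv_path = NULL) {
  stopifnot(inherits(dm, "deviation_map"))
  if (!is.null(ppm_path)) {
    pal <- deviation_palette()
    lab <- dm$labels
    rgb <- array(0L, c(nrow(lab), ncol(lab), 3L))
    for (nm in names(pal)) {
      m <- lab == nm
      for (c3 in 1:3) {
        plane <- rgb[, , c3]
        plane[m] <- pal[[nm]][c3]
        rgb[, , c3] <- plane
      }
    }
    con <- file(ppm_path, "w")
    writeLines(c("P3", sprintf("%d %d", ncol(lab), nrow(lab)), "255"), con)
    # interleave R,G,B per pixel, row by row
    flat <- matrix(0L, nrow(lab), 3L * ncol(lab))
    flat[, seq(1, 3 * ncol(lab), 3)] <- rgb[, , 1]
    flat[, seq(2, 3 * ncol(lab), 3)] <- rgb[, , 2]
    flat[, seq(3, 3 * ncol(lab), 3)] <- rgb[, , 3]
    write(t(flat), con, ncolumns = 15)
    close(con)
  }
  if (!is.null(csv_path)) {
    codes <- matrix(deviation_codes[dm$labels], nrow(dm$labels))
    data.table::fwrite(data.table::as.data.table(codes), csv_path,
                       col.names = FALSE)
    jsonlite::write_json(list(legend = as.list(deviation_codes),
                              layer = dm$layer),
                         paste0(csv_path, ".json"), auto_unbox = TRUE)
  }
  invisible(c(ppm_path, csv_path))
}

#' Run configuration
#'
#' JSON run configuration: graph parameters, metadata overrides, atlas
#' coverage, output directory, seed, verbosity.  Unknown keys are
#' rejected.
#'
#' @param path JSON config path.
#' @return List with validated elements `params` ([graph_params()]),
#'   `meta_overrides`, `coverage`, `outdir`, `seed`, `quiet`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("w_min", "smooth_sigma", "max_step", "exclude_margin",
             "correction_halfwidth", "meta", "coverage", "outdir", "seed",
             "quiet")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  gp_args <- cfg[intersect(names(cfg),
                           c("w_min", "smooth_sigma", "max_step",
                             "exclude_margin", "correction_halfwidth"))]
  params <- do.call(graph_params, gp_args)
  coverage <- if (is.null(cfg$coverage)) 0.95 else cfg$coverage
  if (coverage <= 0 || coverage >= 1)
    stop("coverage must lie in (0, 1)", call. = FALSE)
  list(params = params,
       meta_overrides = cfg$meta,
       coverage = coverage,
       outdir = cfg$outdir,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       quiet = isTRUE(cfg$quiet))
}

#' Write all pipeline products plus a manifest
#'
#' Writes, under `outdir`: per-layer thickness and reflectance maps (float
#' TIFF + CSV + PGM preview), the boundary tables (CSV + JSON), any
#' deviation maps (PPM + CSV), and `manifest.json` recording inputs,
#' configuration, seed, package version and an MD5 checksum per file.
#'
#' @param products Output of [all_enface_products()] (or `NULL`).
#' @param boundaries A [boundary_set()] (or `NULL`).
#' @param deviations Named list of [deviation_map()]s (or `NULL`).
#' @param outdir Output directory (created if needed).
#' @param config Arbitrary configuration list echoed into the manifest.
#' @param seed Seed echoed into the manifest.
#' @return The manifest, invisibly.
#' @export
write_products <- function(products = NULL, boundaries = NULL,
                           deviations = NULL, outdir, config = list(),
                           seed = NA_integer_) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(f) files <<- c(files, f)
  if (!is.null(products)) {
    for (grp in c("thickness", "reflectance")) {
      for (layer in names(products[[grp]])) {
        m <- products[[grp]][[layer]]
        base <- file.path(outdir, sprintf("%s_%s", tolower(layer), grp))
        add(write_enface_csv(m, paste0(base, ".csv")))
        add(write_enface_tiff(m, paste0(base, ".tif")))
        add(write_map_preview(m, paste0(base, ".pgm")))
      }
    }
  }
  if (!is.null(boundaries)) {
    add(write_boundaries(boundaries, file.path(outdir, "boundaries.csv")))
    add(write_boundaries(boundaries, file.path(outdir, "boundaries.json")))
  }
  if (!is.null(deviations)) {
    for (nm in names(deviations)) {
      base <- file.path(outdir, sprintf("%s_deviation", tolower(nm)))
      write_deviation_map(deviations[[nm]], paste0(base, ".ppm"),
                          paste0(base, ".csv"))
      add(paste0(base, ".ppm")); add(paste0(base, ".csv"))
    }
  }
  manifest <- list(
    software = "octlayers",
    version = as.character(utils::packageVersion("octlayers")),
    seed = seed, config = config,
    files = lapply(setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(outdir, f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a normative atlas directory
#'
#' Four float32 TIFF maps (`mean`, `sd`, `lower`, `upper`; invalid pixels
#' NaN) plus `atlas.json` (subject count, coverage, limit type, layer,
#' scan metadata).
#'
#' @param atlas A [build_atlas()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "normative_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("mean", "sd", "lower", "upper")) {
    v <- atlas[[nm]]
    v[!atlas$valid] <- NaN
    write_tiff(v, file.path(dir, paste0(nm, ".tif")), type = "float32")
  }
  jsonlite::write_json(
    list(n_subjects = atlas$n_subjects, coverage = atlas$coverage,
         limits = atlas$limits, layer = atlas$layer,
         units = "um", meta = meta_to_list(atlas$meta)),
    file.path(dir, "atlas.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' Read a normative atlas directory written by [write_atlas()]
#'
#' @param dir Atlas directory.
#' @return A `normative_atlas` (maps in float32 precision).
#' @export
read_atlas <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  maps <- lapply(c(mean = "mean", sd = "sd", lower = "lower", upper = "upper"),
                 function(nm) read_tiff(file.path(dir, paste0(nm, ".tif")))$pages[[1]])
  valid <- is.finite(maps$mean) & is.finite(maps$sd)
  for (nm in names(maps)) maps[[nm]][!valid] <- NA_real_
  structure(list(mean = maps$mean, sd = maps$sd, lower = maps$lower,
                 upper = maps$upper, valid = valid,
                 n_subjects = side$n_subjects, coverage = side$coverage,
                 limits = side$limits, layer = side$layer,
                 meta = meta_from_list(side$meta)),
            class = "normative_atlas")
}
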