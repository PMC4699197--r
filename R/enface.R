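# Enface (C-scan) products: per-layer thickness maps and vertically
# averaged reflectance images, one enface row per B-scan.

#' Layer definitions for enface mapping
#'
#' The four reported layers and their bounding interfaces: total retina
#' (TR, vitreous/ILM to RPE/choroid), inner retina (IR, vitreous/ILM to
#' INL/OPL), outer retina (OR, INL/OPL to RPE/choroid) and the inner
#' segment ellipsoid band (ISE, ONL/ISe to ISe/RPE).  Because IR and OR
#' share the INL/OPL interface, TR = IR + OR holds identically for
#' thickness.
#'
#' @return Data frame with columns `layer`, `upper`, `lower`.
#' @export
layer_definitions <- function() {
  data.frame(
    layer = c("TR", "IR", "OR", "ISE"),
    upper = c("VITREOUS_ILM", "VITREOUS_ILM", "INL_OPL", "ONL_ISE"),
    lower = c("RPE_CHOROID", "INL_OPL", "RPE_CHOROID", "ISE_RPE"),
    stringsAsFactors = FALSE)
}

layer_interfaces <- function(layer) {
  defs <- layer_definitions()
  i <- match(layer, defs$layer)
  if (is.na(i)) stop(sprintf("unknown layer tag '%s'", layer), call. = FALSE)
  defs[i, ]
}

#' Enface thickness map of one layer
#'
#' Thickness at each (B-scan, A-scan) position is the depth separation of
#' the layer's two bounding interfaces, converted to micrometres:
#' `(lower_row - upper_row) * axial_um_per_px`.  Boundary rows are used at
#' full (possibly sub-pixel) precision.  A pixel is valid only where the
#' boundary set is valid.
#'
#' @param bs A [boundary_set()].
#' @param layer `"TR"`, `"IR"`, `"OR"` or `"ISE"`.
#' @param axial_um_per_px Axial sampling; defaults to the boundary set's
#'   metadata.
#' @return An [enface_map()] of kind `"thickness_um"`.
#' @export
thickness_map <- function(bs, layer, axial_um_per_px = bs$meta$axial_um_per_px) {
  stopifnot(inherits(bs, "boundary_set"))
  def <- layer_interfaces(layer)
  values <- (bs$rows[[def$lower]] - bs$rows[[def$upper]]) * axial_um_per_px
  enface_map(values, kind = "thickness_um", layer = def$layer,
             meta = bs$meta, valid = bs$valid)
}

#' Enface reflectance image of one layer
#'
#' At each (B-scan, A-scan) position, averages the volume intensity
#' vertically across the layer's row band; each B-scan contributes exactly
#' one row of the enface image.  The band is half-open,
#' `[round(upper), round(lower))`, so the interface shared by IR and OR is
#' never counted twice; a degenerate (empty) band falls back to the single
#' pixel at the rounded upper row.  Averaging is done on the linear
#' normalized intensity.
#'
#' @param vol An [oct_volume()].
#' @param bs A [boundary_set()] on the same grid.
#' @param layer `"TR"`, `"IR"`, `"OR"` or `"ISE"`.
#' @return An [enface_map()] of kind `"reflectance"`.
#' @export
reflectance_image <- function(vol, bs, layer) {
  stopifnot(inherits(vol, "oct_volume"), inherits(bs, "boundary_set"))
  meta <- vol$meta
  if (!identical(c(meta$n_bscans, meta$n_ascans),
                 c(bs$meta$n_bscans, bs$meta$n_ascans)))
    stop("volume and boundary set grids do not match", call. = FALSE)
  def <- layer_interfaces(layer)
  upper <- round(bs$rows[[def$upper]])
  lower <- round(bs$rows[[def$lower]])
  bad <- bs$valid & (upper < 1 | lower > meta$n_depth + 1 | upper > meta$n_depth)
  if (any(bad))
    stop("layer band extends outside the depth range", call. = FALSE)
  values <- matrix(NA_real_, meta$n_bscans, meta$n_ascans)
  depth <- seq_len(meta$n_depth)
  for (y in seq_len(meta$n_bscans)) {
    if (!any(bs$valid[y, ])) next
    bsc <- get_bscan(vol, y)
    up <- upper[y, ]; lo <- lower[y, ]
    # cumulative sums down each A-scan give O(1) band means per column
    cs <- rbind(0, apply(bsc, 2L, cumsum))
    for (x in which(bs$valid[y, ])) {
      a <- up[x]; b <- lo[x]
      values[y, x] <- if (b > a) (cs[b, x] - cs[a, x]) / (b - a) else bsc[a, x]
    }
  }
  enface_map(values, kind = "reflectance", layer = def$layer,
             meta = meta, valid = bs$valid)
}

#' All eight enface products of a segmented volume
#'
#' Computes the thickness map and reflectance image of each of the four
#' layers (TR, IR, OR, ISE).
#'
#' @param vol An [oct_volume()].
#' @param bs A [boundary_set()] on the same grid.
#' @return List with elements `thickness` and `reflectance`, each a named
#'   list of four [enface_map()]s.
#' @export
all_enface_products <- function(vol, bs) {
  layers <- layer_definitions()$layer
  list(
    thickness = setNames(lapply(layers, function(l) thickness_map(bs, l)), layers),
    reflectance = setNames(lapply(layers, function(l) reflectance_image(vol, bs, l)), layers))
}
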