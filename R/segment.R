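# Shortest-path boundary extraction and the ordered five-interface
# protocol.  Each B-scan is treated as a graph whose nodes are pixels and
# whose edge weights fall with the vertical gradient magnitude of the
# requested polarity; a column-monotone minimum-weight path then traces the
# strongest layer transition.  Interfaces are found in a fixed order, each
# search restricted relative to the paths already found.

#' Graph-search parameters
#'
#' Tunable constants of the boundary search.
#'
#' @param w_min Positive edge-weight floor added to every weight so that all
#'   weights stay strictly positive (default `1e-5`).
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels applied to each
#'   B-scan before gradients (default 1; 0 disables).
#' @param max_step Maximum allowed |row change| between adjacent columns of a
#'   path, pixels (default 5).
#' @param exclude_margin Offset in pixels applied when restricting the search
#'   region below / between already-found paths, preventing re-detection of
#'   the same transition (default 3).
#' @param correction_halfwidth Half-width in pixels of the band searched
#'   around a manually drawn correction polyline (default 5).
#' @return An object of class `graph_params`.
#' @export
graph_params <- function(w_min = 1e-5, smooth_sigma = 1, max_step = 5L,
                         exclude_margin = 3L, correction_halfwidth = 5L) {
  stopifnot(w_min > 0, smooth_sigma >= 0, max_step >= 1, exclude_margin >= 0,
            correction_halfwidth >= 0)
  structure(list(w_min = w_min, smooth_sigma = smooth_sigma,
                 max_step = as.integer(max_step),
                 exclude_margin = as.integer(exclude_margin),
                 correction_halfwidth = as.integer(correction_halfwidth)),
            class = "graph_params")
}

#' @export
print.graph_params <- function(x, ...) {
  cat(sprintf(
    "graph_params: w_min=%g, smooth_sigma=%g px, max_step=%d px, exclude_margin=%d px, correction_halfwidth=%d px\n",
    x$w_min, x$smooth_sigma, x$max_step, x$exclude_margin,
    x$correction_halfwidth))
  invisible(x)
}

#' Per-column search region
#'
#' The rows a boundary path may occupy in each column, as inclusive 1-based
#' bounds `[min_row, max_row]`.  Scalar bounds are recycled across columns.
#'
#' @param min_row,max_row Integer vectors (or scalars) of row bounds,
#'   `1 <= min_row <= max_row <= n_depth`.
#' @param n_cols Number of columns (A-scans).
#' @param n_depth Number of depth rows, for validation.
#' @return An object of class `search_region`: list of integer vectors
#'   `min_row`, `max_row`, each of length `n_cols`.
#' @export
search_region <- function(min_row, max_row, n_cols, n_depth) {
  min_row <- as.integer(round(rep_len(min_row, n_cols)))
  max_row <- as.integer(round(rep_len(max_row, n_cols)))
  if (any(min_row < 1L) || any(max_row > n_depth) || any(min_row > max_row))
    stop("infeasible search region: need 1 <= min_row <= max_row <= n_depth in every column",
         call. = FALSE)
  structure(list(min_row = min_row, max_row = max_row), class = "search_region")
}

#' Minimum-weight column-monotone path through a normalized gradient image
#'
#' Low-level solver: finds the path (one row per column, |row step| bounded)
#' minimizing the summed edge weights `2 - (g_a + g_b) + w_min`, with free
#' endpoints.  Ties are broken deterministically: smallest total row sum,
#' then topmost row at the first differing column.  Exposed so callers and
#' tests can verify paths against exhaustive enumeration.
#'
#' @param g Normalized gradient matrix (depth rows x columns), values in
#'   `[0, 1]` (see [normalized_gradient()]).
#' @param region A [search_region()], or `NULL` for the full image.
#' @param max_step Maximum |row change| per column transition.
#' @param w_min Edge-weight floor.
#' @return List with `path` (integer vector of 1-based rows, one per column)
#'   and `cost` (total path weight; 0 for a single-column image).
#' @export
min_weight_path <- function(g, region = NULL, max_step = 5L, w_min = 1e-5) {
  stopifnot(is.matrix(g))
  if (is.null(region))
    region <- search_region(1L, nrow(g), ncol(g), nrow(g))
  stopifnot(inherits(region, "search_region"),
            length(region$min_row) == ncol(g))
  res <- .dp_path(g, region$min_row - 1L, region$max_row, # 0-based half-open
                  as.integer(max_step), as.numeric(w_min))
  list(path = res$path + 1L, cost = res$cost)
}

#' Extract one layer boundary from a B-scan
#'
#' Computes the signed vertical gradient, rectifies and normalizes it for
#' the requested polarity, and returns the minimum-weight column-monotone
#' path through the resulting weight graph.
#'
#' @param bscan Numeric matrix (depth rows x A-scans), values in `[0, 1]`.
#' @param polarity `"DARK_TO_BRIGHT"` or `"BRIGHT_TO_DARK"`.
#' @param region A [search_region()] restricting the rows searched, or
#'   `NULL` for the whole image.
#' @param params A [graph_params()] object.
#' @return Integer vector of boundary rows (1-based), one per column, with
#'   attribute `cost` (total path weight).
#' @export
shortest_path_boundary <- function(bscan, polarity = polarities(),
                                   region = NULL, params = graph_params()) {
  polarity <- match_polarity(polarity)
  grad <- vertical_gradient(bscan, params$smooth_sigma)
  g <- normalized_gradient(grad, polarity)
  res <- min_weight_path(g, region, params$max_step, params$w_min)
  structure(res$path, cost = res$cost)
}

# Region strictly below a found path, offset by the exclusion margin.
# Clamped so that at least one row remains in every column.
region_below <- function(path, margin, n_depth, n_cols) {
  lo <- pmin(as.integer(path) + margin, n_depth)
  search_region(lo, n_depth, n_cols, n_depth)
}

# Region between two found paths, inset by the exclusion margin on both
# sides.  Where the inset bounds cross (bands thinner than 2*margin, e.g. a
# shallow fovea), the region collapses to the single midpoint row, which
# preserves both feasibility and depth ordering.
region_between <- function(upper, lower, margin, n_depth, n_cols) {
  lo <- as.integer(upper) + margin
  hi <- as.integer(lower) - margin
  crossed <- lo > hi
  if (any(crossed)) {
    mid <- as.integer(floor((as.integer(upper) + as.integer(lower)) / 2))
    lo[crossed] <- mid[crossed]
    hi[crossed] <- mid[crossed]
  }
  search_region(pmax(lo, 1L), pmin(hi, n_depth), n_cols, n_depth)
}

#' Segment the five retinal interfaces in one B-scan
#'
#' Runs the ordered protocol: (1) the vitreous/ILM interface is found first
#' as the strongest dark-to-bright transition over the whole image; (2) the
#' ONL/ISe interface is found below the vitreous/ILM path; (3) the
#' RPE/choroid interface is found below the ONL/ISe path as a bright-to-dark
#' transition; (4) the INL/OPL interface is found between the vitreous/ILM
#' and ONL/ISe paths; (5) the ISe/RPE interface is found between the ONL/ISe
#' and RPE/choroid paths (bright-to-dark: the hyper-reflective ISe band ends
#' above a darker zone).  Each restriction is offset by
#' `params$exclude_margin` so a search cannot re-detect the transition just
#' found.  The construction guarantees the anatomical depth ordering per
#' column.
#'
#' @param bscan Numeric matrix (depth rows x A-scans), values in `[0, 1]`.
#' @param params A [graph_params()] object.
#' @return Named list of five integer row vectors (one per interface id, in
#'   anatomical order).
#' @export
segment_five_interfaces <- function(bscan, params = graph_params()) {
  stopifnot(is.matrix(bscan))
  n_depth <- nrow(bscan)
  n_cols <- ncol(bscan)
  margin <- params$exclude_margin
  if (n_depth < 2L * margin + 5L)
    stop("image too shallow to host the exclusion margins", call. = FALSE)

  grad <- vertical_gradient(bscan, params$smooth_sigma)
  g_pos <- normalized_gradient(grad, "DARK_TO_BRIGHT")
  g_neg <- normalized_gradient(grad, "BRIGHT_TO_DARK")
  solve <- function(g, region) {
    min_weight_path(g, region, params$max_step, params$w_min)$path
  }

  ilm <- solve(g_pos, NULL)
  onl_ise <- solve(g_pos, region_below(ilm, margin, n_depth, n_cols))
  rpe_cho <- solve(g_neg, region_below(onl_ise, margin, n_depth, n_cols))
  inl_opl <- solve(g_pos, region_between(ilm, onl_ise, margin, n_depth, n_cols))
  ise_rpe <- solve(g_neg, region_between(onl_ise, rpe_cho, margin, n_depth, n_cols))

  list(VITREOUS_ILM = ilm, INL_OPL = inl_opl, ONL_ISE = onl_ise,
       ISE_RPE = ise_rpe, RPE_CHOROID = rpe_cho)
}

#' Segment every B-scan of a volume
#'
#' Applies [segment_five_interfaces()] independently to each B-scan and
#' assembles the results into a [boundary_set()].  A B-scan whose
#' segmentation fails (e.g. infeasible search regions) is logged via
#' `warning()` and marked invalid rather than aborting the volume.
#'
#' @param vol An [oct_volume()].
#' @param params A [graph_params()] object.
#' @return A [boundary_set()] on the volume's `(n_bscans, n_ascans)` grid.
#' @export
segment_volume <- function(vol, params = graph_params()) {
  stopifnot(inherits(vol, "oct_volume"))
  meta <- vol$meta
  ids <- interface_ids()
  rows <- setNames(lapply(ids, function(i)
    matrix(NA_real_, meta$n_bscans, meta$n_ascans)), ids)
  valid <- matrix(FALSE, meta$n_bscans, meta$n_ascans)
  for (y in seq_len(meta$n_bscans)) {
    paths <- tryCatch(segment_five_interfaces(get_bscan(vol, y), params),
                      error = function(e) e)
    if (inherits(paths, "error")) {
      warning(sprintf("B-scan %d: segmentation failed (%s); marked invalid",
                      y, conditionMessage(paths)), call. = FALSE)
      next
    }
    for (id in ids) rows[[id]][y, ] <- paths[[id]]
    valid[y, ] <- TRUE
  }
  boundary_set(rows, meta, valid = valid)
}

#' Apply a band-restricted manual correction to a boundary path
#'
#' Emulates the operator workflow for fixing a locally wrong boundary: the
#' drawn polyline is linearly interpolated to every column it spans, the
#' search region is restricted to a narrow vertical band around the drawn
#' line (`round(line) +/- correction_halfwidth`), a new minimum-weight path
#' is computed inside that band, and the revised segment is spliced into the
#' current path.  Columns outside the polyline's x-range are never changed.
#'
#' @param bscan Numeric matrix (depth rows x A-scans), values in `[0, 1]`.
#' @param path Current boundary path (integer rows, one per column).
#' @param polyline Two-column matrix or data frame of vertices `(x, row)`
#'   spanning a contiguous x-range; need not be sorted.
#' @param polarity Interface polarity used for the re-search.
#' @param params A [graph_params()] object (`correction_halfwidth` sets the
#'   band half-width; 0 forces the path onto the rounded drawn line).
#' @return The revised path (integer vector, same length as `path`).
#' @export
apply_manual_correction <- function(bscan, path, polyline,
                                    polarity = polarities(),
                                    params = graph_params()) {
  polarity <- match_polarity(polarity)
  stopifnot(is.matrix(bscan), length(path) == ncol(bscan))
  polyline <- as.data.frame(polyline)
  if (ncol(polyline) < 2L || nrow(polyline) < 1L)
    stop("polyline must have vertices (x, row)", call. = FALSE)
  names(polyline)[1:2] <- c("x", "row")
  if (any(polyline$x < 1 | polyline$x > ncol(bscan)) ||
      any(polyline$row < 1 | polyline$row > nrow(bscan)))
    stop("polyline vertices outside the image", call. = FALSE)
  polyline <- polyline[order(polyline$x), , drop = FALSE]

  xs <- seq.int(ceiling(min(polyline$x)), floor(max(polyline$x)))
  interp <- if (nrow(polyline) == 1L) rep(polyline$row, length(xs)) else
    approx(polyline$x, polyline$row, xout = xs, ties = mean)$y
  hw <- params$correction_halfwidth
  lo <- pmax(1L, as.integer(round(interp)) - hw)
  hi <- pmin(nrow(bscan), as.integer(round(interp)) + hw)

  grad <- vertical_gradient(bscan, params$smooth_sigma)
  g <- normalized_gradient(grad, polarity) # normalized over the full B-scan
  region <- search_region(lo, hi, length(xs), nrow(bscan))
  revised <- min_weight_path(g[, xs, drop = FALSE], region,
                             params$max_step, params$w_min)$path
  out <- as.integer(path)
  out[xs] <- revised
  out
}
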