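# Per-pixel normative atlases from control thickness maps, and tri-level
# deviation maps classifying a patient map against the normal range.

#' Build a per-pixel normative atlas from control thickness maps
#'
#' For every enface pixel, computes across subjects (using only subjects
#' with that pixel valid): the mean, the sample standard deviation (n-1
#' denominator), and normal-range limits `mean +/- z * SD`, where `z` is the
#' two-sided standard-normal quantile for the requested coverage (1.960 for
#' 0.95).  The limits describe the normal population range of individual
#' subjects — the interval a healthy subject's pixel falls in with the
#' nominal probability — which is what classifying individual patients
#' requires.  Set `limits = "mean_ci"` for the alternative reading (the CI
#' of the cohort mean, `mean +/- z * SD / sqrt(n)`).
#'
#' Pixels valid in fewer than 2 subjects are invalid in the atlas.
#'
#' @param maps List (length >= 2) of thickness [enface_map()]s with
#'   identical grids and layer tags.
#' @param coverage Two-sided coverage of the normal range (default 0.95).
#' @param limits `"population"` (default) or `"mean_ci"`.
#' @return An object of class `normative_atlas`: matrices `mean`, `sd`,
#'   `lower`, `upper`, logical `valid`, plus `n_subjects`, `coverage`,
#'   `layer`, `meta`.
#' @export
build_atlas <- function(maps, coverage = 0.95,
                        limits = c("population", "mean_ci")) {
  limits <- match.arg(limits)
  if (!is.list(maps) || length(maps) < 2L)
    stop("need at least 2 control maps to build an atlas", call. = FALSE)
  if (!all(vapply(maps, inherits, logical(1), "enface_map")))
    stop("maps must be enface_map objects", call. = FALSE)
  if (!all(vapply(maps, function(m) m$kind, character(1)) == "thickness_um"))
    stop("atlas input maps must be thickness maps", call. = FALSE)
  layers <- unique(vapply(maps, function(m) m$layer, character(1)))
  if (length(layers) != 1L)
    stop("mixed layer tags in atlas input", call. = FALSE)
  dims <- unique(lapply(maps, function(m) dim(m$values)))
  if (length(dims) != 1L)
    stop("atlas input maps have mismatched grids", call. = FALSE)
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must lie in (0, 1)", call. = FALSE)

  n <- length(maps)
  d <- dims[[1]]
  vals <- array(NA_real_, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    v <- maps[[i]]$values
    v[!maps[[i]]$valid] <- NA_real_
    vals[, , i] <- v
  }
  cnt <- apply(!is.na(vals), c(1, 2), sum)
  mu <- apply(vals, c(1, 2), mean, na.rm = TRUE)
  s <- apply(vals, c(1, 2), sd, na.rm = TRUE)
  valid <- cnt >= 2L
  mu[!valid] <- NA_real_
  s[!valid] <- NA_real_

  z <- qnorm(1 - (1 - coverage) / 2)
  half <- if (limits == "population") z * s else z * s / sqrt(cnt)
  structure(list(mean = mu, sd = s, lower = mu - half, upper = mu + half,
                 valid = valid, n_subjects = n, coverage = coverage,
                 limits = limits, layer = layers, meta = maps[[1]]$meta),
            class = "normative_atlas")
}

#' @export
print.normative_atlas <- function(x, ...) {
  cat(sprintf(
    "normative_atlas [%s]: %d x %d grid, %d subjects, %.0f%% %s limits, %d/%d pixels valid\n",
    x$layer, nrow(x$mean), ncol(x$mean), x$n_subjects, 100 * x$coverage,
    if (x$limits == "population") "population" else "mean-CI",
    sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Classify a patient thickness map against a normative atlas
#'
#' Labels every pixel `below` (value < lower limit), `above`
#' (value > upper limit) or `within` (boundary values inclusive).  Pixels
#' invalid in either input are `invalid`.  The conventional rendering
#' palette is blue / green / red for below / within / above and gray for
#' invalid.
#'
#' @param patient A thickness [enface_map()] on the atlas grid, same layer.
#' @param atlas A [build_atlas()] result.
#' @return An object of class `deviation_map`: a character matrix `labels`
#'   with values in `below/within/above/invalid`, plus `layer` and `meta`.
#' @export
deviation_map <- function(patient, atlas) {
  stopifnot(inherits(patient, "enface_map"), inherits(atlas, "normative_atlas"))
  if (patient$kind != "thickness_um")
    stop("patient map must be a thickness map", call. = FALSE)
  if (patient$layer != atlas$layer)
    stop(sprintf("layer mismatch: patient '%s' vs atlas '%s'",
                 patient$layer, atlas$layer), call. = FALSE)
  if (!identical(dim(patient$values), dim(atlas$mean)))
    stop("patient and atlas grids do not match", call. = FALSE)
  valid <- patient$valid & atlas$valid
  labels <- matrix("invalid", nrow(valid), ncol(valid))
  v <- patient$values
  labels[valid & (v < atlas$lower)] <- "below"
  labels[valid & (v > atlas$upper)] <- "above"
  labels[valid & (v >= atlas$lower) & (v <= atlas$upper)] <- "within"
  structure(list(labels = labels, layer = patient$layer, meta = patient$meta),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("below", "within", "above", "invalid")))
  cat(sprintf("deviation_map [%s]: %d x %d — below %d, within %d, above %d, invalid %d\n",
              x$layer, nrow(x$labels), ncol(x$labels),
              tab["below"], tab["within"], tab["above"], tab["invalid"]))
  invisible(x)
}

#' Fixed rendering palette of deviation labels
#'
#' @return Named list of RGB triplets (0-255) for below (blue), within
#'   (green), above (red) and invalid (gray).
#' @export
deviation_palette <- function() {
  list(below = c(0L, 0L, 255L), within = c(0L, 255L, 0L),
       above = c(255L, 0L, 0L), invalid = c(128L, 128L, 128L))
}

#' Simulate thickness maps from a per-pixel Gaussian model
#'
#' Draws `n` independent maps whose pixel `(y, x)` is
#' `N(mean_map[y,x], sd_map[y,x])`, truncated at 0 (thickness cannot be
#' negative).  Used for Monte-Carlo checks of the atlas coverage.
#'
#' @param n Number of maps.
#' @param mean_map,sd_map Numeric matrices of the generating parameters (um).
#' @param layer Layer tag for the simulated maps.
#' @param meta A [scan_metadata()] whose grid matches `mean_map`; defaults to
#'   a minimal metadata object of the right grid size.
#' @param seed Optional integer seed.
#' @return List of `n` thickness [enface_map()]s.
#' @export
simulate_gaussian_maps <- function(n, mean_map, sd_map, layer = "TR",
                                   meta = NULL, seed = NULL) {
  stopifnot(is.matrix(mean_map), identical(dim(mean_map), dim(sd_map)), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(meta))
    meta <- scan_metadata(n_bscans = nrow(mean_map), n_ascans = ncol(mean_map),
                          n_depth = 8L)
  lapply(seq_len(n), function(i) {
    v <- matrix(rnorm(length(mean_map), mean_map, sd_map), nrow(mean_map))
    enface_map(pmax(v, 0), kind = "thickness_um", layer = layer, meta = meta)
  })
}

#' Pooled within-limits fraction of fresh maps under an atlas
#'
#' Classifies each supplied map with [deviation_map()] and returns the
#' pooled fraction of valid pixels labelled `within`.  When the fresh maps
#' are drawn from the same per-pixel Gaussian used to build the atlas, this
#' fraction converges to the atlas coverage as the cohort and map counts
#' grow.
#'
#' @param atlas A [build_atlas()] result.
#' @param fresh_maps List of thickness [enface_map()]s.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_check <- function(atlas, fresh_maps) {
  counts <- vapply(fresh_maps, function(m) {
    lab <- deviation_map(m, atlas)$labels
    c(within = sum(lab == "within"), valid = sum(lab != "invalid"))
  }, numeric(2))
  sum(counts["within", ]) / sum(counts["valid", ])
}
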