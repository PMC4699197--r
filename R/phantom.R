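# Deterministic synthetic SDOCT phantom: layered macular anatomy with a
# foveal pit, speckle, exported ground-truth boundaries, and diabetic
# retinopathy pathology injectors.  Stands in for patient data in every
# test: no clinical volumes ship with the package.
#
# The axial band structure mirrors the contrast relations of real SDOCT
# macular scans that make the ordered segmentation protocol well-posed:
# dark vitreous over a bright inner-retina surface (the strongest
# dark-to-bright step), an inner retina fading to the dark INL, a thin
# bright OPL strip below the INL/OPL interface, a dark ONL, the
# hyper-reflective ISe band, a darker interdigitation gap, the brightest
# RPE band (whose lower edge is the strongest bright-to-dark step), and a
# medium choroid.

#' Synthetic phantom specification
#'
#' All anatomical dimensions are in micrometres and converted to pixels via
#' the metadata's axial sampling; the foveal pit is an anisotropic 2-D
#' Gaussian centred on the grid.  Defaults approximate normal macular
#' anatomy: ~340 um total retina with a ~78 um foveal depression carried by
#' the inner interfaces, central inner-retina thinning, and central OR/ISe
#' thickening.
#'
#' @param meta A [scan_metadata()]; defaults to the high-density profile.
#' @param ilm_depth_um Baseline depth of the vitreous/ILM interface below
#'   the image top (default 30% of the image depth).
#' @param ir_um,onl_um,ise_um,rpe_um Baseline band separations (um):
#'   vitreous/ILM to INL/OPL, INL/OPL to ONL/ISe, ONL/ISe to ISe/RPE,
#'   ISe/RPE to RPE/choroid.
#' @param pit_depth_um Foveal dip of the vitreous/ILM interface.
#' @param pit_inl_rise_um Central rise of the INL/OPL interface.  The pit
#'   is carried almost entirely by the vitreous/ILM surface; a slight
#'   INL/OPL rise yields both central inner-retina thinning and the
#'   central outer-retina thickening of normal maps, while keeping the
#'   foveal inner-retina band thicker than the rendering blur so every
#'   interface stays resolvable.
#' @param pit_onl_um Weak central dip of the ONL/ISe interface.
#' @param ise_thicken_um Central increase of the ONL/ISe to ISe/RPE
#'   separation (foveal ISe thickening).
#' @param pit_sigma_um Lateral (isotropic, in retinal um) Gaussian sigma of
#'   all foveal terms.
#' @param intensities Named list of band reflectivities in `[0, 1]`:
#'   `vitreous`, `rnfl_top` (a flat bright RNFL strip caps the inner
#'   retina, making the vitreous/ILM step the strongest dark-to-bright
#'   transition, as in real scans), `inl_bottom` (below the RNFL strip the
#'   inner retina ramps from `rnfl_top` down to `inl_bottom`), `opl`,
#'   `onl`, `ise`, `iz` (interdigitation gap), `rpe`, `choroid`.
#' @param rnfl_um Thickness of the flat bright strip below vitreous/ILM.
#' @param opl_um Thickness of the bright OPL strip below INL/OPL.
#' @param iz_um Thickness of the interdigitation gap below ISe/RPE.
#' @param transition_sigma_px Axial Gaussian scale of interface transitions.
#' @param speckle Relative standard deviation of the multiplicative speckle
#'   (unit-mean gamma; default 0.25, i.e. gamma shape 16, approximating
#'   9-frame averaging; 0 disables).
#' @param seed Integer RNG seed recorded in the spec and used for all
#'   randomness of the rendering.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(meta = scan_metadata(),
                         ilm_depth_um = 0.3 * meta$n_depth * meta$axial_um_per_px,
                         ir_um = 117, onl_um = 156, ise_um = 35, rpe_um = 31,
                         pit_depth_um = 78, pit_inl_rise_um = 4,
                         pit_onl_um = 8, ise_thicken_um = 8,
                         pit_sigma_um = 500,
                         intensities = list(vitreous = 0.02, rnfl_top = 0.80,
                                            inl_bottom = 0.25, opl = 0.65,
                                            onl = 0.20, ise = 0.82, iz = 0.45,
                                            rpe = 0.92, choroid = 0.35),
                         rnfl_um = 16, opl_um = 23, iz_um = 12,
                         transition_sigma_px = 1, speckle = 0.25, seed = 1L) {
  stopifnot(inherits(meta, "scan_metadata"), speckle >= 0,
            transition_sigma_px >= 0)
  need <- c("vitreous", "rnfl_top", "inl_bottom", "opl", "onl", "ise", "iz",
            "rpe", "choroid")
  if (!all(need %in% names(intensities)))
    stop("intensities must name all nine bands", call. = FALSE)
  iv <- unlist(intensities[need])
  if (any(iv < 0 | iv > 1)) stop("band intensities must lie in [0, 1]", call. = FALSE)
  if (any(c(ir_um, onl_um, ise_um, rpe_um) <= 0))
    stop("band separations must be strictly positive", call. = FALSE)
  if (ir_um - pit_depth_um - pit_inl_rise_um <= 0)
    stop("foveal terms would invert the vitreous/ILM and INL/OPL interfaces",
         call. = FALSE)
  if (rpe_um - ise_thicken_um <= 0)
    stop("ise_thicken_um would invert the ISe/RPE and RPE/choroid interfaces",
         call. = FALSE)
  spec <- list(meta = meta, ilm_depth_um = ilm_depth_um, ir_um = ir_um,
               onl_um = onl_um, ise_um = ise_um, rpe_um = rpe_um,
               pit_depth_um = pit_depth_um, pit_inl_rise_um = pit_inl_rise_um,
               pit_onl_um = pit_onl_um, ise_thicken_um = ise_thicken_um,
               pit_sigma_um = pit_sigma_um, intensities = intensities[need],
               rnfl_um = rnfl_um, opl_um = opl_um, iz_um = iz_um,
               transition_sigma_px = transition_sigma_px,
               speckle = speckle, seed = as.integer(seed))
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %d x %d x %d grid, TR %.0f um, pit %.0f um, speckle %.2f, seed %d\n",
    x$meta$n_bscans, x$meta$n_depth, x$meta$n_ascans,
    x$ir_um + x$onl_um + x$ise_um + x$rpe_um, x$pit_depth_um, x$speckle,
    x$seed))
  invisible(x)
}

# Foveal weight in [0, 1]: anisotropic Gaussian centred on the grid,
# isotropic in retinal micrometres.
pit_profile <- function(meta, sigma_um) {
  cy <- (meta$n_bscans + 1) / 2
  cx <- (meta$n_ascans + 1) / 2
  dy <- (seq_len(meta$n_bscans) - cy) * meta$bscan_spacing_um
  dx <- (seq_len(meta$n_ascans) - cx) * ascan_pitch_um(meta)
  outer(dy^2, dx^2, `+`) |> (\(d2) exp(-d2 / (2 * sigma_um^2)))()
}

# Ground-truth interface surfaces in (sub-pixel) row units.
phantom_surfaces <- function(spec) {
  meta <- spec$meta
  ax <- meta$axial_um_per_px
  P <- pit_profile(meta, spec$pit_sigma_um)
  depth_px <- function(um) 1 + um / ax # row 1 is depth 0
  z_ilm <- depth_px(spec$ilm_depth_um + spec$pit_depth_um * P)
  z_inl <- depth_px(spec$ilm_depth_um + spec$ir_um - spec$pit_inl_rise_um * P)
  z_onl <- depth_px(spec$ilm_depth_um + spec$ir_um + spec$onl_um +
                      spec$pit_onl_um * P)
  z_ise <- z_onl + (spec$ise_um + spec$ise_thicken_um * P) / ax
  z_rpe <- depth_px(spec$ilm_depth_um + spec$ir_um + spec$onl_um +
                      spec$ise_um + spec$rpe_um + spec$pit_onl_um * P)
  surfs <- list(VITREOUS_ILM = z_ilm, INL_OPL = z_inl, ONL_ISE = z_onl,
                ISE_RPE = z_ise, RPE_CHOROID = z_rpe)
  lo <- min(vapply(surfs, min, numeric(1)))
  hi <- max(vapply(surfs, max, numeric(1)))
  if (lo < 1 || hi > meta$n_depth)
    stop("phantom surfaces fall outside the depth range; increase n_depth or reduce ilm_depth_um",
         call. = FALSE)
  for (k in seq_len(length(surfs) - 1L))
    if (any(surfs[[k + 1L]] - surfs[[k]] <= 0))
      stop("phantom spec violates interface ordering", call. = FALSE)
  surfs
}

# Render one noiseless B-scan (depth x A-scans) from per-column surface
# rows.  Piecewise-constant bands (plus the inner-retina ramp) followed by
# an axial Gaussian blur giving ~1 px transition scale.
render_bscan <- function(surf_rows, spec, n_depth) {
  iv <- spec$intensities
  ax <- spec$meta$axial_um_per_px
  n_cols <- length(surf_rows$VITREOUS_ILM)
  Z <- matrix(seq_len(n_depth), n_depth, n_cols)
  S <- function(v) matrix(v, n_depth, n_cols, byrow = TRUE)
  z_ilm <- S(surf_rows$VITREOUS_ILM); z_inl <- S(surf_rows$INL_OPL)
  z_onl <- S(surf_rows$ONL_ISE); z_ise <- S(surf_rows$ISE_RPE)
  z_rpe <- S(surf_rows$RPE_CHOROID)
  rnfl_px <- pmin(spec$rnfl_um / ax, 0.4 * (z_inl - z_ilm))
  opl_px <- pmin(spec$opl_um / ax, 0.6 * (z_onl - z_inl))
  iz_px <- pmin(spec$iz_um / ax, 0.6 * (z_rpe - z_ise))

  img <- matrix(iv$vitreous, n_depth, n_cols)
  m <- Z >= z_ilm & Z < z_ilm + rnfl_px
  img[m] <- iv$rnfl_top
  m <- Z >= z_ilm + rnfl_px & Z < z_inl
  frac <- (Z - z_ilm - rnfl_px) / pmax(z_inl - z_ilm - rnfl_px, 1e-9)
  img[m] <- iv$rnfl_top + frac[m] * (iv$inl_bottom - iv$rnfl_top)
  m <- Z >= z_inl & Z < z_inl + opl_px; img[m] <- iv$opl
  m <- Z >= z_inl + opl_px & Z < z_onl; img[m] <- iv$onl
  m <- Z >= z_onl & Z < z_ise; img[m] <- iv$ise
  m <- Z >= z_ise & Z < z_ise + iz_px; img[m] <- iv$iz
  m <- Z >= z_ise + iz_px & Z < z_rpe; img[m] <- iv$rpe
  m <- Z >= z_rpe; img[m] <- iv$choroid

  if (spec$transition_sigma_px > 0)
    img <- convolve_axis(img, gaussian_kernel(spec$transition_sigma_px), 1L)
  img
}

#' Generate a synthetic SDOCT volume with ground-truth boundaries
#'
#' Renders every A-scan as piecewise-constant band reflectivities at the
#' spec's interface surfaces, applies Gaussian-shaped axial transitions
#' (~1 px scale) and unit-mean multiplicative gamma speckle, and returns
#' the exact surfaces as the ground-truth boundary set.  Identical specs
#' (including seed) give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` (an [oct_volume()]), `truth` (a
#'   [boundary_set()] holding the exact sub-pixel surfaces) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  meta <- spec$meta
  surfs <- phantom_surfaces(spec)
  set.seed(spec$seed)
  shape <- if (spec$speckle > 0) 1 / spec$speckle^2 else NA_real_
  vol <- array(0, c(meta$n_bscans, meta$n_depth, meta$n_ascans))
  for (y in seq_len(meta$n_bscans)) {
    rows_y <- lapply(surfs, function(s) s[y, ])
    img <- render_bscan(rows_y, spec, meta$n_depth)
    if (spec$speckle > 0) {
      noise <- matrix(rgamma(length(img), shape = shape, scale = 1 / shape),
                      nrow(img))
      img <- img * noise
    }
    vol[y, , ] <- pmin(pmax(img, 0), 1)
  }
  truth <- boundary_set(surfs, meta)
  list(volume = oct_volume(vol, meta), truth = truth, spec = spec)
}

#' Pathology specification for the phantom injectors
#'
#' @param kind One of `"cyst"`, `"hard_exudate"`, `"laser_scar"`,
#'   `"vessel_shadow"`, `"edema"`, `"atrophy"`.
#' @param center Length-2 vector `(y, x)`: B-scan and A-scan index of the
#'   lesion centre.
#' @param radius Lesion radius in A-scan pixels (the B-scan axis is scaled
#'   by the metadata's anisotropy so the footprint is round on the retina).
#' @param magnitude Kind-specific strength: added/removed thickness in um
#'   for `cyst`/`edema`/`laser_scar`/`atrophy`; attenuation factor in
#'   `(0, 1]` for `hard_exudate` (shadow strength) and `vessel_shadow`.
#' @return An object of class `pathology_spec`.
#' @export
pathology_spec <- function(kind = c("cyst", "hard_exudate", "laser_scar",
                                    "vessel_shadow", "edema", "atrophy"),
                           center, radius, magnitude) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 2L, radius > 0, is.finite(magnitude))
  if (kind %in% c("hard_exudate", "vessel_shadow") &&
      (magnitude <= 0 || magnitude > 1))
    stop("attenuation magnitude must lie in (0, 1]", call. = FALSE)
  if (kind %in% c("cyst", "edema", "laser_scar", "atrophy") && magnitude <= 0)
    stop("thickness magnitude must be positive (um)", call. = FALSE)
  structure(list(kind = kind, center = as.numeric(center),
                 radius = as.numeric(radius),
                 magnitude = as.numeric(magnitude)),
            class = "pathology_spec")
}

# Smooth compact footprint weight: raised-cosine bump, 1 at the centre,
# exactly 0 at and beyond the radius.  Returns the weight matrix plus the
# index ranges it is nonzero on.
lesion_footprint <- function(meta, center, radius) {
  aniso <- meta$bscan_spacing_um / ascan_pitch_um(meta)
  ys <- seq_len(meta$n_bscans)
  xs <- seq_len(meta$n_ascans)
  d <- sqrt(outer(((ys - center[1]) * aniso)^2, (xs - center[2])^2, `+`))
  w <- matrix(0, meta$n_bscans, meta$n_ascans)
  inside <- d < radius
  w[inside] <- cos(pi * d[inside] / (2 * radius))^2
  w
}

# Shift the part of one A-scan at and below row z0 down by d rows, filling
# the opened gap with `fill`; rows pushed past the bottom are dropped.
shift_column_down <- function(col, z0, d, fill) {
  n <- length(col)
  if (d < 1 || z0 > n) return(col)
  src_last <- n - d
  if (src_last >= z0) col[(z0 + d):n] <- col[z0:src_last]
  col[z0:min(z0 + d - 1, n)] <- fill
  col
}

# Shift the part of one A-scan at and below row z0 up by d rows, repeating
# the bottom value into the vacated rows.
shift_column_up <- function(col, z0, d) {
  n <- length(col)
  if (d < 1 || z0 + d > n) return(col)
  col[z0:(n - d)] <- col[(z0 + d):n]
  col[(n - d + 1):n] <- col[n]
  col
}

#' Inject a pathology into a phantom volume and its ground truth
#'
#' Modifies the rendered volume and the ground-truth boundary set
#' consistently, only within the lesion footprint:
#' \describe{
#'   \item{edema}{displaces the ONL/ISe, ISe/RPE and RPE/choroid surfaces
#'     downward by up to `magnitude` um (outer-retinal thickening: TR and
#'     OR thicken, IR does not), inserting tissue-reflectivity rows.}
#'   \item{cyst}{as edema, but the inserted rows are hypo-reflective fluid
#'     (cystoid spaces).}
#'   \item{hard_exudate}{hyper-reflective blob between the vitreous/ILM and
#'     INL/OPL surfaces plus multiplicative attenuation (factor
#'     `1 - magnitude` at the centre) of all rows beneath it; boundaries
#'     unchanged.}
#'   \item{laser_scar}{moves the ISe/RPE surface up toward ONL/ISe by up to
#'     `magnitude` um (ISe thinning) and darkens the remaining ISe band.}
#'   \item{vessel_shadow}{columnar attenuation of all rows below the
#'     INL/OPL surface.}
#'   \item{atrophy}{moves the INL/OPL surface and everything below it up by
#'     up to `magnitude` um (inner-retinal tissue loss: IR and TR thin).}
#' }
#'
#' @param vol An [oct_volume()] (typically from [generate_phantom()]).
#' @param bs The matching ground-truth [boundary_set()].
#' @param p A [pathology_spec()].
#' @param spec The generating [phantom_spec()] (supplies band
#'   reflectivities for inserted tissue/fluid).
#' @return List with modified `volume` and `truth`.
#' @export
apply_pathology <- function(vol, bs, p, spec = phantom_spec(meta = vol$meta)) {
  stopifnot(inherits(vol, "oct_volume"), inherits(bs, "boundary_set"),
            inherits(p, "pathology_spec"))
  meta <- vol$meta
  if (p$center[1] < 1 || p$center[1] > meta$n_bscans ||
      p$center[2] < 1 || p$center[2] > meta$n_ascans)
    stop("lesion centre outside the grid", call. = FALSE)
  ax <- meta$axial_um_per_px
  iv <- spec$intensities
  w <- lesion_footprint(meta, p$center, p$radius)
  hit <- which(w > 0, arr.ind = TRUE)
  rows <- bs$rows
  intensity <- vol$intensity
  shift_px <- w * p$magnitude / ax # for the um-magnitude kinds

  if (p$kind %in% c("edema", "cyst")) {
    room <- meta$n_depth - rows$RPE_CHOROID
    if (any(shift_px > room - 1))
      stop("magnitude pushes the RPE/choroid surface out of the image",
           call. = FALSE)
    fill <- if (p$kind == "cyst") 0.03 else iv$onl
    opl_px <- spec$opl_um / ax
    for (k in seq_len(nrow(hit))) {
      y <- hit[k, 1]; x <- hit[k, 2]
      d <- as.integer(round(shift_px[y, x]))
      z0 <- as.integer(round(rows$INL_OPL[y, x] + opl_px + 2))
      intensity[y, , x] <- shift_column_down(intensity[y, , x], z0, d, fill)
    }
    for (id in c("ONL_ISE", "ISE_RPE", "RPE_CHOROID"))
      rows[[id]] <- rows[[id]] + shift_px
  } else if (p$kind == "hard_exudate") {
    half_px <- 4 # blob half-height
    for (k in seq_len(nrow(hit))) {
      y <- hit[k, 1]; x <- hit[k, 2]
      wk <- w[y, x]
      zc <- round((rows$VITREOUS_ILM[y, x] + rows$INL_OPL[y, x]) / 2)
      zb <- max(1, zc - half_px):min(meta$n_depth, zc + half_px)
      intensity[y, zb, x] <- intensity[y, zb, x] +
        wk * (0.95 - intensity[y, zb, x])
      below <- seq.int(min(zc + half_px + 1, meta$n_depth), meta$n_depth)
      intensity[y, below, x] <- intensity[y, below, x] * (1 - p$magnitude * wk)
    }
  } else if (p$kind == "laser_scar") {
    band <- rows$ISE_RPE - rows$ONL_ISE
    if (any(shift_px > band - 0.5))
      stop("magnitude exceeds the ISe band thickness", call. = FALSE)
    new_ise <- rows$ISE_RPE - shift_px
    for (k in seq_len(nrow(hit))) {
      y <- hit[k, 1]; x <- hit[k, 2]
      z_new <- round(new_ise[y, x]); z_old <- round(rows$ISE_RPE[y, x])
      if (z_old > z_new)
        intensity[y, z_new:(z_old - 1), x] <- iv$iz
      z_top <- round(rows$ONL_ISE[y, x])
      if (z_new > z_top) {
        zb <- z_top:(z_new - 1)
        intensity[y, zb, x] <- intensity[y, zb, x] * (1 - 0.3 * w[y, x])
      }
    }
    rows$ISE_RPE <- new_ise
  } else if (p$kind == "vessel_shadow") {
    for (k in seq_len(nrow(hit))) {
      y <- hit[k, 1]; x <- hit[k, 2]
      zb <- round(rows$INL_OPL[y, x]):meta$n_depth
      intensity[y, zb, x] <- intensity[y, zb, x] * (1 - p$magnitude * w[y, x])
    }
  } else if (p$kind == "atrophy") {
    band <- rows$INL_OPL - rows$VITREOUS_ILM
    if (any(shift_px > band - 0.5))
      stop("magnitude exceeds the inner-retina thickness", call. = FALSE)
    for (k in seq_len(nrow(hit))) {
      y <- hit[k, 1]; x <- hit[k, 2]
      d <- as.integer(round(shift_px[y, x]))
      z0 <- as.integer(round(rows$VITREOUS_ILM[y, x] + 2))
      intensity[y, , x] <- shift_column_up(intensity[y, , x], z0, d)
    }
    for (id in c("INL_OPL", "ONL_ISE", "ISE_RPE", "RPE_CHOROID"))
      rows[[id]] <- rows[[id]] - shift_px
  }

  list(volume = oct_volume(pmin(pmax(intensity, 0), 1), meta),
       truth = boundary_set(rows, meta, valid = bs$valid))
}

#' Cohort between-subject variability
#'
#' Standard deviations (um) of per-subject Gaussian perturbations applied
#' to the default phantom anatomy.  Defaults are of the order of normal
#' between-subject macular variability.
#'
#' @param ilm_sd_um SD of the overall axial placement (no thickness effect).
#' @param ir_sd_um,onl_sd_um,ise_sd_um SDs of the band separations.
#' @param pit_sd_um SD of the foveal pit depth.
#' @return Named list of SDs.
#' @export
cohort_variability <- function(ilm_sd_um = 10, ir_sd_um = 6, onl_sd_um = 8,
                               ise_sd_um = 2, pit_sd_um = 8) {
  list(ilm_sd_um = ilm_sd_um, ir_sd_um = ir_sd_um, onl_sd_um = onl_sd_um,
       ise_sd_um = ise_sd_um, pit_sd_um = pit_sd_um)
}

#' Simulate a cohort of phantom subjects
#'
#' Draws per-subject anatomical parameters from Gaussian perturbations of a
#' template spec and generates one phantom per subject.  The cohort `seed`
#' drives the parameter draws only; rendering (speckle) uses the template's
#' own seed, so zero variability yields identical subjects.
#'
#' @param n Number of subjects (>= 2).
#' @param spec Template [phantom_spec()].
#' @param variability A [cohort_variability()] list.
#' @param seed Integer seed for the parameter draws.
#' @return List of `n` [generate_phantom()] results.
#' @export
phantom_cohort <- function(n, spec = phantom_spec(),
                           variability = cohort_variability(), seed = 1L) {
  stopifnot(n >= 2)
  set.seed(seed)
  draws <- matrix(rnorm(5L * n), n, 5L)
  lapply(seq_len(n), function(i) {
    s <- spec
    s$ilm_depth_um <- s$ilm_depth_um + draws[i, 1] * variability$ilm_sd_um
    s$ir_um <- s$ir_um + draws[i, 2] * variability$ir_sd_um
    s$onl_um <- s$onl_um + draws[i, 3] * variability$onl_sd_um
    s$ise_um <- s$ise_um + draws[i, 4] * variability$ise_sd_um
    s$pit_depth_um <- s$pit_depth_um + draws[i, 5] * variability$pit_sd_um
    generate_phantom(s)
  })
}
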