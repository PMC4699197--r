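# Shared fixtures, all generated in code: a small scan profile keeps the
# routine tests fast; the acceptance file uses the full default profile.

small_meta <- function(n_bscans = 7L, n_ascans = 96L, n_depth = 160L) {
  scan_metadata(n_bscans = n_bscans, n_ascans = n_ascans, n_depth = n_depth)
}

small_spec <- function(speckle = 0, seed = 3L, meta = small_meta(), ...) {
  phantom_spec(meta = meta, speckle = speckle, seed = seed, ...)
}

# Memoized small phantoms (noiseless / default speckle), shared across tests.
.phantom_cache <- new.env(parent = emptyenv())
small_phantom <- function(speckle = 0, seed = 3L) {
  key <- sprintf("s%g_%d", speckle, seed)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(small_spec(speckle, seed))
  .phantom_cache[[key]]
}

# A random but valid boundary set: five sorted row surfaces per pixel.
random_boundary_set <- function(meta = small_meta(3L, 12L, 60L), seed = 1L) {
  set.seed(seed)
  n <- meta$n_bscans * meta$n_ascans
  draws <- matrix(runif(5L * n, 2, meta$n_depth - 1), nrow = n)
  draws <- t(apply(draws, 1L, sort))
  rows <- setNames(lapply(1:5, function(k)
    matrix(draws[, k], meta$n_bscans, meta$n_ascans)), interface_ids())
  boundary_set(rows, meta)
}

# Independent re-computation of a lesion's footprint weight (raised-cosine
# bump, round on the retina) for locality checks.
lesion_footprint_test <- function(meta, center, radius) {
  aniso <- meta$bscan_spacing_um / (288 * meta$field_deg / meta$n_ascans)
  d <- sqrt(outer(((seq_len(meta$n_bscans) - center[1]) * aniso)^2,
                  (seq_len(meta$n_ascans) - center[2])^2, `+`))
  w <- matrix(0, meta$n_bscans, meta$n_ascans)
  w[d < radius] <- cos(pi * d[d < radius] / (2 * radius))^2
  w
}

interface_polarity <- c(VITREOUS_ILM = "DARK_TO_BRIGHT",
                        INL_OPL = "DARK_TO_BRIGHT",
                        ONL_ISE = "DARK_TO_BRIGHT",
                        ISE_RPE = "BRIGHT_TO_DARK",
                        RPE_CHOROID = "BRIGHT_TO_DARK")
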