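make_bs <- function(rows_list, meta) boundary_set(rows_list, meta)

test_that("thickness is the interface separation in micrometres", {
  meta <- small_meta(3L, 10L, 40L)
  flat <- function(r) matrix(r, meta$n_bscans, meta$n_ascans)

  # zero separation between ILM and INL/OPL: IR thickness is identically 0
  bs <- make_bs(list(VITREOUS_ILM = flat(10), INL_OPL = flat(10),
                     ONL_ISE = flat(20), ISE_RPE = flat(25),
                     RPE_CHOROID = flat(30)), meta)
  expect_equal(thickness_map(bs, "IR")$values, flat(0))

  # one-pixel separation maps to the axial sampling (3.9 um by default)
  bs1 <- make_bs(list(VITREOUS_ILM = flat(10), INL_OPL = flat(11),
                      ONL_ISE = flat(20), ISE_RPE = flat(25),
                      RPE_CHOROID = flat(30)), meta)
  expect_equal(thickness_map(bs1, "IR")$values, flat(3.9))
  expect_equal(thickness_map(bs1, "IR", axial_um_per_px = 7)$values, flat(7))

  expect_error(thickness_map(bs1, "XX"), "unknown layer")
})

test_that("TR = IR + OR holds exactly on arbitrary valid boundary sets", {
  for (seed in 1:5) {
    bs <- random_boundary_set(seed = seed)
    tr <- thickness_map(bs, "TR")$values
    ir <- thickness_map(bs, "IR")$values
    or <- thickness_map(bs, "OR")$values
    # exact identity through the shared INL/OPL interface, up to one ulp of
    # floating-point roundoff in the two subtraction orders
    expect_lte(max(abs(tr - (ir + or))), 1e-9)
  }
})

test_that("reflectance is the vertical band mean with half-open bounds", {
  meta <- small_meta(2L, 3L, 12L)
  flat <- function(r) matrix(r, meta$n_bscans, meta$n_ascans)
  arr <- array(0.5, c(2, 12, 3))
  # band rows 4..7 hold (0.2, 0.2, 0.6, 0.6): half-open [4, 8) averages 0.4
  arr[, 4:7, ] <- rep(c(0.2, 0.2, 0.6, 0.6), each = 2)
  vol <- oct_volume(arr, meta)
  bs <- make_bs(list(VITREOUS_ILM = flat(4), INL_OPL = flat(8),
                     ONL_ISE = flat(9), ISE_RPE = flat(10),
                     RPE_CHOROID = flat(11)), meta)
  expect_equal(reflectance_image(vol, bs, "IR")$values, flat(0.4))

  # constant-intensity layer: mean equals the constant
  expect_equal(reflectance_image(vol, bs, "ISE")$values, flat(0.5))

  # degenerate band (upper == lower) falls back to the single upper pixel
  bs0 <- make_bs(list(VITREOUS_ILM = flat(4), INL_OPL = flat(4),
                      ONL_ISE = flat(9), ISE_RPE = flat(10),
                      RPE_CHOROID = flat(11)), meta)
  expect_equal(reflectance_image(vol, bs0, "IR")$values, flat(0.2))
})

test_that("reflectance agrees with a brute-force per-pixel loop", {
  meta <- small_meta(3L, 8L, 30L)
  set.seed(17)
  arr <- array(runif(3 * 30 * 8), c(3, 30, 8))
  vol <- oct_volume(arr, meta)
  bs <- random_boundary_set(meta = meta, seed = 4)
  for (layer in c("TR", "IR", "OR", "ISE")) {
    got <- reflectance_image(vol, bs, layer)$values
    def <- layer_definitions()
    up <- round(bs$rows[[def$upper[def$layer == layer]]])
    lo <- round(bs$rows[[def$lower[def$layer == layer]]])
    want <- matrix(NA_real_, 3, 8)
    for (y in 1:3) for (x in 1:8) {
      rows <- if (lo[y, x] > up[y, x]) up[y, x]:(lo[y, x] - 1) else up[y, x]
      want[y, x] <- mean(arr[y, rows, x])
    }
    expect_equal(got, want)
  }
})

test_that("reflectance scales linearly with volume intensity", {
  ph <- small_phantom(speckle = 0)
  bs <- ph$truth
  vol2 <- oct_volume(ph$volume$intensity / 2, ph$volume$meta)
  r1 <- reflectance_image(ph$volume, bs, "OR")$values
  r2 <- reflectance_image(vol2, bs, "OR")$values
  expect_equal(r2, r1 / 2)
})

test_that("all eight products share the enface grid and validity mask", {
  ph <- small_phantom(speckle = 0)
  bs <- ph$truth
  bs$valid[2, 7] <- FALSE
  prods <- all_enface_products(ph$volume, bs)
  expect_named(prods, c("thickness", "reflectance"))
  expect_length(prods$thickness, 4L)
  expect_length(prods$reflectance, 4L)
  meta <- ph$volume$meta
  for (grp in prods) for (m in grp) {
    expect_identical(dim(m$values), c(meta$n_bscans, meta$n_ascans))
    expect_false(m$valid[2, 7])
    expect_true(is.na(m$values[2, 7]))
  }
})
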