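test_that("scan metadata defaults match the high-density macular protocol", {
  m <- scan_metadata()
  expect_equal(m$n_bscans, 145L)
  expect_equal(m$n_ascans, 768L)
  expect_equal(m$axial_um_per_px, 3.9)
  expect_equal(m$bscan_spacing_um, 31)
  expect_equal(m$field_deg, 15)
  expect_equal(m$frames_averaged, 9L)
  expect_error(scan_metadata(n_bscans = 0), "counts")
  expect_error(scan_metadata(axial_um_per_px = -1), "axial")
})

test_that("volume construction validates shape and intensity range", {
  meta <- small_meta(2L, 4L, 6L)
  arr <- array(runif(2 * 6 * 4), c(2, 6, 4))
  vol <- oct_volume(arr, meta)
  expect_s3_class(vol, "oct_volume")
  expect_identical(get_bscan(vol, 2), {
    m <- arr[2, , ]
    dim(m) <- c(6, 4)
    m
  })
  expect_error(oct_volume(array(0, c(2, 6, 5)), meta), "does not match")
  bad <- arr
  bad[1] <- 1.5
  expect_error(oct_volume(bad, meta), "\\[0, 1\\]")
  expect_error(get_bscan(vol, 3), "out of range")
})

test_that("boundary sets enforce the anatomical depth ordering", {
  bs <- random_boundary_set()
  expect_identical(nrow(validate_boundary_set(bs)), 0L)

  # force a single inversion: INL/OPL above vitreous/ILM at one pixel
  rows <- bs$rows
  rows$INL_OPL[2, 5] <- rows$VITREOUS_ILM[2, 5] - 1
  v <- validate_boundary_set(list(rows = rows, valid = bs$valid))
  expect_equal(nrow(v), 1L)
  expect_equal(v$upper, "VITREOUS_ILM")
  expect_equal(v$lower, "INL_OPL")
  expect_equal(c(v$bscan, v$ascan), c(2L, 5L))
  expect_error(boundary_set(rows, bs$meta), "ordering violated")
})

test_that("ordering violations match an exhaustive per-pixel scan", {
  bs <- random_boundary_set(seed = 7)
  rows <- bs$rows
  set.seed(8)
  # random perturbation breaking the order at scattered pixels
  for (id in interface_ids())
    rows[[id]] <- rows[[id]] + matrix(rnorm(length(rows[[id]]), 0, 6),
                                      nrow(rows[[id]]))
  rows <- lapply(rows, function(r) pmin(pmax(r, 1), bs$meta$n_depth))
  got <- validate_boundary_set(list(rows = rows, valid = bs$valid))

  # independent brute force: nested loops over pixels and interface pairs
  ids <- interface_ids()
  want <- list()
  for (y in seq_len(nrow(bs$valid))) for (x in seq_len(ncol(bs$valid))) {
    for (k in 1:4) {
      if (rows[[ids[k + 1]]][y, x] < rows[[ids[k]]][y, x])
        want[[length(want) + 1L]] <- data.frame(
          upper = ids[k], lower = ids[k + 1], bscan = y, ascan = x,
          stringsAsFactors = FALSE)
    }
  }
  want <- do.call(rbind, want)
  expect_gt(nrow(got), 0L)
  key <- function(d) sort(paste(d$upper, d$lower, d$bscan, d$ascan))
  expect_identical(key(got), key(want))
})

test_that("invalid pixels are carried by masks, not sentinels", {
  bs <- random_boundary_set()
  bs$valid[1, 3] <- FALSE
  tm <- thickness_map(bs, "TR")
  expect_false(tm$valid[1, 3])
  expect_true(is.na(tm$values[1, 3]))
})

test_that("enface map construction validates kind-specific ranges", {
  meta <- small_meta(2L, 3L, 8L)
  v <- matrix(runif(6), 2, 3)
  expect_error(enface_map(-v, kind = "thickness_um", layer = "TR", meta = meta),
               ">= 0")
  expect_error(enface_map(v + 1, kind = "reflectance", layer = "TR", meta = meta),
               "\\[0, 1\\]")
  m <- enface_map(v * 100, kind = "thickness_um", layer = "IR", meta = meta)
  expect_equal(m$layer, "IR")
  expect_true(all(m$valid))
})
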