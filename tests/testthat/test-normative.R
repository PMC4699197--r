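sim_meta <- function(nr, nc) scan_metadata(n_bscans = nr, n_ascans = nc,
                                           n_depth = 8L)

const_map <- function(v, nr = 4L, nc = 6L, layer = "TR") {
  enface_map(matrix(v, nr, nc), kind = "thickness_um", layer = layer,
             meta = sim_meta(nr, nc))
}

test_that("atlas statistics match hand-computed sample moments", {
  # identical cohort: zero variance, limits collapse onto the mean
  atlas <- build_atlas(replicate(5, const_map(250), simplify = FALSE))
  expect_equal(atlas$mean, matrix(250, 4, 6))
  expect_equal(atlas$sd, matrix(0, 4, 6))
  expect_equal(atlas$lower, atlas$mean)
  expect_equal(atlas$upper, atlas$mean)

  # two subjects at 100 and 120 um: mean 110, sample SD sqrt(200)
  atlas <- build_atlas(list(const_map(100), const_map(120)))
  expect_equal(atlas$mean[1, 1], 110)
  expect_equal(atlas$sd[1, 1], sqrt(200))
  expect_equal(atlas$lower[1, 1], 110 - qnorm(0.975) * sqrt(200))
  expect_equal(atlas$upper[1, 1], 110 + qnorm(0.975) * sqrt(200))
  expect_equal(atlas$n_subjects, 2L)

  expect_error(build_atlas(list(const_map(100))), "at least 2")
  expect_error(build_atlas(list(const_map(100), const_map(100, layer = "IR"))),
               "mixed layer")
})

test_that("atlas mean and SD converge to the generating parameters", {
  mu <- matrix(seq(200, 320, length.out = 24), 4, 6)
  sdm <- matrix(12, 4, 6)
  maps <- simulate_gaussian_maps(800, mu, sdm, seed = 301)
  atlas <- build_atlas(maps)
  expect_lt(max(abs(atlas$mean - mu)), 12 / sqrt(800) * 5)
  expect_lt(max(abs(atlas$sd - 12)), 12 * 5 / sqrt(2 * 799))
})

test_that("pixels valid in fewer than two subjects are invalid in the atlas", {
  m1 <- const_map(100); m2 <- const_map(120); m3 <- const_map(140)
  m2$valid[1, 1] <- FALSE
  m3$valid[1, 1] <- FALSE
  atlas <- build_atlas(list(m1, m2, m3))
  expect_false(atlas$valid[1, 1])
  expect_true(is.na(atlas$mean[1, 1]))
  expect_true(all(atlas$valid[-1]))
})

test_that("deviation labels agree with explicit threshold comparison", {
  set.seed(55)
  mu <- matrix(280, 5, 8)
  sdm <- matrix(15, 5, 8)
  atlas <- build_atlas(simulate_gaussian_maps(60, mu, sdm, seed = 56))

  # patient at the atlas mean: everywhere within
  at_mean <- enface_map(atlas$mean, "thickness_um", "TR", sim_meta(5L, 8L))
  expect_true(all(deviation_map(at_mean, atlas)$labels == "within"))

  # patient beyond the upper limit everywhere: all above
  above <- enface_map(atlas$upper + 1, "thickness_um", "TR", sim_meta(5L, 8L))
  expect_true(all(deviation_map(above, atlas)$labels == "above"))

  # boundary values are inclusive, hence within
  at_limit <- enface_map(atlas$upper, "thickness_um", "TR", sim_meta(5L, 8L))
  expect_true(all(deviation_map(at_limit, atlas)$labels == "within"))

  # random patient: per-pixel brute-force comparison
  pv <- matrix(rnorm(40, 280, 40), 5, 8)
  patient <- enface_map(pv, "thickness_um", "TR", sim_meta(5L, 8L))
  got <- deviation_map(patient, atlas)$labels
  for (y in 1:5) for (x in 1:8) {
    want <- if (pv[y, x] < atlas$lower[y, x]) "below"
            else if (pv[y, x] > atlas$upper[y, x]) "above" else "within"
    expect_identical(got[y, x], want)
  }

  # label partition: below + within + above account for every valid pixel
  expect_equal(sum(got %in% c("below", "within", "above")), sum(atlas$valid))

  bad <- enface_map(matrix(280, 4, 8), "thickness_um", "TR", sim_meta(4L, 8L))
  expect_error(deviation_map(bad, atlas), "grids do not match")
  wrong_layer <- enface_map(pv, "thickness_um", "IR", sim_meta(5L, 8L))
  expect_error(deviation_map(wrong_layer, atlas), "layer mismatch")
})

test_that("widening the coverage never ejects a pixel from 'within'", {
  maps <- simulate_gaussian_maps(40, matrix(300, 6, 6), matrix(20, 6, 6),
                                 seed = 77)
  patient <- simulate_gaussian_maps(1, matrix(300, 6, 6), matrix(40, 6, 6),
                                    seed = 78)[[1]]
  a90 <- build_atlas(maps, coverage = 0.90)
  a99 <- build_atlas(maps, coverage = 0.99)
  l90 <- deviation_map(patient, a90)$labels
  l99 <- deviation_map(patient, a99)$labels
  expect_true(all(l99[l90 == "within"] == "within"))
})

test_that("the pooled within fraction approaches the nominal coverage", {
  mu <- matrix(300, 24, 24)
  sdm <- matrix(15, 24, 24)
  atlas <- build_atlas(simulate_gaussian_maps(2000, mu, sdm, seed = 90))
  fresh <- simulate_gaussian_maps(50, mu, sdm, seed = 91)
  expect_equal(coverage_check(atlas, fresh), 0.95, tolerance = 0.01)

  # far-out-of-distribution maps are essentially never within
  far <- simulate_gaussian_maps(5, mu + 5 * sdm, sdm * 1e-3, seed = 92)
  expect_lt(coverage_check(atlas, far), 0.01)

  # and a 99% atlas covers ~99%
  a99 <- build_atlas(simulate_gaussian_maps(2000, mu, sdm, seed = 90),
                     coverage = 0.99)
  expect_equal(coverage_check(a99, fresh), 0.99, tolerance = 0.005)
})

test_that("mean-CI limits shrink with the cohort size", {
  maps <- simulate_gaussian_maps(100, matrix(300, 4, 4), matrix(10, 4, 4),
                                 seed = 111)
  pop <- build_atlas(maps)
  mci <- build_atlas(maps, limits = "mean_ci")
  expect_equal(mci$upper - mci$mean, (pop$upper - pop$mean) / sqrt(100))
})
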