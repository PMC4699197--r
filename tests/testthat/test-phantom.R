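test_that("phantom generation is deterministic and correctly shaped", {
  sp <- small_spec(speckle = 0.25, seed = 12)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth$rows, b$truth$rows)
  expect_identical(dim(a$volume$intensity), c(7L, 160L, 96L))

  c3 <- generate_phantom(small_spec(speckle = 0.25, seed = 13))
  expect_false(identical(a$volume$intensity, c3$volume$intensity))
})

test_that("ground-truth surfaces are ordered and inside the image", {
  ph <- small_phantom(speckle = 0)
  expect_identical(nrow(validate_boundary_set(ph$truth)), 0L)
  for (id in interface_ids()) {
    expect_true(all(ph$truth$rows[[id]] >= 1))
    expect_true(all(ph$truth$rows[[id]] <= ph$volume$meta$n_depth))
  }
  expect_error(phantom_spec(meta = small_meta(), pit_depth_um = 130),
               "invert")
})

test_that("noiseless rendering reproduces the stated band reflectivities", {
  ph <- small_phantom(speckle = 0)
  sp <- ph$spec
  ax <- sp$meta$axial_um_per_px
  y <- 1L; x <- 5L # far corner: foveal terms are ~0 there
  b <- get_bscan(ph$volume, y)
  mid <- function(a, b2) round((a + b2) / 2)
  tr <- ph$truth$rows
  # wide bands: the blurred profile is exactly flat at the band centre
  expect_equal(b[round(tr$VITREOUS_ILM[y, x]) - 8, x], sp$intensities$vitreous)
  onl_top <- tr$INL_OPL[y, x] + sp$opl_um / ax
  expect_equal(b[mid(onl_top, tr$ONL_ISE[y, x]), x], sp$intensities$onl)
  expect_equal(b[round(tr$RPE_CHOROID[y, x]) + 8, x], sp$intensities$choroid)
  # bands comparable in width to the transition blur: centre value reaches
  # the nominal reflectivity up to the blur's tail leakage
  expect_equal(b[mid(tr$ONL_ISE[y, x], tr$ISE_RPE[y, x]), x],
               sp$intensities$ise, tolerance = 1e-3)
  expect_equal(b[mid(tr$INL_OPL[y, x], onl_top), x], sp$intensities$opl,
               tolerance = 2e-2)
  rpe_top <- tr$ISE_RPE[y, x] + sp$iz_um / ax
  expect_equal(b[mid(rpe_top, tr$RPE_CHOROID[y, x]), x], sp$intensities$rpe,
               tolerance = 5e-2)
})

test_that("end-to-end: segmenting a clean phantom reproduces truth thickness", {
  ph <- small_phantom(speckle = 0)
  bs <- segment_volume(ph$volume)
  ax <- ph$volume$meta$axial_um_per_px
  for (layer in c("TR", "IR", "OR", "ISE")) {
    got <- thickness_map(bs, layer)$values
    want <- thickness_map(ph$truth, layer)$values
    expect_lte(max(abs(got - want)), 2 * ax) # both interfaces within 1 px
  }
})

test_that("hard exudates brighten IR and shadow the deeper layers", {
  ph <- small_phantom(speckle = 0)
  p <- pathology_spec("hard_exudate", center = c(4, 48), radius = 12,
                      magnitude = 0.6)
  mod <- apply_pathology(ph$volume, ph$truth, p, ph$spec)
  # boundaries untouched
  expect_identical(mod$truth$rows, ph$truth$rows)

  prods0 <- all_enface_products(ph$volume, ph$truth)
  prods1 <- all_enface_products(mod$volume, mod$truth)
  foot <- which(lesion_footprint_test(ph$volume$meta, c(4, 48), 12) > 0.2)
  expect_gt(mean(prods1$reflectance$IR$values[foot]),
            mean(prods0$reflectance$IR$values[foot]))
  expect_lt(mean(prods1$reflectance$OR$values[foot]),
            mean(prods0$reflectance$OR$values[foot]))
  expect_lt(mean(prods1$reflectance$ISE$values[foot]),
            mean(prods0$reflectance$ISE$values[foot]))
  # locality: nothing changes outside the lesion footprint
  out <- which(lesion_footprint_test(ph$volume$meta, c(4, 48), 12) == 0)
  expect_identical(prods1$reflectance$IR$values[out],
                   prods0$reflectance$IR$values[out])
})

test_that("laser scars thin the ISe band by exactly their magnitude", {
  ph <- small_phantom(speckle = 0)
  m <- 12 # um
  p <- pathology_spec("laser_scar", center = c(4, 30), radius = 10,
                      magnitude = m)
  mod <- apply_pathology(ph$volume, ph$truth, p, ph$spec)
  t0 <- thickness_map(ph$truth, "ISE")$values
  t1 <- thickness_map(mod$truth, "ISE")$values
  expect_equal(t1[4, 30], t0[4, 30] - m)
  expect_true(all(t1 <= t0 + 1e-9))
  out <- which(lesion_footprint_test(ph$volume$meta, c(4, 30), 10) == 0)
  expect_identical(t1[out], t0[out])
})

test_that("outer-retinal edema thickens TR and OR but not IR", {
  ph <- small_phantom(speckle = 0)
  m <- 40 # um
  p <- pathology_spec("edema", center = c(4, 70), radius = 14, magnitude = m)
  mod <- apply_pathology(ph$volume, ph$truth, p, ph$spec)
  for (layer in c("TR", "OR")) {
    t0 <- thickness_map(ph$truth, layer)$values
    t1 <- thickness_map(mod$truth, layer)$values
    expect_equal(t1[4, 70], t0[4, 70] + m)
  }
  expect_identical(thickness_map(mod$truth, "IR")$values,
                   thickness_map(ph$truth, "IR")$values)
})

test_that("cysts insert a hypo-reflective space; shadows attenuate columns", {
  ph <- small_phantom(speckle = 0)
  cyst <- apply_pathology(ph$volume, ph$truth,
                          pathology_spec("cyst", c(4, 48), 10, 35), ph$spec)
  # the inserted fluid darkens the outer-retina band at the centre
  r0 <- reflectance_image(ph$volume, ph$truth, "OR")$values
  r1 <- reflectance_image(cyst$volume, cyst$truth, "OR")$values
  expect_lt(r1[4, 48], r0[4, 48])

  vs <- apply_pathology(ph$volume, ph$truth,
                        pathology_spec("vessel_shadow", c(4, 20), 4, 0.7),
                        ph$spec)
  s0 <- reflectance_image(ph$volume, ph$truth, "ISE")$values
  s1 <- reflectance_image(vs$volume, vs$truth, "ISE")$values
  expect_lt(s1[4, 20], s0[4, 20])
  expect_identical(vs$truth$rows, ph$truth$rows)

  atr <- apply_pathology(ph$volume, ph$truth,
                         pathology_spec("atrophy", c(4, 80), 10, 25), ph$spec)
  i0 <- thickness_map(ph$truth, "IR")$values
  i1 <- thickness_map(atr$truth, "IR")$values
  expect_equal(i1[4, 80], i0[4, 80] - 25)
})

test_that("over-strong lesions that would break the anatomy are rejected", {
  ph <- small_phantom(speckle = 0)
  expect_error(apply_pathology(ph$volume, ph$truth,
                               pathology_spec("laser_scar", c(4, 30), 10, 60),
                               ph$spec),
               "exceeds")
  expect_error(pathology_spec("vessel_shadow", c(4, 20), 4, 1.5),
               "attenuation")
  expect_error(apply_pathology(ph$volume, ph$truth,
                               pathology_spec("edema", c(4, 70), 10, 400),
                               ph$spec),
               "out of the image")
})

test_that("cohorts are reproducible and recover the generating spread", {
  # degenerate variability: all subjects identical
  zero_var <- cohort_variability(0, 0, 0, 0, 0)
  co <- phantom_cohort(3, small_spec(speckle = 0.1), zero_var, seed = 5)
  expect_identical(co[[1]]$volume$intensity, co[[2]]$volume$intensity)
  expect_identical(co[[2]]$volume$intensity, co[[3]]$volume$intensity)

  # default variability, n = 10 subjects per cohort: the per-pixel SD of
  # the true TR thickness maps should recover the generating SD away from
  # the fovea.  A single 10-subject sample SD carries ~24% relative noise
  # (subject offsets are common across pixels), so average over five
  # independent cohorts at a fixed seed.
  v <- cohort_variability()
  gen_sd <- sqrt(v$ir_sd_um^2 + v$onl_sd_um^2 + v$ise_sd_um^2)
  corner_sd <- mean(sapply(41:45, function(s) {
    co <- phantom_cohort(10, small_spec(speckle = 0), seed = s)
    maps <- lapply(co, function(sub) thickness_map(sub$truth, "TR"))
    mean(build_atlas(maps)$sd[1:2, 1:10])
  }))
  expect_gt(corner_sd / gen_sd, 0.8)
  expect_lt(corner_sd / gen_sd, 1.2)

  coA <- phantom_cohort(3, small_spec(speckle = 0.1), seed = 5)
  coB <- phantom_cohort(3, small_spec(speckle = 0.1), seed = 6)
  expect_false(identical(coA[[1]]$volume$intensity, coB[[1]]$volume$intensity))
})
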