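test_that("identical seeds give bit-identical phantoms", {
  a <- make_phantom(tiny_spec(seed = 11))
  b <- make_phantom(tiny_spec(seed = 11))
  expect_identical(a$lsfm$data, b$lsfm$data)
  expect_identical(a$truth_mask$data, b$truth_mask$data)
  expect_identical(a$vessel_mask$data, b$vessel_mask$data)
})

test_that("phantom generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(make_phantom(tiny_spec(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("noiseless vessel-free phantom has exact piecewise-constant means", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0))
  b <- set$background
  les <- set$truth_mask$data
  img <- set$lsfm$data
  expect_true(all(img[les] == b * set$spec$lesion_contrast))
  brain_only <- img > 0 & !les
  expect_true(all(img[brain_only] == b))
})

test_that("vessels are bright, thin, and disjoint from the lesion", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 8))
  expect_gt(sum(set$vessel_mask$data), 0)
  expect_equal(sum(set$vessel_mask$data & set$truth_mask$data), 0)
  expect_true(all(set$lsfm$data[set$vessel_mask$data] ==
                    set$background * set$spec$vessel_contrast))
})

test_that("voxelised truth volume matches the analytic ellipsoid within 2%", {
  # 300 um isotropic semiaxes on a 5 um grid: 60 voxels per semiaxis
  spec <- phantom_spec(grid_shape = c(217, 297, 217), spacing_um = c(5, 5, 5),
                       brain_semiaxes_um = c(500, 700, 500),
                       lesion_center_um = c(0, 250, 0),
                       lesion_semiaxes_um = c(300, 300, 300),
                       vessel_count = 0, noise_sigma = 0, seed = 1)
  set <- make_phantom(spec)
  analytic <- 4 / 3 * pi * 0.3^3
  expect_equal(set$truth_analytic_mm3, analytic)
  expect_lt(abs(set$truth_volume_mm3 - analytic) / analytic, 0.02)
})

test_that("shrink factors rescale the truth volume by exactly their product", {
  sk <- c(0.85, 0.80, 0.75)
  full <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0))
  shrunk <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0,
                                   shrink_factors = sk))
  expect_equal(shrunk$truth_analytic_mm3 / full$truth_analytic_mm3, prod(sk))
  expect_equal(shrunk$preshrink_analytic_mm3, full$truth_analytic_mm3)
  # voxelised volume tracks the analytic one
  expect_lt(abs(shrunk$truth_volume_mm3 - shrunk$truth_analytic_mm3) /
              shrunk$truth_analytic_mm3, 0.02)
})

test_that("a lesion specified outside the brain is rejected", {
  expect_error(tiny_spec(lesion_center_um = c(0, 480, 0)), "inside the brain")
})

test_that("MRI derivation reproduces truth at native thickness and overestimates with edema", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0))
  truth <- mask_volume(set$truth_mask)$volume_mm3
  dz_mm <- set$truth_mask$spacing_um[1] / 1000

  native <- derive_mri(set, slice_thickness_mm = dz_mm, edema_dilation_um = 0)
  expect_equal(slice_volume(native$slices)$volume_mm3, truth, tolerance = 1e-9)

  coarse <- derive_mri(set, slice_thickness_mm = 0.2, edema_dilation_um = 0)
  expect_equal(slice_volume(coarse$slices)$volume_mm3, truth, tolerance = 0.02)

  edema <- derive_mri(set, slice_thickness_mm = dz_mm, edema_dilation_um = 50)
  expect_gt(slice_volume(edema$slices)$volume_mm3, truth)

  expect_error(derive_mri(set, slice_thickness_mm = dz_mm / 2), "axial spacing")
})

test_that("an empty lesion yields all-zero MRI areas", {
  spec <- tiny_spec(noise_sigma = 0, vessel_count = 0,
                    lesion_semiaxes_um = c(4, 4, 4),
                    lesion_center_um = c(5, 195, 5))  # between voxel centres
  set <- make_phantom(spec)
  expect_equal(sum(set$truth_mask$data), 0)
  mri <- derive_mri(set, slice_thickness_mm = 0.2)
  expect_true(all(mri$slices$areas_mm2 == 0))
})

test_that("histology slice series converges to voxel volume at native interval", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0))
  truth <- mask_volume(set$truth_mask)$volume_mm3
  dz_mm <- set$truth_mask$spacing_um[1] / 1000
  s <- derive_histology(set, thickness_mm = dz_mm, interval_mm = dz_mm)
  expect_equal(slice_volume(s)$volume_mm3, truth, tolerance = 1e-9)
  expect_equal(s$thickness_mm, dz_mm)  # interval recorded as the multiplier
})

test_that("doubling the histology interval halves the section count (+-1)", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0))
  n1 <- length(derive_histology(set, interval_mm = 0.1)$areas_mm2)
  n2 <- length(derive_histology(set, interval_mm = 0.2)$areas_mm2)
  expect_lte(abs(n1 - 2 * n2), 2)
})

test_that("a lesion thinner than the interval can be missed entirely", {
  # lesion 40 um thick in z, centred between sampled planes 200 um apart
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0,
                                lesion_semiaxes_um = c(40, 140, 130)))
  expect_gt(set$truth_volume_mm3, 0)
  zc <- set$spec$lesion_center_um[1] - set$truth_mask$origin_um[1]  # um from plane 1
  s <- derive_histology(set, thickness_mm = 0.05, interval_mm = 0.2,
                        offset_mm = (zc + 100) %% 200 / 1000)
  expect_true(all(s$areas_mm2 == 0))
})

test_that("speckle derivation is seeded and balanced outside the stroke area", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0))
  a <- derive_speckle(set, n_frames = 5, frame_shape = c(48, 48))
  b <- derive_speckle(set, n_frames = 5, frame_shape = c(48, 48))
  expect_identical(a$baseline$frames, b$baseline$frames)
  expect_identical(a$post$frames, b$post$frames)

  spk <- derive_speckle(set, n_frames = 300, frame_shape = c(48, 48),
                        contrast_ratio = 1.5)
  kb <- contrast_map(spk$baseline, 7)
  kp <- contrast_map(spk$post, 7)
  out <- !spk$stroke_area_px
  # outside the stroke area the two stacks are statistically identical
  expect_lt(abs(mean(kp$k[out]) - mean(kb$k[out])) / mean(kb$k[out]), 0.02)
})

test_that("unit contrast ratio makes post indistinguishable from baseline in expectation", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 0))
  spk <- derive_speckle(set, n_frames = 300, frame_shape = c(48, 48),
                        contrast_ratio = 1)
  kb <- contrast_map(spk$baseline, 7)
  kp <- contrast_map(spk$post, 7)
  inside <- spk$stroke_area_px
  expect_gt(sum(inside), 0)
  expect_lt(abs(mean(kp$k[inside]) - mean(kb$k[inside])) / mean(kb$k[inside]), 0.03)
})
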