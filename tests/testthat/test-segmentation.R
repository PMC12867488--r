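test_that("nearest-rank percentile matches its definition on simple cases", {
  const <- voxel_grid(array(7, c(10, 10, 10)), c(1, 1, 1))
  rule <- threshold_rule(50, roi_box(c(0, 0, 0), c(10, 10, 10)))
  expect_equal(contralateral_threshold(const, rule), 7)

  v <- voxel_grid(array(sample(1:100), c(10, 10, 1)), c(1, 1, 1))
  roi <- roi_box(c(0, 0, 0), c(10, 10, 1))  # exactly 100 voxels: no warning
  expect_equal(contralateral_threshold(v, threshold_rule(99, roi)), 99)
  expect_equal(contralateral_threshold(v, threshold_rule(100, roi)), 100)
})

test_that("nearest-rank percentile matches full-sort brute force on random ROIs", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(50:10000, 1)
    x <- rnorm(n, 100, 25)
    p <- runif(1, 0.5, 100)
    expect_identical(nearest_rank_percentile(x, p),
                     unname(quantile(x, p / 100, type = 1)))
  }
})

test_that("empty and undersized ROIs are handled", {
  v <- voxel_grid(array(1, c(5, 5, 5)), c(1, 1, 1))
  expect_error(roi_box(c(0, 0, 0), c(0, 5, 5)))
  expect_error(contralateral_threshold(
    v, threshold_rule(99, roi_box(c(0, 0, 0), c(6, 5, 5)))), "bounds")
  expect_warning(contralateral_threshold(
    v, threshold_rule(99, roi_box(c(0, 0, 0), c(2, 2, 2)))), "unstable")
})

test_that("component labelling matches adjacency expectations at each connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[4, 4, 4] <- TRUE
  cs <- label_components(mask_grid(m, c(1, 1, 1)), 26)
  expect_equal(nrow(cs$summary), 2)
  expect_equal(cs$summary$voxels, c(1L, 1L))

  # two voxels sharing only a corner
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(nrow(label_components(mask_grid(m, c(1, 1, 1)), 26)$summary), 1)
  expect_equal(nrow(label_components(mask_grid(m, c(1, 1, 1)), 18)$summary), 2)
  expect_equal(nrow(label_components(mask_grid(m, c(1, 1, 1)), 6)$summary), 2)

  # sharing only an edge
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  expect_equal(nrow(label_components(mask_grid(m, c(1, 1, 1)), 18)$summary), 1)
  expect_equal(nrow(label_components(mask_grid(m, c(1, 1, 1)), 6)$summary), 2)

  empty <- label_components(mask_grid(array(FALSE, c(3, 3, 3)), c(1, 1, 1)))
  expect_equal(nrow(empty$summary), 0)
})

test_that("labelling agrees with the graph-components oracle on random volumes", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (case in 1:5) {
    m <- array(runif(12^3) < 0.3, c(12, 12, 12))
    for (conn in c(6, 18, 26)) {
      ours <- label_components(mask_grid(m, c(1, 1, 1)), conn)$labels
      expect_identical(canon_labels(ours), canon_labels(cc_oracle(m, conn)))
    }
  }
})

test_that("component summaries are size-sorted with physical centroids", {
  m <- array(FALSE, c(5, 5, 5))
  m[1:2, 1, 1] <- TRUE          # 2 voxels
  m[4:5, 4:5, 4:5] <- TRUE      # 8 voxels
  cs <- label_components(mask_grid(m, c(10, 10, 10)), 26)
  expect_equal(cs$summary$voxels, c(8L, 2L))
  # centroid of the 2-voxel bar: z indices 0,1 -> mean 0.5 -> origin + 5 um
  expect_equal(cs$summary$centroid_z_um[2], -20 + 5)
})

test_that("core selection takes the largest component with a deterministic tie-break", {
  m <- array(FALSE, c(10, 5, 5))
  m[1:2, 1:5, 1:5] <- TRUE        # 50 voxels, low z
  m[9, 1:4, 1:5] <- TRUE          # 20 voxels
  cs <- label_components(mask_grid(m, c(1, 1, 1)), 26)
  expect_equal(select_core(cs, "largest"), 1L)
  expect_equal(cs$summary$voxels[1], 50L)

  # seed strategy picks the component containing the seed point
  seed_um <- c(8 - (10 - 1) / 2, 1 - 2, 2 - 2)  # voxel (9,2,3) in um
  expect_equal(select_core(cs, seed_um), 2L)
  expect_error(select_core(cs, c(100, 0, 0)), "outside")

  # equal sizes: the smaller-centroid-z component wins, independent of the
  # order in which components are encountered (checked via a z mirror)
  m2 <- array(FALSE, c(9, 3, 3))
  m2[1:2, 1, 1] <- TRUE
  m2[7:8, 2, 2] <- TRUE
  for (arr in list(m2, m2[9:1, , , drop = FALSE])) {
    cs2 <- label_components(mask_grid(arr, c(1, 1, 1)), 26)
    expect_equal(cs2$summary$voxels, c(2L, 2L))
    expect_lt(cs2$summary$centroid_z_um[1], cs2$summary$centroid_z_um[2])
    expect_equal(select_core(cs2, "largest"), 1L)
  }
})

test_that("binarization thresholds and opening behave at the extremes", {
  set <- make_phantom(tiny_spec(noise_sigma = 0.05, vessel_count = 3, seed = 4))
  vol <- set$lsfm
  empty <- binarize_and_exclude_vessels(vol, max(vol$data) + 1, 30)
  expect_equal(sum(empty$data), 0)

  plain <- binarize_and_exclude_vessels(vol, 150, 0)
  expect_identical(plain$data, vol$data >= 150)
})

test_that("opening removes 10 um vessels but keeps the lesion at 30 um detail size", {
  set <- make_phantom(tiny_spec(noise_sigma = 0, vessel_count = 8, seed = 9))
  thr <- 150  # between background 100 and lesion 200, below vessel 300
  opened <- binarize_and_exclude_vessels(set$lsfm, thr, 30)
  expect_equal(sum(opened$data & set$vessel_mask$data), 0)
  retained <- sum(opened$data & set$truth_mask$data) / sum(set$truth_mask$data)
  expect_gte(retained, 0.95)
})

test_that("segmented voxel count is monotone in threshold and detail size", {
  set <- make_phantom(tiny_spec(noise_sigma = 0.1, vessel_count = 4, seed = 2))
  vol <- set$lsfm
  counts_thr <- vapply(c(120, 140, 160, 190),
                       function(t) sum(binarize_and_exclude_vessels(vol, t, 0)$data),
                       numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  # opening is anti-extensive and monotone in the ball diameter up to
  # voxelisation of the ball (discrete balls of growing radius are not
  # perfectly nested, so a few boundary voxels may flicker)
  counts_det <- vapply(c(0, 20, 30, 50),
                       function(d) sum(binarize_and_exclude_vessels(vol, 150, d)$data),
                       numeric(1))
  expect_true(all(counts_det <= counts_det[1]))
  expect_true(all(diff(counts_det) <= 1e-3 * counts_det[1]))
})

test_that("end-to-end segmentation recovers the phantom lesion and is deterministic", {
  set <- make_phantom(tiny_spec(seed = 21))
  rule <- phantom_rule(set)
  seg1 <- segment_lesion(set$lsfm, rule)
  seg2 <- segment_lesion(set$lsfm, rule)
  expect_true(seg1$found)
  expect_identical(seg1$mask$data, seg2$mask$data)
  v <- mask_volume(seg1$mask)$volume_mm3
  expect_lt(abs(v - set$truth_volume_mm3) / set$truth_volume_mm3, 0.05)
  # provenance: parameters and threshold are recorded
  expect_equal(seg1$params$percentile, 99)
  expect_equal(seg1$params$threshold, seg1$threshold_value)
  expect_true(seg1$selected_id %in% seg1$all_components$id)
})

test_that("a volume with no surviving supra-threshold structure reports no lesion, without error", {
  a <- array(5, c(8, 8, 8))
  a[2, 2, 2] <- 6  # lone bright voxel; the 40 um opening removes it
  vol <- voxel_grid(a, c(10, 10, 10))
  seg <- suppressWarnings(segment_lesion(
    vol, threshold_rule(100, roi_box(c(0, 0, 0), c(8, 8, 8))),
    detail_size_um = 40))
  expect_false(seg$found)
  expect_true(is.na(seg$selected_id))
  expect_equal(sum(seg$mask$data), 0)
})

test_that("threshold refinement is the identity at zero and monotone upward", {
  set <- make_phantom(tiny_spec(noise_sigma = 0.05, vessel_count = 0, seed = 3))
  rule <- phantom_rule(set)
  seg <- segment_lesion(set$lsfm, rule)
  same <- refine_threshold(set$lsfm, seg, 0)
  expect_identical(same$mask$data, seg$mask$data)

  up <- refine_threshold(set$lsfm, seg, 5)
  expect_lte(sum(up$mask$data), sum(seg$mask$data))
  expect_equal(up$params$refine_delta_steps, 5L)

  # +-1 step changes the recovered volume by < 2% on a noiseless phantom
  for (d in c(-1, 1)) {
    r <- refine_threshold(set$lsfm, seg, d)
    expect_lt(abs(mask_volume(r$mask)$volume_mm3 -
                    mask_volume(seg$mask)$volume_mm3) /
                mask_volume(seg$mask)$volume_mm3, 0.02)
  }
  expect_error(refine_threshold(set$lsfm, seg, 11), "delta")
})

test_that("distance-transform ball morphology matches the explicit-offset oracle", {
  brute <- function(m, sp, r, erode) {
    dims <- dim(m)
    rr <- floor(r / sp)
    g <- expand.grid(dz = -rr[1]:rr[1], dy = -rr[2]:rr[2], dx = -rr[3]:rr[3])
    g <- g[(g$dz * sp[1])^2 + (g$dy * sp[2])^2 + (g$dx * sp[3])^2 <= r^2 + 1e-9, ]
    out <- array(FALSE, dims)
    for (z in 1:dims[1]) for (y in 1:dims[2]) for (x in 1:dims[3]) {
      qz <- z + g$dz; qy <- y + g$dy; qx <- x + g$dx
      inb <- qz >= 1 & qz <= dims[1] & qy >= 1 & qy <= dims[2] & qx >= 1 & qx <= dims[3]
      vals <- m[cbind(qz[inb], qy[inb], qx[inb])]
      out[z, y, x] <- if (erode) m[z, y, x] && all(inb) && all(vals) else any(vals)
    }
    out
  }
  set.seed(31)
  for (case in 1:4) {
    sp <- list(c(10, 10, 10), c(15, 5, 5), c(12, 8, 8), c(10, 2, 2))[[case]]
    m <- array(runif(12 * 11 * 10) < 0.35, c(12, 11, 10))
    r <- c(8, 15, 22, 30)[case]
    for (er in c(TRUE, FALSE))
      expect_identical(strokevol:::ball_morph(m, sp, r, er), brute(m, sp, r, er))
  }
})
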