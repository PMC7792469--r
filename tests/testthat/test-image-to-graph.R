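test_that("threshold segmentation recovers an analytic cylinder volume", {
  m <- cylinder_mask(r_mm = 2, spacing = 0.5, n_z = 80)
  vol <- voxel_volume(ifelse(m, 400, 0), 0.5)
  seg <- segment_vessels(vol, hu_threshold = 200,
                         seeds = matrix(c(5.75, 5.75, 10), 1))
  nvox <- sum(seg$artery_mask) + sum(seg$aorta_mask)
  expected <- pi * 4^2 * 80   # pi r^2 L in voxel units (r = 4 voxels)
  expect_lt(abs(nvox - expected) / expected, 0.10)

  expect_error(segment_vessels(vol, hu_threshold = 500,
                               seeds = matrix(c(5.75, 5.75, 10), 1)),
               "empty segmentation|below threshold")
  expect_error(segment_vessels(vol, hu_threshold = 200,
                               seeds = matrix(c(0.5, 0.5, 0.5), 1)),
               "below threshold")
})

test_that("skeleton of a straight cylinder is centred with correct radius", {
  m <- cylinder_mask(r_mm = 2, spacing = 0.5, n_z = 80)
  sk <- skeletonize_and_measure(m, 0.5, origin = c(0, 0, 0))
  expect_length(sk$chains, 1)
  ch <- sk$chains[[1]]
  # interior centerline within one voxel of the true axis (x = y = 5.75 mm);
  # the first/last couple of voxels at the open tube ends may wander
  n <- nrow(ch$pos_mm)
  interior <- ch$pos_mm[4:(n - 3), , drop = FALSE]
  expect_lt(max(abs(interior[, 1] - 5.75)), 0.5)
  expect_lt(max(abs(interior[, 2] - 5.75)), 0.5)
  med_r <- median(ch$radius_mm)
  expect_lt(abs(med_r - 2), 0.25)

  expect_error(skeletonize_and_measure(array(FALSE, c(3, 3, 3)), 0.5),
               "fewer than 2")
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_error(skeletonize_and_measure(one, 0.5), "fewer than 2")
})

test_that("Y-bifurcation phantom yields one junction and two terminals", {
  g <- make_coronary_tree(seed = 4, n_generations = 2)  # trunk + 2 daughters
  ph <- make_voxel_phantom(g, seed = 4)
  ex <- extract_graph(ph$volume, seeds = matrix(ph$aorta_seed, 1))
  expect_equal(nrow(ex$segments), 3)
  expect_equal(sum(ex$nodes$kind == "junction"), 1)
  expect_equal(sum(ex$nodes$kind == "terminal"), 2)
  expect_equal(sum(ex$nodes$kind == "ostium"), 1)
})

test_that("preprocessing drops slices and suppresses far bright structures", {
  g <- make_coronary_tree(seed = 5)
  ph <- make_voxel_phantom(g, seed = 5, distractor = TRUE)
  d <- dim(ph$volume$intensities)

  v <- preprocess_volume(ph$volume, list(drop_slices = 10))
  expect_equal(dim(v$intensities)[3], d[3] - 10)
  expect_equal(v$origin[3], ph$volume$origin[3] + 10 * 0.5)
  expect_error(preprocess_volume(ph$volume, list(drop_slices = d[3])),
               "slices")

  # distractor blob suppressed to background, arterial voxels unchanged
  v2 <- preprocess_volume(ph$volume)
  dc <- ph$artefacts$distractor
  ijk <- round((dc - ph$volume$origin) / ph$volume$spacing) + 1
  box <- v2$intensities[(ijk[1] - 6):(ijk[1] + 6),
                        (ijk[2] - 6):(ijk[2] + 6),
                        (ijk[3] - 6):(ijk[3] + 6)]
  expect_lte(max(box), 200)
  ex <- extract_graph(v2, seeds = matrix(ph$aorta_seed, 1))
  expect_equal(nrow(ex$segments), nrow(g$segments))

  # identity when nothing is outside the ROI and k = 0
  ph2 <- make_voxel_phantom(g, seed = 5)
  v3 <- preprocess_volume(ph2$volume)
  expect_equal(v3$intensities, ph2$volume$intensities)
})

test_that("build_artery_graph rejects cyclic skeleton attachments", {
  sk <- structure(list(chains = list(
    list(lin0 = c(0L, 1L), ijk = rbind(c(1, 1, 1), c(2, 1, 1)),
         radius_mm = c(1.5, 1.5), attach = c(2, 1), skel_idx = c(NA, 1L)),
    list(lin0 = c(5L, 6L), ijk = rbind(c(1, 2, 1), c(2, 2, 1)),
         radius_mm = c(1.5, 1.5), attach = c(1, 1), skel_idx = c(NA, 2L))),
    spacing = rep(0.5, 3), origin = c(0, 0, 0), dims = c(4L, 4L, 4L)),
    class = "skeleton")
  expect_error(build_artery_graph(sk), "cycle")
})

test_that("volume I/O roundtrips (NIfTI and raw + JSON sidecar)", {
  g <- make_coronary_tree(seed = 6, n_generations = 2)
  vol <- make_voxel_phantom(g, seed = 6)$volume
  tn <- withr::local_tempfile(fileext = ".nii.gz")
  nifti_write(vol, tn)
  v2 <- nifti_read(tn)
  expect_equal(dim(v2$intensities), dim(vol$intensities))
  expect_lt(max(abs(v2$intensities - vol$intensities)), 1e-3)
  expect_equal(v2$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, vol$origin, tolerance = 1e-4)

  tr <- withr::local_tempfile()
  write_volume_raw(vol, tr)
  v3 <- read_volume_raw(tr)
  expect_lt(max(abs(v3$intensities - vol$intensities)), 1e-3)
  expect_equal(v3$spacing, vol$spacing)
})
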