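# Threshold segmentation, artifact removal, plate split, and region
# partition.

test_that("binarize thresholds exactly and flags degenerate cases", {
  v <- array(50, c(12, 12, 12))
  v[4:9, 4:9, 4:9] <- 200
  vol <- gray_volume(v, 5)
  m <- binarize(vol, 125)
  expect_identical(m$values, v >= 125)
  expect_warning(me <- binarize(vol, 300), "above the global maximum")
  expect_false(any(me$values))
  expect_error(binarize(gray_volume(array(7, c(4, 4, 4)), 5), "auto"),
               "constant")
  # idempotence on the 0/1 cast
  m2 <- binarize(gray_volume(array(as.numeric(m$values), dim(v)), 5), 0.5)
  expect_identical(m2$values, m$values)
})

test_that("binarize is monotone in the threshold", {
  set.seed(1)
  v <- array(runif(8000, 0, 255), c(20, 20, 20))
  vol <- gray_volume(v, 5)
  thr <- c(60, 120, 180)
  masks <- lapply(thr, function(t) binarize(vol, t)$values)
  expect_true(all(masks[[2]][masks[[3]]]))
  expect_true(all(masks[[1]][masks[[2]]]))
})

test_that("auto threshold recovers the phantom material (Dice >= 0.98)", {
  ph <- tiny_phantom()
  m <- binarize(ph$volume, "auto")
  expect_gte(dice(m$values, ph$truth$label > 0L), 0.98)
  thr <- m$provenance$threshold
  expect_gt(thr, ph$truth$config$tissue_gray)
  expect_lt(thr, ph$truth$config$bone_gray)
})

test_that("artifact removal keeps large components only, never adds, and is idempotent", {
  v <- array(FALSE, c(40, 40, 20))
  v[5:35, 5:35, 5:15] <- TRUE      # large block
  v[2, 2, 2] <- TRUE               # speck 1
  v[38:39, 38, 18] <- TRUE         # speck 2
  m <- binary_mask(v, 5)
  r <- remove_artifacts(m, 100)
  expect_equal(sum(r$values), 31 * 31 * 11)
  expect_true(all(v[r$values]))
  expect_identical(remove_artifacts(r, 100)$values, r$values)
  e <- binary_mask(array(FALSE, c(4, 4, 4)), 5)
  expect_identical(remove_artifacts(e, 10)$values, e$values)
})

test_that("speck artifacts are removed from the phantom (Dice >= 0.99)", {
  ph <- tiny_phantom()
  m <- binarize(ph$volume, "auto")
  r <- remove_artifacts(m, 40)
  expect_gte(dice(r$values, ph$truth$label > 0L), 0.99)
  # the recorded speck voxels are gone
  expect_false(any(r$values[ph$truth$specks]))
})

test_that("two parallel slabs split exactly into upper and lower plates", {
  v <- array(FALSE, c(30, 30, 24))
  v[5:25, 5:25, 4:7] <- TRUE    # lower (tympanic)
  v[5:25, 5:25, 15:18] <- TRUE  # upper (vestibular)
  m <- binary_mask(v, 5)
  fr <- spiral_frame(center_um = c(70, 70, 120))
  sp <- split_plates(m, fr)
  upper <- array(FALSE, dim(v)); upper[5:25, 5:25, 15:18] <- TRUE
  expect_identical(sp$vp$values, upper)
  expect_identical(sp$tp$values, v & !upper)
})

test_that("plate split is an exact partition and matches construction labels", {
  ph <- tiny_phantom()
  gt <- phantom_material_mask(ph$truth)
  sp <- split_plates(gt, ph$truth$frame)
  expect_false(any(sp$vp$values & sp$tp$values))
  expect_identical(sp$vp$values | sp$tp$values, gt$values)
  lab <- ph$truth$label
  plate_sel <- lab == 1L | lab == 2L   # pillars are legitimately ambiguous
  rec <- array(0L, dim(lab))
  rec[sp$vp$values] <- 1L
  rec[sp$tp$values] <- 2L
  agree <- sum(rec[plate_sel] == lab[plate_sel]) / sum(plate_sel)
  expect_gte(agree, 0.99)
})

test_that("region partition is exact and matches construction labels", {
  ph <- tiny_phantom()
  gt <- phantom_material_mask(ph$truth)
  rg <- partition_regions(gt, ph$truth$frame, c(360, 630))
  expect_identical(rg$labels > 0L, gt$values)
  mat <- ph$truth$label > 0L
  agree <- sum(rg$labels[mat] == ph$truth$region[mat]) / sum(mat)
  expect_gte(agree, 0.99)
  expect_error(partition_regions(gt, ph$truth$frame, c(360, 1080)),
               "outside the observed angular range")
  expect_error(partition_regions(gt, ph$truth$frame, c(-10, 360)), "bound")
})
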