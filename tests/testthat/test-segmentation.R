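test_that("a solid block filling the volume masks everything", {
  g <- VoxelGrid(array(200L, c(3, 12, 12)), 0.001, 8L)
  g@voxels[1, 1, 1] <- 10L # ensure a non-degenerate histogram
  mask <- makeLeafMask(g, closingRadius = 1)
  expect_true(all(voxels(mask)[-1]))
  expect_equal(role(mask), "mask")
})

test_that("the clean leaf phantom mask is recovered exactly, holes filled", {
  ph <- generateLeafPhantom(dicotPhantomSpec(seed = 5))
  mask <- makeLeafMask(ph$grid)
  expect_identical(unname(voxels(mask)), unname(voxels(ph$mask)))
})

test_that("mask area grows monotonically with the closing radius", {
  ph <- generateLeafPhantom(dicotPhantomSpec(seed = 6, noiseSD = 12))
  areas <- vapply(c(1, 2, 4), function(r)
    sum(voxels(makeLeafMask(ph$grid, closingRadius = r))), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("an empty mask slice raises an error naming the slice", {
  a <- array(200L, c(3, 16, 16))
  a[2, , ] <- 0L # slice 2 entirely background
  g <- VoxelGrid(a, 0.001, 8L)
  err <- tryCatch(makeLeafMask(g), error = identity)
  expect_s3_class(err, "leafspace_empty_mask")
  expect_match(conditionMessage(err), "2")
})

test_that("disjoint air and mask composite to an empty airspace", {
  air <- array(FALSE, c(2, 8, 8)); air[, 1:4, ] <- TRUE
  mask <- array(FALSE, c(2, 8, 8)); mask[, 5:8, ] <- TRUE
  comp <- extractAirspace(BinaryVolume(air, 0.001, role = "airspace"),
                          BinaryVolume(mask, 0.001, role = "mask"))
  expect_false(any(voxels(comp)))
  expect_equal(role(comp), "composite")
})

test_that("compositing volumes of different shapes raises a classed error", {
  a <- BinaryVolume(array(TRUE, c(2, 8, 8)), 0.001, role = "airspace")
  m <- BinaryVolume(array(TRUE, c(2, 8, 9)), 0.001, role = "mask")
  expect_error(extractAirspace(a, m), class = "leafspace_shape_mismatch")
})

test_that("noise removal drops isolated voxels and keeps a 5x5x5 block", {
  a <- array(FALSE, c(20, 20, 20))
  a[3, 3, 3] <- TRUE                # equivalent diameter 1.24 < 3 -> removed
  a[8:12, 8:12, 8:12] <- TRUE       # equivalent diameter 6.2 >= 3 -> kept
  expect_gte((6 * 125 / pi)^(1 / 3), 3) # the size rule the block must beat
  v <- BinaryVolume(a, 0.001, role = "composite")
  out <- removeSmallParticles(v, factor = 3)
  expect_false(voxels(out)[3, 3, 3])
  expect_true(all(voxels(out)[8:12, 8:12, 8:12]))
  expect_equal(sum(voxels(out)), 125)
})

test_that("noise removal also fills small solid inclusions and is idempotent", {
  a <- array(TRUE, c(12, 12, 12))
  a[6, 6, 6] <- FALSE # one-voxel tissue speck inside air -> filled
  v <- BinaryVolume(a, 0.001, role = "composite")
  once <- removeSmallParticles(v, factor = 3)
  expect_true(all(voxels(once)))
  twice <- removeSmallParticles(once, factor = 3)
  expect_identical(voxels(twice), voxels(once))
})

test_that("per-slice filtering uses the 2D equivalent-diameter rule", {
  a <- array(FALSE, c(3, 20, 20))
  a[2, 5, 5] <- TRUE           # 2D eq. diameter 1.13 -> removed
  a[2, 10:14, 10:14] <- TRUE   # 2D eq. diameter 5.6 -> kept
  out <- removeSmallParticles(BinaryVolume(a, 0.001, role = "composite"),
                              factor = 3, filter2d = TRUE)
  expect_false(voxels(out)[2, 5, 5])
  expect_equal(sum(voxels(out)), 25)
})

test_that("cropping to the full extent is the identity", {
  ph <- generateLeafPhantom(dicotPhantomSpec(seed = 2))
  d <- dim(voxels(ph$airspace))
  crop <- cropROI(ph$airspace, c(1, 1, d[2], d[3]))
  expect_identical(unname(voxels(crop)), unname(voxels(ph$airspace)))
})

test_that("a 200x200 crop of a 400x400 stack has shape (z, 200, 200)", {
  g <- VoxelGrid(array(0L, c(2, 400, 400)), 0.001, 8L)
  expect_equal(dim(cropROI(g, c(51, 101, 200, 200))), c(2, 200, 200))
})

test_that("out-of-bounds ROIs are rejected", {
  g <- VoxelGrid(array(0L, c(2, 40, 40)), 0.001, 8L)
  expect_error(cropROI(g, c(30, 30, 20, 20)), class = "leafspace_roi_bounds")
  expect_error(cropROI(g, c(0, 1, 10, 10)), class = "leafspace_roi_bounds")
})

test_that("area-weighted porosity over tiling ROIs equals the parent porosity", {
  # spongy target below the dicot default: sphere packing saturates earlier
  # in this smaller volume
  ph <- generateLeafPhantom(leafPhantomSpec(shape = c(60L, 120L, 120L),
                                            margin = 2L, seed = 9,
                                            spongy = list(
                                              sphereRadiusRange = c(3L, 8L),
                                              targetPorosity = 0.25)))
  air <- ph$airspace; mask <- ph$mask
  parent <- porosity(analyzeStack(air, mask))
  tiles <- list(c(1, 1, 60, 60), c(1, 61, 60, 60),
                c(61, 1, 60, 60), c(61, 61, 60, 60))
  num <- 0; den <- 0
  for (roi in tiles) {
    t <- analyzeStack(cropROI(air, roi), cropROI(mask, roi))
    num <- num + sum(poreRecords(t)$area_mm2)
    den <- den + sum(maskArea(t))
  }
  expect_equal(100 * num / den, parent, tolerance = 1e-12)
})
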