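test_that("phantom generation is bit-reproducible for a fixed seed", {
  a <- generateLeafPhantom(dicotPhantomSpec(seed = 12, noiseSD = 8))
  b <- generateLeafPhantom(dicotPhantomSpec(seed = 12, noiseSD = 8))
  expect_identical(voxels(a$grid), voxels(b$grid))
  expect_identical(voxels(a$airspace), voxels(b$airspace))
  c <- generateLeafPhantom(dicotPhantomSpec(seed = 13, noiseSD = 8))
  expect_false(identical(voxels(a$grid), voxels(c$grid)))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateLeafPhantom(dicotPhantomSpec(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("a zero-airspace spec yields zero-porosity truth", {
  spec <- leafPhantomSpec(shape = c(40L, 60L, 60L),
                          palisade = list(channelRadius = 2L, channelCount = 0L,
                                          layerFraction = 0.45),
                          spongy = list(sphereRadiusRange = c(2L, 4L),
                                        targetPorosity = 0),
                          seed = 1)
  ph <- generateLeafPhantom(spec)
  expect_equal(ph$truth@analytic$porosity_pct, 0)
  expect_equal(ph$truth@discrete$porosity_pct, 0)
  expect_false(any(voxels(ph$airspace)))
})

test_that("discrete truth porosity approximates analytic truth on the dicot preset", {
  ph <- generateLeafPhantom(dicotPhantomSpec(seed = 8))
  expect_lt(abs(ph$truth@analytic$porosity_pct -
                ph$truth@discrete$porosity_pct), 1)
})

test_that("channel lateral surface in the discrete truth follows the chain-code rule", {
  spec <- leafPhantomSpec(shape = c(40L, 80L, 80L),
                          palisade = list(channelRadius = 4L, channelCount = 5L,
                                          layerFraction = 0.5),
                          spongy = list(sphereRadiusRange = c(2L, 3L),
                                        targetPorosity = 0),
                          seed = 14)
  ph <- generateLeafPhantom(spec)
  res <- voxelSize(ph$airspace)
  # recompute the per-slice perimeters with the independent oracle
  slices <- which(vapply(seq_len(dim(voxels(ph$airspace))[1]),
                         function(i) any(voxels(ph$airspace)[i, , ]),
                         logical(1)))
  expected <- sum(vapply(slices, function(i)
    sum(oraclePerimeters(voxels(ph$airspace)[i, , ])) * res, numeric(1))) * res
  expect_equal(ph$truth@discrete$lateral_surface_mm2, expected,
               tolerance = 1e-9)
})

test_that("sphere phantom analytic truth matches exact sums over the placed spheres", {
  sp <- generateSpherePhantom(shape = c(96L, 96L, 96L), seed = 6,
                              radiusRange = c(10L, 14L), targetPorosity = 0.2)
  tr <- sp$truth
  expect_lt(abs(tr@analytic$porosity_pct - tr@discrete$porosity_pct), 1.5)
  expect_gt(tr@analytic$sphere_count, 1)
  # porosity reached the requested target
  expect_gt(tr@discrete$porosity_pct, 19)
})

test_that("infeasible packings raise a classed error rather than hanging", {
  expect_error(
    generateSpherePhantom(shape = c(24L, 24L, 24L), radiusRange = c(8L, 9L),
                          targetPorosity = 0.6, seed = 1),
    class = "leafspace_infeasible_packing")
})

test_that("the section phantom with no holes has zero porosity truth", {
  ph <- generateSectionPhantom(holeCount = 0L, seed = 2)
  expect_equal(ph$truth@discrete$porosity_pct, 0)
  expect_false(any(ph$airspace))
})

test_that("mean porosity over many random sections approaches the 3D porosity", {
  ph <- generateLeafPhantom(dicotPhantomSpec(seed = 4))
  air <- voxels(ph$airspace); mask <- voxels(ph$mask)
  p3d <- sum(air) / sum(mask)
  secs <- suppressWarnings(sampleRandomSections(ph$airspace, 200, seed = 50))
  idx <- attr(secs, "indices")
  perSec <- vapply(seq_along(idx), function(i)
    sum(secs[[i]]) / sum(mask[idx[i], , ]), numeric(1))
  se <- sd(perSec) / sqrt(length(perSec))
  expect_lt(abs(mean(perSec) - p3d), 2 * se + 1e-6)
})

test_that("random sections are reproducible and honour the axis argument", {
  v <- BinaryVolume(array(FALSE, c(10, 20, 30)), 1, role = "airspace")
  s1 <- sampleRandomSections(v, 4, seed = 7)
  s2 <- sampleRandomSections(v, 4, seed = 7)
  expect_identical(attr(s1, "indices"), attr(s2, "indices"))
  expect_equal(dim(s1[[1]]), c(20, 30))
  expect_equal(dim(sampleRandomSections(v, 2, seed = 1, axis = "y")[[1]]),
               c(10, 30))
  expect_equal(dim(sampleRandomSections(v, 2, seed = 1, axis = "x")[[1]]),
               c(10, 20))
})

test_that("sections of an all-air volume are all true", {
  v <- BinaryVolume(array(TRUE, c(6, 8, 8)), 1, role = "airspace")
  secs <- sampleRandomSections(v, 3, seed = 3)
  expect_true(all(vapply(secs, all, logical(1))))
})

test_that("oversampling sections falls back to replacement with a warning", {
  v <- BinaryVolume(array(TRUE, c(4, 6, 6)), 1, role = "airspace")
  expect_warning(secs <- sampleRandomSections(v, 10, seed = 2), "replacement")
  expect_length(secs, 10)
})

test_that("invalid phantom specs are rejected", {
  expect_error(leafPhantomSpec(epidermisThickness = 70L),
               class = "leafspace_bad_spec")
  expect_error(leafPhantomSpec(palisade = list(channelRadius = 5L,
                                               channelCount = 2L,
                                               layerFraction = 1.2)),
               class = "leafspace_bad_spec")
})

test_that("rendering specks corrupt the grayscale but never the truth volumes", {
  clean <- generateLeafPhantom(dicotPhantomSpec(seed = 15))
  speck <- generateLeafPhantom(dicotPhantomSpec(seed = 15, speckCount = 40L))
  expect_identical(voxels(clean$airspace), voxels(speck$airspace))
  expect_identical(voxels(clean$mask), voxels(speck$mask))
  expect_false(identical(voxels(clean$grid), voxels(speck$grid)))
})
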