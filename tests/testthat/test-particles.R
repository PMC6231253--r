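test_that("a boundary of 8 straight and 4 diagonal steps measures 8 + 4*sqrt(2)", {
  # 5x5 square with its four corner pixels cut off: the boundary walk is
  # 4 runs of 2 straight steps and 4 diagonal corner cuts
  oct <- matrix(TRUE, 5, 5)
  oct[1, 1] <- oct[1, 5] <- oct[5, 1] <- oct[5, 5] <- FALSE
  p <- particlePerimeter(oct)
  expect_equal(p - 4, 8 + 4 * sqrt(2), tolerance = 1e-12) # the step sum
  expect_equal(p, oraclePerimeters(oct), tolerance = 1e-12)
})

test_that("a single pixel has perimeter 4", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(particlePerimeter(m), 4)
})

test_that("axis-aligned rectangles measure exactly 2w + 2h", {
  for (w in c(2, 5, 9)) for (h in c(3, 7)) {
    m <- matrix(FALSE, h + 4, w + 4)
    m[3:(h + 2), 3:(w + 2)] <- TRUE
    expect_equal(particlePerimeter(m), 2 * w + 2 * h)
  }
})

test_that("the digitized disc perimeter equals the chain-code oracle to 1e-9", {
  disc <- digitDisc(20)
  expect_equal(particlePerimeter(disc), oraclePerimeters(disc),
               tolerance = 1e-9)
})

test_that("pore perimeters include enclosed solid islands unless disabled", {
  ring <- matrix(FALSE, 11, 11)
  ring[3:9, 3:9] <- TRUE
  ring[5:7, 5:7] <- FALSE # 3x3 solid island inside the pore
  withHole <- particlePerimeter(ring, includeHoles = TRUE)
  outerOnly <- particlePerimeter(ring, includeHoles = FALSE)
  expect_equal(outerOnly, 2 * 7 + 2 * 7)
  expect_equal(withHole, outerOnly + 2 * 3 + 2 * 3)
  expect_equal(withHole, oraclePerimeters(ring), tolerance = 1e-12)
})

test_that("component labelling matches an independent flood-fill oracle", {
  set.seed(77)
  m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  for (conn in c(4L, 8L)) {
    lab <- labelSlice(m, conn)
    ours <- attr(lab, "nlabels")
    oracle <- attr(oracleLabel2d(m, conn), "n")
    expect_identical(ours, oracle)
  }
})

test_that("perimeters of random blobs match the oracle component by component", {
  for (seed in c(5, 17, 29)) {
    blob <- randomBlob(seed)
    res <- analyzeStack(
      BinaryVolume(array(blob, c(1, dim(blob))), 0.001, role = "composite"),
      BinaryVolume(array(TRUE, c(1, dim(blob))), 0.001, role = "mask"))
    ours <- sort(poreRecords(res)$perimeter_mm / 0.001)
    oracle <- sort(oraclePerimeters(blob))
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
})

test_that("k disjoint spanning channels give exactly k records on every slice", {
  k <- 3; nz <- 6
  air <- array(FALSE, c(nz, 30, 30))
  at <- list(c(6, 6), c(6, 22), c(22, 14))
  for (c0 in at)
    air[, (c0[1] - 2):(c0[1] + 2), (c0[2] - 2):(c0[2] + 2)] <- TRUE
  tab <- analyzeStack(BinaryVolume(air, 0.001, role = "composite"),
                      BinaryVolume(array(TRUE, dim(air)), 0.001, role = "mask"))
  perSlice <- table(poreRecords(tab)$slice)
  expect_equal(length(perSlice), nz)
  expect_true(all(perSlice == k))
})

test_that("an empty airspace yields an empty table and zero pores", {
  air <- BinaryVolume(array(FALSE, c(3, 10, 10)), 0.001, role = "composite")
  mask <- BinaryVolume(array(TRUE, c(3, 10, 10)), 0.001, role = "mask")
  tab <- analyzeStack(air, mask)
  expect_equal(nrow(poreRecords(tab)), 0L)
  expect_equal(poreCount(tab)$pores_2d, 0L)
})

test_that("areas and perimeters are calibrated by the voxel size", {
  air <- array(FALSE, c(1, 12, 12)); air[1, 4:7, 4:8] <- TRUE # 4x5 rectangle
  tab <- analyzeStack(BinaryVolume(air, 0.00275, role = "composite"),
                      BinaryVolume(array(TRUE, dim(air)), 0.00275, role = "mask"))
  rec <- poreRecords(tab)
  expect_equal(rec$area_mm2, 20 * 0.00275^2)
  expect_equal(rec$perimeter_mm, (2 * 4 + 2 * 5) * 0.00275)
})

test_that("airspace voxels outside the mask are rejected", {
  air <- array(TRUE, c(2, 6, 6))
  mask <- array(FALSE, c(2, 6, 6)); mask[, 1:3, ] <- TRUE
  expect_error(analyzeStack(BinaryVolume(air, 0.001, role = "composite"),
                            BinaryVolume(mask, 0.001, role = "mask")),
               class = "leafspace_air_outside_mask")
})

test_that("particlePerimeter demands exactly one component", {
  m <- matrix(FALSE, 8, 8)
  expect_error(particlePerimeter(m), class = "leafspace_empty_component")
  m[1, 1] <- TRUE; m[8, 8] <- TRUE
  expect_error(particlePerimeter(m), class = "leafspace_not_single_component")
})

test_that("pore tables export to CSV with one row per pore", {
  td <- withr::local_tempdir()
  air <- array(FALSE, c(2, 10, 10)); air[, 3:5, 3:5] <- TRUE
  tab <- analyzeStack(BinaryVolume(air, 0.001, role = "composite"),
                      BinaryVolume(array(TRUE, dim(air)), 0.001, role = "mask"))
  p <- file.path(td, "pores.csv")
  writePoreTable(tab, p)
  expect_equal(nrow(read.csv(p)), nrow(poreRecords(tab)))
})
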