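fullMask <- function(d, res = 0.00275) {
  BinaryVolume(array(TRUE, d), res, role = "mask")
}
asComposite <- function(a, res = 0.00275) {
  BinaryVolume(a, res, role = "composite")
}

test_that("porosity equals the voxel-count ratio exactly", {
  set.seed(31)
  a <- array(runif(6 * 20 * 20) < 0.25, c(6, 20, 20))
  tab <- analyzeStack(asComposite(a), fullMask(dim(a)))
  expect_equal(porosity(tab), 100 * sum(a) / length(a), tolerance = 1e-12)
})

test_that("air equal to mask gives 100% porosity; empty air gives 0%", {
  d <- c(3, 10, 10)
  full <- analyzeStack(asComposite(array(TRUE, d)), fullMask(d))
  expect_equal(porosity(full), 100)
  none <- analyzeStack(asComposite(array(FALSE, d)), fullMask(d))
  expect_equal(porosity(none), 0)
  expect_equal(smes(none), 0)
})

test_that("the square-pore S_mes matches the hand computation from Eq. 2", {
  res <- 0.00275
  N <- 8
  a <- array(FALSE, c(N, 100, 100))
  a[, 41:50, 41:50] <- TRUE # one 10x10 pore on every slice
  tab <- analyzeStack(asComposite(a, res), fullMask(c(N, 100, 100), res))
  # perimeter 2*10+2*10 = 40 px per slice; numerator = N * 40 * res * res
  num <- N * 40 * res * res
  expect_equal(smes(tab, "projected"), num / (100 * 100 * res^2),
               tolerance = 1e-12)
  expect_equal(smes(tab, "summed"), num / (N * 100 * 100 * res^2),
               tolerance = 1e-12)
  expect_equal(smes(tab, "projected") / smes(tab, "summed"), N)
})

test_that("cylindrical channels recover the analytic lateral surface within the perimeter bias", {
  res <- 0.00275
  k <- 3; r <- 12; nz <- 10
  a <- array(FALSE, c(nz, 100, 100))
  for (cx in c(20, 50, 80)) {
    disc <- outer((1:100 - 50)^2, (1:100 - cx)^2, "+") <= r^2
    for (z in seq_len(nz)) {
      sl <- a[z, , ]; sl[disc] <- TRUE; a[z, , ] <- sl
    }
  }
  tab <- analyzeStack(asComposite(a, res), fullMask(c(nz, 100, 100), res))
  analytic <- k * 2 * pi * r * res * nz * res     # lateral surface, mm^2
  measured <- smes(tab, "projected") * (100 * 100 * res^2)
  expect_lt(abs(measured - analytic) / analytic, 0.10)
})

test_that("a homogeneous stack has a constant porosity profile equal to the total", {
  a <- array(FALSE, c(6, 12, 12))
  a[, 3:6, 3:6] <- TRUE # identical pattern on every slice
  tab <- analyzeStack(asComposite(a), fullMask(dim(a)))
  prof <- porosityProfile(tab)
  expect_equal(prof$porosity_pct, rep(porosity(tab), 6))
  expect_equal(prof$depth_mm, (0:5) * 0.00275)
  expect_equal(prof$depth_norm, (0:5) / 5)
})

test_that("a two-layer phantom yields a step profile at the layer boundary", {
  nz <- 20
  a <- array(FALSE, c(nz, 40, 40))
  a[1:10, 1:10, 1:4] <- TRUE    # 2.5% of each upper slice
  a[11:20, 1:20, 1:32] <- TRUE  # 40% of each lower slice
  tab <- analyzeStack(asComposite(a), fullMask(dim(a)))
  prof <- porosityProfile(tab)
  expect_equal(prof$porosity_pct[1:10], rep(2.5, 10))
  expect_equal(prof$porosity_pct[11:20], rep(40, 10))
})

test_that("the area-weighted profile mean reproduces the overall porosity", {
  ph <- generateLeafPhantom(dicotPhantomSpec(seed = 3))
  tab <- analyzeStack(ph$airspace, ph$mask)
  prof <- porosityProfile(tab)
  expect_equal(weighted.mean(prof$porosity_pct, maskArea(tab)),
               porosity(tab), tolerance = 1e-12)
})

test_that("pore counting distinguishes per-slice pores from 3D channels", {
  k <- 4; nz <- 5
  air <- array(FALSE, c(nz, 40, 40))
  for (c0 in list(c(5, 5), c(5, 30), c(30, 5), c(30, 30)))
    air[, (c0[1] - 2):(c0[1] + 2), (c0[2] - 2):(c0[2] + 2)] <- TRUE
  vol <- asComposite(air)
  tab <- analyzeStack(vol, fullMask(dim(air)))
  counts <- poreCount(tab, vol)
  expect_equal(counts$channels_3d, k)
  expect_equal(counts$pores_2d, k * nz)
})

test_that("leaf thickness is the mean column-wise mask extent", {
  res <- 0.00275
  mask <- array(FALSE, c(10, 8, 8))
  mask[3:7, , ] <- TRUE # uniform 5-slice slab
  expect_equal(leafThickness(BinaryVolume(mask, res, role = "mask")), 5 * res)
  # invariant to in-plane cropping
  m <- BinaryVolume(mask, res, role = "mask")
  expect_equal(leafThickness(cropROI(m, c(2, 2, 4, 4))), 5 * res)
})

test_that("a wedge mask yields the analytic mean of the linear ramp", {
  res <- 0.001
  nz <- 30; nx <- 10
  mask <- array(FALSE, c(nz, 1, nx))
  for (x in 1:nx) mask[1:(3 * x), 1, x] <- TRUE # ramp 3, 6, ..., 30
  expect_equal(leafThickness(BinaryVolume(mask, res, role = "mask")),
               mean(3 * (1:nx)) * res)
})

test_that("voxel-face surface counts are exact on cubes", {
  res <- 0.002
  a <- array(FALSE, c(10, 10, 10)); a[4, 4, 4] <- TRUE
  v <- BinaryVolume(a, res, role = "composite")
  expect_equal(voxelFaceSurface(v, corrected = FALSE), 6 * res^2)
  a2 <- array(FALSE, c(12, 12, 12)); a2[3:7, 3:7, 3:7] <- TRUE
  v2 <- BinaryVolume(a2, res, role = "composite")
  expect_equal(voxelFaceSurface(v2, corrected = FALSE), 6 * 25 * res^2)
  expect_equal(voxelFaceSurface(v2), 4 * 25 * res^2) # with the 2/3 correction
})

test_that("air touching the volume border contributes border faces", {
  res <- 1
  a <- array(TRUE, c(2, 2, 2)) # fills the volume: all 24 faces are border
  expect_equal(voxelFaceSurface(BinaryVolume(a, res, role = "composite"),
                                corrected = FALSE), 24)
})

test_that("zero mask area raises a classed error", {
  recs <- data.frame(slice = integer(0), label = integer(0),
                     area_mm2 = numeric(0), perimeter_mm = numeric(0))
  tab <- new("PoreTable", records = recs, voxelSize = 0.001, sliceCount = 2L,
             maskArea = c(0, 0))
  expect_error(porosity(tab), class = "leafspace_zero_mask")
  expect_error(smes(tab), class = "leafspace_zero_mask")
})

test_that("slices without mask area get NA porosity and a warning", {
  air <- array(FALSE, c(3, 6, 6)); air[1, 2, 2] <- TRUE
  mask <- array(TRUE, c(3, 6, 6)); mask[2, , ] <- FALSE
  tab <- analyzeStack(asComposite(air), BinaryVolume(mask, 0.00275, role = "mask"))
  expect_warning(prof <- porosityProfile(tab), "zero mask area")
  expect_true(is.na(prof$porosity_pct[2]))
  expect_false(anyNA(prof$porosity_pct[-2]))
})
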