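#' @include AllClasses.R AllGenerics.R particles.R
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# linear indices into a (nz, ny, nx) array for sphere/disc voxel offsets
sphereOffsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dz = s, dy = s, dx = s)
  g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

discOffsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dy = s, dx = s)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

# sample one element of a vector (safe for length-1 vectors, unlike sample())
sampleFrom <- function(v) v[sample.int(length(v), 1L)]

#' Specification of a synthetic leaf phantom
#'
#' Defines a leaf-disc phantom that emulates dicot anatomy: solid epidermal
#' layers on both surfaces, a low-porosity palisade-like layer of vertical
#' air channels below the adaxial epidermis, and a high-porosity spongy-like
#' layer of packed air spheres towards the abaxial side, surrounded in-plane
#' by low-attenuation background. All ground truth is known analytically.
#'
#' @param shape integer(3) (z, y, x) voxel dimensions.
#' @param voxelSize voxel edge in mm (default 0.00275, a 2.75 um scan).
#' @param epidermisThickness solid layer thickness at both surfaces (voxels).
#' @param palisade list(channelRadius, channelCount, layerFraction): vertical
#'   air channels of the given radius spanning the palisade layer
#'   (layerFraction of the mesophyll depth).
#' @param spongy list(sphereRadiusRange, targetPorosity): non-overlapping air
#'   spheres packed by rejection sampling until the layer porosity is within
#'   0.5 percentage points of the target.
#' @param noise list(speckCount, speckMaxDiameter): rendering specks (air
#'   specks in tissue and tissue specks in air) that corrupt the grayscale
#'   rendering only, never the ground-truth volumes.
#' @param margin in-plane background margin around the leaf slab (voxels).
#' @param tissueIntensity,airIntensity 8-bit base intensities of the
#'   two-level rendering (defaults 180 and 30, well-separated modes).
#' @param noiseSD Gaussian noise standard deviation added to the rendering
#'   (intensity units; 0 = clean).
#' @param seed RNG seed; generation is bit-reproducible for a fixed seed.
#' @return a list of class "leafPhantomSpec".
#' @export
leafPhantomSpec <- function(shape = c(120L, 160L, 160L),
                            voxelSize = 0.00275,
                            epidermisThickness = 8L,
                            palisade = list(channelRadius = 5L,
                                            channelCount = 12L,
                                            layerFraction = 0.45),
                            spongy = list(sphereRadiusRange = c(3L, 8L),
                                          targetPorosity = 0.35),
                            noise = list(speckCount = 0L, speckMaxDiameter = 2L),
                            margin = 12L,
                            tissueIntensity = 180L,
                            airIntensity = 30L,
                            noiseSD = 0,
                            seed = 1L) {
  spec <- list(shape = as.integer(shape), voxelSize = voxelSize,
               epidermisThickness = as.integer(epidermisThickness),
               palisade = palisade, spongy = spongy, noise = noise,
               margin = as.integer(margin),
               tissueIntensity = as.integer(tissueIntensity),
               airIntensity = as.integer(airIntensity),
               noiseSD = noiseSD, seed = as.integer(seed))
  if (palisade$layerFraction <= 0 || palisade$layerFraction >= 1)
    lsError("bad_spec", "palisade layerFraction must be in (0, 1)")
  if (2 * spec$epidermisThickness >= spec$shape[1])
    lsError("bad_spec", "epidermis layers exceed the stack depth")
  if (any(unlist(spongy$sphereRadiusRange) < 1) || palisade$channelRadius < 1)
    lsError("bad_spec", "radii must be >= 1 voxel")
  class(spec) <- "leafPhantomSpec"
  spec
}

#' Dicot leaf phantom preset
#' @param seed RNG seed.
#' @param noiseSD Gaussian rendering noise SD (intensity units).
#' @param speckCount number of rendering noise specks.
#' @return a "leafPhantomSpec".
#' @export
dicotPhantomSpec <- function(seed = 1L, noiseSD = 0, speckCount = 0L) {
  leafPhantomSpec(seed = seed, noiseSD = noiseSD,
                  noise = list(speckCount = as.integer(speckCount),
                               speckMaxDiameter = 2L))
}

#' Monocot-like leaf phantom preset
#'
#' A thinner slab with a single, more uniform mesophyll: narrow vertical
#' channels throughout and a lower spongy sphere porosity, emulating the more
#' gradual depth profile of grass leaves.
#' @inheritParams dicotPhantomSpec
#' @return a "leafPhantomSpec".
#' @export
monocotPhantomSpec <- function(seed = 1L, noiseSD = 0, speckCount = 0L) {
  leafPhantomSpec(shape = c(80L, 160L, 160L), epidermisThickness = 6L,
                  palisade = list(channelRadius = 3L, channelCount = 20L,
                                  layerFraction = 0.5),
                  spongy = list(sphereRadiusRange = c(2L, 5L),
                                targetPorosity = 0.20),
                  noise = list(speckCount = as.integer(speckCount),
                               speckMaxDiameter = 2L),
                  seed = seed, noiseSD = noiseSD)
}

# Rejection-sample non-overlapping sphere centres (radii tried in the given
# order, largest first) inside the box z0..z1, y0..y1, x0..x1 until the drawn
# voxel count reaches targetVoxels; returns data.frame(z, y, x, r). Sphere
# surfaces keep `clearance` voxels of separation (0 = spheres may touch but
# never overlap, so analytic volume and surface sums stay exact) and r + 2
# voxels to the box bounds.
packSpheres <- function(z0, z1, y0, y1, x0, x1, radii, targetVoxels,
                        clearance = 0, maxFailures = 4000L) {
  centers <- matrix(numeric(0), ncol = 4)
  drawn <- 0
  ri <- 1L
  failures <- 0L
  while (drawn < targetVoxels) {
    if (ri > length(radii))
      lsError("infeasible_packing",
              "target porosity unreachable with the given sphere radii")
    r <- radii[ri]
    if (z0 + r + 2 > z1 - r - 2 || y0 + r + 2 > y1 - r - 2 ||
        x0 + r + 2 > x1 - r - 2) { ri <- ri + 1L; next }
    cand <- c(sampleFrom(seq(z0 + r + 2, z1 - r - 2)),
              sampleFrom(seq(y0 + r + 2, y1 - r - 2)),
              sampleFrom(seq(x0 + r + 2, x1 - r - 2)))
    ok <- TRUE
    if (nrow(centers) > 0) {
      d2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 +
        (centers[, 3] - cand[3])^2
      ok <- all(d2 >= (centers[, 4] + r + clearance)^2)
    }
    if (ok) {
      centers <- rbind(centers, c(cand, r))
      drawn <- drawn + nrow(sphereOffsets(r))
      failures <- 0L
    } else {
      failures <- failures + 1L
      if (failures >= maxFailures) { ri <- ri + 1L; failures <- 0L }
    }
  }
  as.data.frame(`colnames<-`(centers, c("z", "y", "x", "r")))
}

drawSpheres <- function(vox, centers) {
  d <- dim(vox)
  for (r in unique(centers$r)) {
    off <- sphereOffsets(r)
    sel <- centers$r == r
    for (i in which(sel)) {
      z <- centers$z[i] + off$dz
      y <- centers$y[i] + off$dy
      x <- centers$x[i] + off$dx
      vox[cbind(z, y, x)] <- TRUE
    }
  }
  vox
}

#' Generate a synthetic leaf phantom
#'
#' Deterministically renders the phantom described by a [leafPhantomSpec()]:
#' a grayscale stack (two base intensities plus optional specks and Gaussian
#' noise, so the segmentation pipeline can be exercised end to end), the
#' exact truth airspace and truth mask volumes, and a [PhantomTruth-class]
#' holding analytic (continuous geometry) and discrete (voxel-counted)
#' ground-truth values.
#'
#' @param spec a "leafPhantomSpec".
#' @return list(grid, airspace, mask, truth).
#' @export
generateLeafPhantom <- function(spec) {
  stopifnot(inherits(spec, "leafPhantomSpec"))
  withSeed(spec$seed, {
    nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
    m <- spec$margin
    e <- spec$epidermisThickness
    res <- spec$voxelSize

    mask <- array(FALSE, spec$shape)
    mask[, (m + 1):(ny - m), (m + 1):(nx - m)] <- TRUE

    mes0 <- e + 1L               # first mesophyll slice
    mes1 <- nz - e               # last mesophyll slice
    nmes <- mes1 - mes0 + 1L
    npal <- max(1L, round(spec$palisade$layerFraction * nmes))
    pal <- mes0:(mes0 + npal - 1L)          # palisade slices
    spg <- if (mes0 + npal <= mes1) (mes0 + npal):mes1 else integer(0)

    air <- array(FALSE, spec$shape)

    # palisade: non-overlapping vertical cylindrical channels
    k <- spec$palisade$channelCount
    r <- spec$palisade$channelRadius
    ctr <- matrix(numeric(0), ncol = 2)
    guard <- 0L
    while (nrow(ctr) < k) {
      if ((guard <- guard + 1L) > 20000L)
        lsError("infeasible_packing", "cannot place the requested channels")
      cand <- c(sampleFrom(seq(m + r + 2, ny - m - r - 1)),
                sampleFrom(seq(m + r + 2, nx - m - r - 1)))
      if (nrow(ctr) == 0 ||
          all((ctr[, 1] - cand[1])^2 + (ctr[, 2] - cand[2])^2 >= (2 * r + 2)^2))
        ctr <- rbind(ctr, cand)
    }
    doff <- discOffsets(r)
    for (i in seq_len(k)) {
      yy <- ctr[i, 1] + doff$dy
      xx <- ctr[i, 2] + doff$dx
      for (z in pal) air[cbind(z, yy, xx)] <- TRUE
    }
    discArea <- nrow(doff)

    # spongy: packed air spheres up to the target porosity (within 0.5 pp)
    spheres <- NULL
    if (length(spg) > 0 && spec$spongy$targetPorosity > 0) {
      layerVox <- length(spg) * (ny - 2 * m) * (nx - 2 * m)
      target <- (spec$spongy$targetPorosity - 0.005) * layerVox
      radii <- seq(max(spec$spongy$sphereRadiusRange),
                   min(spec$spongy$sphereRadiusRange))
      spheres <- packSpheres(min(spg), max(spg), m + 1, ny - m, m + 1, nx - m,
                             radii, target)
      air <- drawSpheres(air, spheres)
    }

    # grayscale rendering
    gray <- array(spec$airIntensity, spec$shape)
    gray[mask & !air] <- spec$tissueIntensity
    if (spec$noise$speckCount > 0) {
      inMask <- which(mask)
      pos <- sample(inMask, spec$noise$speckCount)
      rad <- sample(0:(max(0, spec$noise$speckMaxDiameter - 1) %/% 2),
                    spec$noise$speckCount, replace = TRUE)
      for (i in seq_along(pos)) {
        idx <- arrayInd(pos[i], spec$shape)
        off <- sphereOffsets(rad[i])
        z <- pmin(pmax(idx[1] + off$dz, 1), nz)
        y <- pmin(pmax(idx[2] + off$dy, 1), ny)
        x <- pmin(pmax(idx[3] + off$dx, 1), nx)
        flip <- if (air[pos[i]]) spec$tissueIntensity else spec$airIntensity
        gray[cbind(z, y, x)] <- flip
      }
    }
    if (spec$noiseSD > 0)
      gray <- gray + rnorm(length(gray), 0, spec$noiseSD)
    gray <- round(pmin(pmax(gray, 0), 255))

    # ground truth
    slabVox <- nz * (ny - 2 * m) * (nx - 2 * m)
    airAnalytic <- k * pi * r^2 * npal +
      if (!is.null(spheres)) sum(4 / 3 * pi * spheres$r^3) else 0
    perSlice <- vapply(seq_len(nz), function(i) {
      sl <- cpp_analyze_slice(air[i, , ], 8L, TRUE)
      sum(sl$perimeter_px) * res
    }, numeric(1))
    truth <- new("PhantomTruth",
      analytic = list(
        porosity_pct = 100 * airAnalytic / slabVox,
        channel_lateral_surface_mm2 = k * 2 * pi * r * npal * res^2,
        channel_diameters_mm = rep(2 * r * res, k),
        sphere_surface_mm2 = if (!is.null(spheres))
          sum(4 * pi * spheres$r^2) * res^2 else 0,
        thickness_mm = nz * res,
        palisade_slices = pal,
        spongy_slices = spg,
        channel_count = k,
        sphere_count = if (!is.null(spheres)) nrow(spheres) else 0L),
      discrete = list(
        porosity_pct = 100 * sum(air) / sum(mask),
        per_slice_perimeter_mm = perSlice,
        lateral_surface_mm2 = sum(perSlice) * res,
        air_voxels = sum(air),
        mask_voxels = sum(mask),
        channel_area_px = discArea))

    list(grid = VoxelGrid(gray, voxelSize = res, bitDepth = 8L),
         airspace = BinaryVolume(air, voxelSize = res, role = "airspace"),
         mask = BinaryVolume(mask, voxelSize = res, role = "mask"),
         truth = truth)
  })
}

#' Generate an isotropic random-sphere phantom
#'
#' Non-overlapping air spheres placed uniformly in a solid block: an
#' isotropic two-phase structure with exactly known analytic porosity and
#' surface area, used to validate the stereological identity
#' S_V = (4/pi) B_A between section boundary-length density and 3D surface
#' density.
#'
#' @param shape integer(3) voxel dimensions (z, y, x).
#' @param voxelSize voxel edge in mm.
#' @param radiusRange integer(2), sphere radius range in voxels.
#' @param targetPorosity target air volume fraction (reached within 0.5 pp).
#' @param seed RNG seed.
#' @return list(airspace = [BinaryVolume-class], truth = [PhantomTruth-class]).
#' @export
generateSpherePhantom <- function(shape = c(128L, 128L, 128L),
                                  voxelSize = 0.00275,
                                  radiusRange = c(14L, 20L),
                                  targetPorosity = 0.25,
                                  seed = 1L) {
  withSeed(seed, {
    nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
    radii <- seq(max(radiusRange), min(radiusRange))
    target <- (targetPorosity - 0.005) * prod(shape)
    spheres <- packSpheres(1, nz, 1, ny, 1, nx, radii, target, clearance = 1)
    air <- drawSpheres(array(FALSE, shape), spheres)
    truth <- new("PhantomTruth",
      analytic = list(
        porosity_pct = 100 * sum(4 / 3 * pi * spheres$r^3) / prod(shape),
        surface_mm2 = sum(4 * pi * spheres$r^2) * voxelSize^2,
        sphere_count = nrow(spheres)),
      discrete = list(
        porosity_pct = 100 * sum(air) / prod(shape),
        air_voxels = sum(air)))
    list(airspace = BinaryVolume(air, voxelSize = voxelSize, role = "airspace"),
         truth = truth)
  })
}

#' Generate a synthetic 2D section phantom
#'
#' A bright tissue band across the image with dark elliptical airspace holes
#' and a dark background, with exact truth masks; emulates a stained
#' microscope section for the stereology workflow.
#'
#' @param shape integer(2) (rows, cols).
#' @param pixelSize pixel edge in mm.
#' @param bandRows integer(2), first and last row of the tissue band.
#' @param holeCount number of elliptical holes.
#' @param holeSemiAxes numeric(2), range of hole semi-axes in pixels.
#' @param tissueIntensity,airIntensity,backgroundIntensity 8-bit intensities.
#' @param noiseSD Gaussian rendering noise SD.
#' @param seed RNG seed.
#' @return list(image = [SectionImage-class], leaf, airspace (truth masks),
#'   truth = [PhantomTruth-class]).
#' @export
generateSectionPhantom <- function(shape = c(200L, 400L),
                                   pixelSize = 0.002,
                                   bandRows = c(51L, 150L),
                                   holeCount = 8L,
                                   holeSemiAxes = c(8, 16),
                                   tissueIntensity = 180L,
                                   airIntensity = 30L,
                                   backgroundIntensity = 30L,
                                   noiseSD = 0,
                                   seed = 1L) {
  withSeed(seed, {
    ny <- shape[1]; nx <- shape[2]
    leaf <- matrix(FALSE, ny, nx)
    leaf[bandRows[1]:bandRows[2], ] <- TRUE
    airMask <- matrix(FALSE, ny, nx)
    placed <- matrix(numeric(0), ncol = 3) # y, x, max semi-axis
    guard <- 0L
    while (nrow(placed) < holeCount) {
      if ((guard <- guard + 1L) > 20000L)
        lsError("infeasible_packing", "cannot place the requested holes")
      a <- runif(1, holeSemiAxes[1], holeSemiAxes[2]) # y semi-axis
      b <- runif(1, holeSemiAxes[1], holeSemiAxes[2]) # x semi-axis
      mx <- ceiling(max(a, b))
      cy <- sampleFrom(seq(bandRows[1] + mx + 2, bandRows[2] - mx - 2))
      cx <- sampleFrom(seq(mx + 3, nx - mx - 2))
      if (nrow(placed) == 0 ||
          all((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2 >
                (placed[, 3] + mx + 3)^2)) {
        yy <- (cy - mx):(cy + mx)
        xx <- (cx - mx):(cx + mx)
        g <- expand.grid(y = yy, x = xx)
        inside <- ((g$y - cy) / a)^2 + ((g$x - cx) / b)^2 <= 1
        airMask[cbind(g$y[inside], g$x[inside])] <- TRUE
        placed <- rbind(placed, c(cy, cx, mx))
      }
    }
    px <- matrix(backgroundIntensity, ny, nx)
    px[leaf] <- tissueIntensity
    px[airMask] <- airIntensity
    if (noiseSD > 0) px <- px + rnorm(length(px), 0, noiseSD)
    px <- round(pmin(pmax(px, 0), 255))
    perim <- sectionPerimeter(airMask) * pixelSize
    truth <- new("PhantomTruth",
      analytic = list(porosity_pct = NA_real_),
      discrete = list(
        porosity_pct = 100 * sum(airMask) / sum(leaf),
        total_perimeter_mm = perim,
        air_pixels = sum(airMask),
        leaf_pixels = sum(leaf)))
    list(image = SectionImage(px, pixelSize = pixelSize,
                              widthMM = nx * pixelSize),
         leaf = leaf, airspace = airMask, truth = truth)
  })
}

#' Sample random axis-orthogonal sections from a binary volume
#'
#' Uniformly random section positions along the chosen axis; sampling is
#' without replacement unless more sections than positions are requested
#' (then with replacement, with a warning).
#'
#' @param volume a [BinaryVolume-class].
#' @param n number of sections.
#' @param seed RNG seed.
#' @param axis "z" (depth, default), "y" or "x".
#' @return list of logical matrices; the sampled indices are attached as the
#'   "indices" attribute.
#' @export
sampleRandomSections <- function(volume, n, seed = 1L, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  stopifnot(n >= 1)
  v <- voxels(volume)
  nAvail <- switch(axis, z = dim(v)[1], y = dim(v)[2], x = dim(v)[3])
  withSeed(seed, {
    replace <- n > nAvail
    if (replace)
      warning("more sections requested than available slices; sampling with replacement")
    idx <- sample.int(nAvail, n, replace = replace)
    out <- lapply(idx, function(i)
      switch(axis, z = v[i, , ], y = v[, i, ], x = v[, , i]))
    attr(out, "indices") <- idx
    out
  })
}
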