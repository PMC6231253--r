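#' @include AllClasses.R AllGenerics.R threshold.R
NULL

#' Create a leaf-disc mask from a grayscale stack
#'
#' Automated replacement for manual label-field masking: the stack is
#' thresholded with the maximum-entropy method (tissue on the high-intensity
#' side), then each slice is morphologically closed (bridging intercellular
#' gaps), hole-filled (internal airspace becomes part of the disc) and reduced
#' to its largest connected component. A user-supplied mask stack read with
#' [readBinaryStack()] can be used instead wherever a mask is accepted.
#'
#' @param grid a [VoxelGrid-class].
#' @param closingRadius disc radius (voxels) of the morphological closing;
#'   larger radii bridge wider airspace openings at the leaf surface.
#' @param thresholdMethod threshold method for tissue/background separation.
#' @return A [BinaryVolume-class] with role "mask"; attributes record the
#'   threshold used.
#' @export
makeLeafMask <- function(grid, closingRadius = 5, thresholdMethod = "max_entropy") {
  thr <- autoThreshold(grid, thresholdMethod)
  arr <- voxels(grid) > thr@thresholdRaw  # tissue = high side
  d <- dim(arr)
  kern <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, shape = "disc")
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) {
    sl <- arr[i, , ] * 1
    sl <- EBImage::closing(sl, kern)
    sl <- EBImage::fillHull(sl)
    lab <- cpp_label2d(sl > 0.5, 8L)
    nlab <- attr(lab, "nlabels")
    if (nlab == 0L)
      lsError("empty_mask", sprintf("leaf mask is empty on slice %d", i))
    sizes <- cpp_label_sizes(as.integer(lab), nlab)
    out[i, , ] <- lab == which.max(sizes)
  }
  m <- BinaryVolume(out, voxelSize = voxelSize(grid), role = "mask")
  attr(m, "threshold") <- thr
  attr(m, "closingRadius") <- closingRadius
  m
}

#' Composite airspace and mask
#'
#' Voxelwise AND of a thresholded airspace volume and the leaf-disc mask,
#' isolating the intercellular airspace inside the disc.
#'
#' @param air airspace [BinaryVolume-class].
#' @param mask leaf-disc mask [BinaryVolume-class].
#' @return A [BinaryVolume-class] with role "composite".
#' @export
extractAirspace <- function(air, mask) {
  if (!identical(dim(voxels(air)), dim(voxels(mask))))
    lsError("shape_mismatch", "airspace and mask volumes differ in shape")
  BinaryVolume(voxels(air) & voxels(mask), voxelSize = voxelSize(air),
               role = "composite")
}

# filter one phase: remove 3D connected components (26-conn foreground,
# 6-conn background) with equivalent spherical diameter below the cutoff
filterPhase3d <- function(vox, connectivity, minDiameter) {
  lab <- cpp_label3d(as.vector(vox), dim(vox), connectivity)
  nlab <- attr(lab, "nlabels")
  if (nlab == 0L) return(vox)
  sizes <- cpp_label_sizes(lab, nlab)
  eqd <- (6 * sizes / pi)^(1 / 3)
  keep <- eqd >= minDiameter
  dim(lab) <- dim(vox)
  sel <- lab > 0L
  vox[sel] <- keep[lab[sel]]
  vox
}

filterPhase2d <- function(vox, connectivity, minDiameter) {
  for (i in seq_len(dim(vox)[1])) {
    lab <- cpp_label2d(vox[i, , ], connectivity)
    nlab <- attr(lab, "nlabels")
    if (nlab == 0L) next
    sizes <- cpp_label_sizes(as.integer(lab), nlab)
    eqd <- 2 * sqrt(sizes / pi)  # equivalent circular diameter in 2D
    keep <- eqd >= minDiameter
    sl <- vox[i, , ]
    sel <- lab > 0L
    sl[sel] <- keep[lab[sel]]
    vox[i, , ] <- sl
  }
  vox
}

#' Remove small particles (noise) from a binary volume
#'
#' De-noising rule: connected components of both phases whose equivalent
#' spherical diameter is below \code{factor} voxel edges (i.e. below
#' \code{factor} times the scan resolution) are removed — foreground specks
#' are deleted first, then background specks are filled. Foreground uses
#' 26-connectivity, background the dual 6-connectivity (8/4 in the 2D
#' variant).
#'
#' @param vol a [BinaryVolume-class].
#' @param factor dimensionless size cutoff in multiples of the voxel edge
#'   (default 3: particles smaller than 3 x the spatial resolution).
#' @param filter2d apply the rule per slice in 2D instead of in 3D.
#' @return the filtered [BinaryVolume-class].
#' @export
removeSmallParticles <- function(vol, factor = 3, filter2d = FALSE) {
  stopifnot(factor >= 0)
  vox <- voxels(vol)
  if (filter2d) {
    vox <- filterPhase2d(vox, 8L, factor)
    vox <- !filterPhase2d(!vox, 4L, factor)
  } else {
    vox <- filterPhase3d(vox, 26L, factor)
    vox <- !filterPhase3d(!vox, 6L, factor)
  }
  out <- BinaryVolume(vox, voxelSize = voxelSize(vol), role = role(vol))
  attr(out, "minParticleFactor") <- factor
  attr(out, "filter2d") <- filter2d
  out
}

validateROI <- function(d, roi) {
  if (length(roi) != 4L) lsError("roi_bounds", "roi must be c(y0, x0, height, width)")
  y0 <- roi[1]; x0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (y0 < 1 || x0 < 1 || h < 1 || w < 1 ||
      y0 + h - 1 > d[2] || x0 + w - 1 > d[3])
    lsError("roi_bounds",
            sprintf("ROI (%d,%d,%d,%d) outside the %dx%d in-plane extent",
                    y0, x0, h, w, d[2], d[3]))
  c(y0, x0, h, w)
}

#' @rdname cropROI
#' @export
setMethod("cropROI", "VoxelGrid", function(x, roi) {
  d <- dim(voxels(x))
  roi <- validateROI(d, as.integer(roi))
  out <- VoxelGrid(x@voxels[, roi[1]:(roi[1] + roi[3] - 1),
                            roi[2]:(roi[2] + roi[4] - 1), drop = FALSE],
                   voxelSize = voxelSize(x), bitDepth = x@bitDepth)
  attr(out, "roi") <- roi
  out
})

#' @rdname cropROI
#' @export
setMethod("cropROI", "BinaryVolume", function(x, roi) {
  d <- dim(voxels(x))
  roi <- validateROI(d, as.integer(roi))
  out <- BinaryVolume(x@voxels[, roi[1]:(roi[1] + roi[3] - 1),
                               roi[2]:(roi[2] + roi[4] - 1), drop = FALSE],
                      voxelSize = voxelSize(x), role = role(x))
  attr(out, "roi") <- roi
  out
})
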