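#' @include AllClasses.R AllGenerics.R particles.R
NULL

#' Leaf porosity (%)
#'
#' Porosity = (sum of pore areas over all slices / sum of mask areas over all
#' slices) x 100. Invariant to slice order and to splitting the stack into
#' sub-stacks recombined with area weights.
#'
#' @param table a [PoreTable-class].
#' @return porosity in percent.
#' @export
porosity <- function(table) {
  am <- sum(maskArea(table))
  if (am <= 0) lsError("zero_mask", "total mask area is zero")
  100 * sum(poreRecords(table)$area_mm2) / am
}

#' Mesophyll surface area exposed to intercellular airspace (S_mes)
#'
#' S_mes = (sum of pore perimeters x RES) / leaf area, in mm^2 mm^-2. The
#' numerator is the lateral pore surface: the summed in-plane boundary length
#' of every pore, extruded by the slice thickness RES. The default
#' denominator is the projected leaf area (the mean per-slice mask area),
#' which matches the magnitude of reported whole-leaf values; with
#' \code{denominator = "summed"} the mask areas are summed over all slices
#' instead (the literal per-slice-area reading, smaller by a factor equal to
#' the slice count). Faces of pores normal to the depth axis are not counted,
#' faithfully to the perimeter x slice-thickness construction; see
#' [voxelFaceSurface()] for a full 3D voxel-face estimate.
#'
#' @param table a [PoreTable-class].
#' @param denominator "projected" (default) or "summed".
#' @return S_mes in mm^2 per mm^2 of leaf area.
#' @export
smes <- function(table, denominator = c("projected", "summed")) {
  denominator <- match.arg(denominator)
  if (sum(maskArea(table)) <= 0) lsError("zero_mask", "total mask area is zero")
  num <- sum(poreRecords(table)$perimeter_mm) * voxelSize(table)
  den <- switch(denominator,
                projected = mean(maskArea(table)),
                summed = sum(maskArea(table)))
  num / den
}

#' Depth-resolved porosity profile
#'
#' Per-slice porosity from the adaxial (slice 1) to the abaxial surface.
#' Slices with zero mask area get a missing porosity (with a warning), not 0.
#'
#' @param table a [PoreTable-class].
#' @return data.frame(slice, depth_mm, depth_norm, porosity_pct); depth_mm =
#'   (slice - 1) x RES and depth_norm spans 0..1 across the stack.
#' @export
porosityProfile <- function(table) {
  n <- table@sliceCount
  am <- maskArea(table)
  recs <- poreRecords(table)
  ap <- vapply(seq_len(n), function(i) sum(recs$area_mm2[recs$slice == i]),
               numeric(1))
  por <- ifelse(am > 0, 100 * ap / am, NA_real_)
  if (any(am <= 0))
    warning(sprintf("%d slice(s) have zero mask area; porosity recorded as NA",
                    sum(am <= 0)))
  data.frame(slice = seq_len(n),
             depth_mm = (seq_len(n) - 1) * voxelSize(table),
             depth_norm = if (n > 1) (seq_len(n) - 1) / (n - 1) else 0,
             porosity_pct = por)
}

#' Pore counts
#'
#' Counts the per-slice 2D pores (the analyze-particles records) and,
#' when the airspace volume is supplied, the 3D 26-connected air channels.
#'
#' @param table a [PoreTable-class].
#' @param air optional airspace [BinaryVolume-class] for the 3D channel count.
#' @return list(pores_2d, channels_3d); channels_3d is NA without \code{air}.
#' @export
poreCount <- function(table, air = NULL) {
  n3 <- NA_integer_
  if (!is.null(air)) {
    lab <- cpp_label3d(as.vector(voxels(air)), dim(voxels(air)), 26L)
    n3 <- attr(lab, "nlabels")
  }
  list(pores_2d = nrow(poreRecords(table)), channels_3d = n3)
}

#' Leaf thickness from the mask extent
#'
#' Mean over all in-plane (y, x) columns intersecting the disc of the depth
#' span of the mask in that column, times the voxel size. The column mean is
#' robust to slight tilt of the disc.
#'
#' @param mask leaf-disc [BinaryVolume-class].
#' @return thickness in mm.
#' @export
leafThickness <- function(mask) {
  mv <- voxels(mask)
  if (!any(mv)) lsError("empty_mask", "mask is empty")
  d <- dim(mv)
  flat <- matrix(mv, nrow = d[1])       # slices x (y*x columns)
  anyCol <- colSums(flat) > 0
  zmin <- apply(flat[, anyCol, drop = FALSE], 2, function(v) which(v)[1])
  zmax <- apply(flat[, anyCol, drop = FALSE], 2, function(v) max(which(v)))
  mean(zmax - zmin + 1) * voxelSize(mask)
}

#' Voxel-face surface area of the airspace
#'
#' Counts the faces between air voxels and solid voxels (the volume border
#' counts as solid) and calibrates by RES^2. The raw face count overestimates
#' a smooth isotropic surface by exactly 3/2 (the mean of |nx|+|ny|+|nz| over
#' the sphere of directions), so by default the classical 2/3 correction is
#' applied; \code{corrected = FALSE} returns the raw face area. This is the
#' full 3D surface (it includes depth-facing pore faces) and is deliberately
#' separate from the lateral perimeter-based [smes()] estimate.
#'
#' @param air airspace [BinaryVolume-class].
#' @param corrected apply the 2/3 isotropic digitization correction.
#' @return surface area in mm^2.
#' @export
voxelFaceSurface <- function(air, corrected = TRUE) {
  a <- voxels(air)
  d <- dim(a)
  faces <- 0
  # border faces (border treated as solid)
  faces <- faces + sum(a[1, , ]) + sum(a[d[1], , ]) +
    sum(a[, 1, ]) + sum(a[, d[2], ]) + sum(a[, , 1]) + sum(a[, , d[3]])
  # internal faces along each axis: adjacent voxel pairs differing in phase
  if (d[1] > 1) faces <- faces + sum(a[-1, , ] != a[-d[1], , ])
  if (d[2] > 1) faces <- faces + sum(a[, -1, ] != a[, -d[2], ])
  if (d[3] > 1) faces <- faces + sum(a[, , -1] != a[, , -d[3]])
  area <- faces * voxelSize(air)^2
  if (corrected) area * 2 / 3 else area
}

#' Single-sample 3D metrics
#'
#' Convenience wrapper composing the analyze-particles table and the
#' headline descriptors into one metrics record.
#'
#' @param air airspace [BinaryVolume-class].
#' @param mask leaf-disc mask [BinaryVolume-class].
#' @param sample_id sample identifier.
#' @param smesDenominator passed to [smes()].
#' @param thicknessMap optional precomputed [ThicknessMap-class]; computed
#'   from \code{air} when TRUE, skipped when NULL/FALSE.
#' @return list(record, table, profile): the one-row metrics data.frame, the
#'   [PoreTable-class] and the porosity profile.
#' @export
leafMetrics <- function(air, mask, sample_id = "sample",
                        smesDenominator = "projected", thicknessMap = NULL) {
  table <- analyzeStack(air, mask)
  tm <- NULL
  meanD <- NA_real_
  maxD <- NA_real_
  if (isTRUE(thicknessMap)) tm <- localThickness(air)
  else if (is(thicknessMap, "ThicknessMap")) tm <- thicknessMap
  if (!is.null(tm)) {
    st <- channelDiameterStats(tm)
    meanD <- st$mean
    maxD <- st$max
  }
  rec <- metricsRecord(sample_id,
                       porosity_pct = porosity(table),
                       smes = smes(table, smesDenominator),
                       pore_count = nrow(poreRecords(table)),
                       leaf_thickness_mm = leafThickness(mask),
                       mean_channel_diameter_mm = meanD,
                       max_channel_diameter_mm = maxD)
  list(record = rec, table = table, profile = porosityProfile(table))
}
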