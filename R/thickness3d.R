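#' @include AllClasses.R AllGenerics.R
NULL

#' Local thickness transform of the airspace
#'
#' For every air voxel p, the local thickness is the diameter of the largest
#' sphere that contains p and fits entirely within the airspace (the
#' Hildebrand-Ruegsegger definition used for air-channel diameter heat maps).
#' Computed by a Euclidean distance transform followed by sphere propagation
#' in decreasing radius order; sphere fitting is normative, since doubling
#' the distance transform underestimates diameters in necks and corners. The
#' volume border is treated as solid, so spheres may not extend outside.
#'
#' @param air airspace [BinaryVolume-class].
#' @param method "sphere" (normative) or "edt2x" (fast preview: twice the
#'   distance-transform radius at each voxel; not the inscribed-sphere value).
#' @return A [ThicknessMap-class] with diameters in mm (0 outside airspace).
#' @export
localThickness <- function(air, method = c("sphere", "edt2x")) {
  method <- match.arg(method)
  av <- voxels(air)
  if (!any(av)) lsError("empty_airspace", "airspace volume is empty")
  if (method == "sphere") {
    vals <- cpp_local_thickness(as.vector(av), dim(av))
  } else {
    vals <- 2 * sqrt(cpp_edt_sq(as.vector(av), dim(av)))
  }
  dim(vals) <- dim(av)
  new("ThicknessMap", values = vals * voxelSize(air),
      voxelSize = voxelSize(air))
}

#' Mean and maximum air-channel diameter
#'
#' The mean is taken over airspace voxels only; the maximum over the whole
#' map.
#'
#' @param map a [ThicknessMap-class].
#' @return list(mean, max) in mm.
#' @export
channelDiameterStats <- function(map) {
  v <- voxels(map)
  inside <- v > 0
  if (!any(inside)) lsError("empty_airspace", "thickness map has no airspace voxels")
  list(mean = mean(v[inside]), max = max(v))
}
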