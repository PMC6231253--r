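#' @include leafspace-package.R
NULL

# Classed error helper: every contract violation raises a condition of class
# "leafspace_<what>" so callers and tests can catch errors by name.
lsError <- function(what, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("leafspace_", what),
                                     "leafspace_error", "error", "condition")))
}

#' VoxelGrid: a 3D grayscale microCT volume
#'
#' Holds a reconstructed grayscale CT volume as a 3D array with an isotropic
#' voxel edge length in mm. The first array axis is leaf depth (slice axis,
#' adaxial at slice 1, abaxial at the last slice); axes 2 and 3 are the
#' in-plane y and x directions.
#'
#' @slot voxels integer 3D array of intensities (z, y, x).
#' @slot voxelSize numeric(1), voxel edge length in mm (the scan resolution).
#' @slot bitDepth integer(1), 8 or 16; intensities must lie in the declared
#'   range.
#' @export
setClass("VoxelGrid",
  representation(voxels = "array", voxelSize = "numeric", bitDepth = "integer"),
  prototype(voxelSize = 1, bitDepth = 8L))

setValidity("VoxelGrid", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L))
    return("voxels must be a 3D array with all dimensions >= 1")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number (mm)")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  r <- range(object@voxels)
  if (r[1] < 0 || r[2] > 2^object@bitDepth - 1)
    return(sprintf("intensities outside the %d-bit range", object@bitDepth))
  TRUE
})

#' BinaryVolume: a 3D boolean volume
#'
#' A segmented volume with the same axis convention as [VoxelGrid-class].
#' The role records what the volume represents: a leaf-disc mask, an
#' airspace (pore) volume, or their composite.
#'
#' @slot voxels logical 3D array (z, y, x).
#' @slot voxelSize numeric(1), voxel edge length in mm.
#' @slot role character(1), one of "mask", "airspace", "composite".
#' @export
setClass("BinaryVolume",
  representation(voxels = "array", voxelSize = "numeric", role = "character"),
  prototype(voxelSize = 1, role = "airspace"))

setValidity("BinaryVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L))
    return("voxels must be a 3D array with all dimensions >= 1")
  if (!is.logical(object@voxels))
    return("voxels must be logical")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number (mm)")
  if (!object@role %in% c("mask", "airspace", "composite"))
    return("role must be one of 'mask', 'airspace', 'composite'")
  TRUE
})

#' ThresholdResult: an automatic threshold selection
#'
#' @slot method character(1): "isodata", "li" or "max_entropy".
#' @slot threshold integer(1), selected histogram bin (0-based, < 256).
#' @slot thresholdRaw numeric(1), the threshold mapped back to the native
#'   intensity scale (upper edge of the selected bin); voxels with intensity
#'   \code{<= thresholdRaw} fall on the low (airspace) side.
#' @slot polarity character(1): which side of the threshold is airspace
#'   ("low"; air attenuates X-rays less than tissue).
#' @export
setClass("ThresholdResult",
  representation(method = "character", threshold = "integer",
                 thresholdRaw = "numeric", polarity = "character"),
  prototype(polarity = "low"))

setValidity("ThresholdResult", function(object) {
  if (!object@method %in% c("isodata", "li", "max_entropy"))
    return("unknown threshold method")
  if (object@threshold < 0L || object@threshold > 255L)
    return("threshold bin out of range")
  if (!object@polarity %in% c("low", "high"))
    return("polarity must be 'low' or 'high'")
  TRUE
})

#' PoreTable: per-slice, per-component pore measurements
#'
#' The analyze-particles output: one record per 2D pore component per slice,
#' with calibrated area and corner-counting perimeter, plus the per-slice
#' mask areas needed by the porosity and S_mes estimators.
#'
#' @slot records data.frame with columns slice (1-based), label, area_mm2,
#'   perimeter_mm.
#' @slot voxelSize numeric(1) mm.
#' @slot sliceCount integer(1).
#' @slot maskArea numeric vector of per-slice mask areas (mm^2), length
#'   sliceCount.
#' @export
setClass("PoreTable",
  representation(records = "data.frame", voxelSize = "numeric",
                 sliceCount = "integer", maskArea = "numeric"))

setValidity("PoreTable", function(object) {
  req <- c("slice", "label", "area_mm2", "perimeter_mm")
  if (!all(req %in% names(object@records)))
    return(paste("records must have columns:", paste(req, collapse = ", ")))
  if (length(object@maskArea) != object@sliceCount)
    return("maskArea must have one entry per slice")
  if (nrow(object@records) > 0) {
    if (any(object@records$slice < 1L | object@records$slice > object@sliceCount))
      return("record slice index out of range")
    if (any(object@records$area_mm2 <= 0) || any(object@records$perimeter_mm <= 0))
      return("areas and perimeters must be positive")
  }
  TRUE
})

#' ThicknessMap: local air-channel diameters
#'
#' Local thickness transform values: for each airspace voxel, the diameter
#' (mm) of the largest inscribed sphere containing it; zero elsewhere.
#'
#' @slot values numeric 3D array of diameters (mm).
#' @slot voxelSize numeric(1) mm.
#' @export
setClass("ThicknessMap",
  representation(values = "array", voxelSize = "numeric"))

setValidity("ThicknessMap", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3D array")
  if (any(object@values < 0))
    return("diameters must be non-negative")
  TRUE
})

#' SectionImage: a 2D microscope section for stereology
#'
#' @slot pixels numeric matrix of grayscale intensities (0..255 scale).
#' @slot pixelSize numeric(1), pixel edge length in mm.
#' @slot widthMM numeric(1), width of the analysed section (W, mm).
#' @export
setClass("SectionImage",
  representation(pixels = "matrix", pixelSize = "numeric", widthMM = "numeric"))

setValidity("SectionImage", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (object@widthMM <= 0) return("widthMM must be positive")
  TRUE
})

#' PhantomTruth: analytic and discrete ground truth of a phantom
#'
#' Ground-truth values attached to a generated phantom, computed both from
#' the continuous geometry (analytic) and from the drawn voxels (discrete).
#'
#' @slot analytic named list of continuous-geometry values.
#' @slot discrete named list of voxel-counted values.
#' @export
setClass("PhantomTruth",
  representation(analytic = "list", discrete = "list"))

# --- constructors -----------------------------------------------------------

#' Create a VoxelGrid
#'
#' @param voxels 3D numeric/integer array (z = depth, y, x).
#' @param voxelSize voxel edge length in mm. Not read from file metadata:
#'   scanner TIFF dialects vary, so it is always an explicit parameter.
#' @param bitDepth 8 or 16; guessed from the data range when NULL.
#' @return A [VoxelGrid-class] object.
#' @export
VoxelGrid <- function(voxels, voxelSize, bitDepth = NULL) {
  storage.mode(voxels) <- "integer"
  if (is.null(bitDepth))
    bitDepth <- if (max(voxels) > 255L) 16L else 8L
  new("VoxelGrid", voxels = voxels, voxelSize = as.numeric(voxelSize),
      bitDepth = as.integer(bitDepth))
}

#' Create a BinaryVolume
#'
#' @param voxels 3D logical array.
#' @param voxelSize voxel edge length in mm.
#' @param role "mask", "airspace" or "composite".
#' @return A [BinaryVolume-class] object.
#' @export
BinaryVolume <- function(voxels, voxelSize, role = "airspace") {
  storage.mode(voxels) <- "logical"
  new("BinaryVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      role = role)
}

#' Create a SectionImage
#'
#' @param pixels grayscale matrix (0..255 scale).
#' @param pixelSize pixel edge in mm.
#' @param widthMM analysed section width W in mm; when NULL, falls back to
#'   the image width (ncol * pixelSize).
#' @return A [SectionImage-class] object.
#' @export
SectionImage <- function(pixels, pixelSize, widthMM = NULL) {
  if (is.null(widthMM)) widthMM <- ncol(pixels) * pixelSize
  new("SectionImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      widthMM = as.numeric(widthMM))
}
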