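#' @include AllClasses.R
NULL

#' Access the voxel data of a volume
#' @param x a VoxelGrid, BinaryVolume or ThicknessMap.
#' @return the underlying 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Access the voxel edge length (mm)
#' @param x a volume, map, table or section object.
#' @return numeric(1), mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Access the role of a binary volume
#' @param x a BinaryVolume.
#' @return character(1): "mask", "airspace" or "composite".
#' @export
setGeneric("role", function(x) standardGeneric("role"))

#' Compute a 256-bin intensity histogram
#' @param x a VoxelGrid or SectionImage (16-bit data are rebinned to 256 bins).
#' @return an object of class "leafHistogram": list(counts, nbins, binWidth).
#' @export
setGeneric("intensityHistogram", function(x) standardGeneric("intensityHistogram"))

#' Crop a region of interest
#'
#' Crops the in-plane (y, x) extent, retaining the full depth, as when
#' selecting vein-free analysis regions.
#'
#' @param x a VoxelGrid or BinaryVolume.
#' @param roi integer(4): c(y0, x0, height, width), 1-based origin.
#' @return an object of the same class, cropped; the ROI is recorded in the
#'   "roi" attribute of the result for provenance.
#' @export
setGeneric("cropROI", function(x, roi) standardGeneric("cropROI"))

#' @rdname voxels
#' @export
setMethod("voxels", "VoxelGrid", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "BinaryVolume", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "ThicknessMap", function(x) x@values)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BinaryVolume", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ThicknessMap", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PoreTable", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "SectionImage", function(x) x@pixelSize)

#' @rdname role
#' @export
setMethod("role", "BinaryVolume", function(x) x@role)

#' Dimensions of a volume
#' @param x a VoxelGrid or BinaryVolume.
#' @return integer(3): slices (depth), rows (y), columns (x).
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@voxels))
#' @rdname dim-VoxelGrid-method
#' @export
setMethod("dim", "BinaryVolume", function(x) dim(x@voxels))

#' Pore records of a PoreTable
#' @param x a PoreTable.
#' @return data.frame(slice, label, area_mm2, perimeter_mm).
#' @export
setGeneric("poreRecords", function(x) standardGeneric("poreRecords"))
#' @rdname poreRecords
#' @export
setMethod("poreRecords", "PoreTable", function(x) x@records)

#' Per-slice mask areas of a PoreTable
#' @param x a PoreTable.
#' @return numeric vector of mask areas (mm^2), one per slice.
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname maskArea
#' @export
setMethod("maskArea", "PoreTable", function(x) x@maskArea)

#' @exportMethod show
setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelGrid: %d slices x %d x %d, %d-bit, voxel %.6g mm\n",
              d[1], d[2], d[3], object@bitDepth, object@voxelSize))
})

#' @exportMethod show
setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryVolume (%s): %d slices x %d x %d, voxel %.6g mm, %d true voxels\n",
              object@role, d[1], d[2], d[3], object@voxelSize,
              sum(object@voxels)))
})

#' @exportMethod show
setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: method %s, bin %d (raw %g), airspace = %s side\n",
              object@method, object@threshold, object@thresholdRaw,
              object@polarity))
})

#' @exportMethod show
setMethod("show", "PoreTable", function(object) {
  cat(sprintf("PoreTable: %d pore records over %d slices, voxel %.6g mm\n",
              nrow(object@records), object@sliceCount, object@voxelSize))
  if (nrow(object@records) > 0) {
    cat("First records:\n")
    print(head(object@records, 4))
  }
})

#' @exportMethod show
setMethod("show", "ThicknessMap", function(object) {
  nz <- sum(object@values > 0)
  cat(sprintf("ThicknessMap: %s voxels, %d in airspace, max diameter %.4g mm\n",
              paste(dim(object@values), collapse = " x "), nz,
              if (nz > 0) max(object@values) else 0))
})

#' @exportMethod show
setMethod("show", "SectionImage", function(object) {
  cat(sprintf("SectionImage: %d x %d px, pixel %.6g mm, W = %.4g mm\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              object@widthMM))
})

#' @exportMethod show
setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth\n  analytic:",
      paste(names(object@analytic), collapse = ", "),
      "\n  discrete:", paste(names(object@discrete), collapse = ", "), "\n")
})

#' Analytic ground truth of a phantom
#' @param x a PhantomTruth.
#' @return named list of continuous-geometry truth values.
#' @export
setGeneric("analyticTruth", function(x) standardGeneric("analyticTruth"))
#' @rdname analyticTruth
#' @export
setMethod("analyticTruth", "PhantomTruth", function(x) x@analytic)

#' Discrete (voxel-counted) ground truth of a phantom
#' @param x a PhantomTruth.
#' @return named list of voxel-counted truth values.
#' @export
setGeneric("discreteTruth", function(x) standardGeneric("discreteTruth"))
#' @rdname discreteTruth
#' @export
setMethod("discreteTruth", "PhantomTruth", function(x) x@discrete)
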