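#' @include AllClasses.R AllGenerics.R
NULL

#' Label connected components in a 2D slice
#'
#' @param slice logical matrix.
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return integer matrix of labels (background 0) with attribute "nlabels".
#' @export
labelSlice <- function(slice, connectivity = 8) {
  stopifnot(is.matrix(slice))
  storage.mode(slice) <- "logical"
  cpp_label2d(slice, as.integer(connectivity))
}

#' Corner-counting perimeter of a single 2D component
#'
#' Boundary length in pixel units under the corner-counting rule: each closed
#' contour (the component's outer boundary and, optionally, the boundary of
#' every solid island it encloses) is traced through boundary pixel centres;
#' axis-aligned steps count 1, diagonal steps count sqrt(2), and each contour
#' carries a corner allowance of 4 (an isolated pixel is a unit square of
#' perimeter 4; axis-aligned rectangles measure exactly 2(w + h)). Multiply
#' by the voxel size to calibrate to mm.
#'
#' @param component logical matrix containing exactly one connected component.
#' @param includeHoles add the contours of enclosed solid islands (a pore
#'   wrapped around a cell island exposes that island's surface too).
#' @return perimeter in pixel units (dimensionless).
#' @export
particlePerimeter <- function(component, includeHoles = TRUE) {
  stopifnot(is.matrix(component))
  storage.mode(component) <- "logical"
  if (!any(component))
    lsError("empty_component", "cannot measure the perimeter of an empty component")
  res <- cpp_analyze_slice(component, 8L, includeHoles)
  if (length(res$label) != 1L)
    lsError("not_single_component",
            sprintf("expected one connected component, found %d", length(res$label)))
  res$perimeter_px[1]
}

#' Per-slice pore analysis of an airspace stack
#'
#' The analyze-particles step: for every slice, every connected pore
#' component yields one record with calibrated area (pixel count x RES^2) and
#' corner-counting perimeter (boundary length x RES). Components touching the
#' slice edge are included (the mask already bounds the tissue). Per-slice
#' mask areas are recorded for the porosity and S_mes denominators.
#'
#' @param air airspace [BinaryVolume-class] (composite of threshold and mask).
#' @param mask leaf-disc mask [BinaryVolume-class] of the same shape.
#' @param connectivity in-plane pore connectivity, 8 (default) or 4.
#' @param includeHoles include the boundaries of enclosed solid islands in
#'   the pore perimeters.
#' @return A [PoreTable-class].
#' @export
analyzeStack <- function(air, mask, connectivity = 8, includeHoles = TRUE) {
  if (!identical(dim(voxels(air)), dim(voxels(mask))))
    lsError("shape_mismatch", "airspace and mask volumes differ in shape")
  av <- voxels(air)
  mv <- voxels(mask)
  if (any(av & !mv))
    lsError("air_outside_mask", "airspace voxels found outside the mask")
  res <- voxelSize(air)
  d <- dim(av)
  recs <- vector("list", d[1])
  maskAreaPx <- numeric(d[1])
  for (i in seq_len(d[1])) {
    maskAreaPx[i] <- sum(mv[i, , ])
    sl <- cpp_analyze_slice(av[i, , ], as.integer(connectivity), includeHoles)
    if (length(sl$label) > 0)
      recs[[i]] <- data.frame(slice = i, label = sl$label,
                              area_mm2 = sl$area_px * res^2,
                              perimeter_mm = sl$perimeter_px * res)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(slice = integer(0), label = integer(0),
               area_mm2 = numeric(0), perimeter_mm = numeric(0))
  new("PoreTable", records = records, voxelSize = res,
      sliceCount = as.integer(d[1]), maskArea = maskAreaPx * res^2)
}

#' Write a PoreTable to CSV
#'
#' @param table a [PoreTable-class].
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
writePoreTable <- function(table, path) {
  write.csv(poreRecords(table), path, row.names = FALSE)
  invisible(path)
}
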