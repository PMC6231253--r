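#' @include AllClasses.R AllGenerics.R
NULL

# Collapse a list of equally-shaped matrices (pages) into a (z, y, x) array.
pagesToArray <- function(pages) {
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' Read a multi-page TIFF stack as a VoxelGrid
#'
#' Pages are read in file order; page 1 becomes slice 1 (the adaxial-most
#' slice by the package's depth convention). Intensities are read without
#' rescaling. The voxel size is a required explicit parameter because scanner
#' TIFF dialects do not embed it reliably.
#'
#' @param path path to a multi-page grayscale TIFF (8- or 16-bit).
#' @param voxelSize voxel edge length in mm (e.g. 0.00275 for a 2.75 um scan).
#' @return A [VoxelGrid-class].
#' @export
readStack <- function(path, voxelSize) {
  if (!file.exists(path))
    lsError("missing_file", sprintf("stack file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  depths <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) 8L else as.integer(b)
  }, integer(1))
  if (any(!depths %in% c(8L, 16L)))
    lsError("unsupported_depth",
            sprintf("unsupported bit depth: %s (only 8 and 16 supported)",
                    paste(unique(depths[!depths %in% c(8L, 16L)]), collapse = ",")))
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    lsError("unsupported_depth",
            "multi-channel pages are not supported; expected grayscale")
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    lsError("ragged_pages",
            sprintf("pages differ in shape: %s", paste(unique(shapes), collapse = ", ")))
  VoxelGrid(pagesToArray(pages), voxelSize = voxelSize,
            bitDepth = max(depths))
}

#' Read a binary mask stack
#'
#' Reads a TIFF stack written by [writeStack()] (or any binary stack using
#' the foreground = nonzero convention) as a [BinaryVolume-class].
#'
#' @inheritParams readStack
#' @param role role to assign ("mask", "airspace" or "composite").
#' @return A [BinaryVolume-class].
#' @export
readBinaryStack <- function(path, voxelSize, role = "mask") {
  g <- readStack(path, voxelSize)
  BinaryVolume(voxels(g) != 0L, voxelSize = voxelSize, role = role)
}

#' Write a volume as a multi-page TIFF stack
#'
#' Grayscale volumes are written at their native bit depth without rescaling;
#' binary volumes are written as 8-bit stacks with foreground = 255 and
#' background = 0. Slice 1 becomes page 1.
#'
#' @param volume a [VoxelGrid-class] or [BinaryVolume-class].
#' @param path destination file path.
#' @return the path, invisibly.
#' @export
writeStack <- function(volume, path) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    lsError("unwritable_path", sprintf("cannot write to: %s", path))
  if (is(volume, "BinaryVolume")) {
    arr <- voxels(volume)
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(i) matrix(as.numeric(arr[i, , ]), nrow = dim(arr)[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  } else if (is(volume, "VoxelGrid")) {
    arr <- voxels(volume)
    den <- 2^volume@bitDepth - 1
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(i) matrix(arr[i, , ] / den, nrow = dim(arr)[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = volume@bitDepth,
                    compression = "none")
  } else {
    lsError("bad_type", "writeStack expects a VoxelGrid or BinaryVolume")
  }
  invisible(path)
}

#' Write a 32-bit float TIFF stack (e.g. a thickness map)
#'
#' @param map a [ThicknessMap-class].
#' @param path destination file path.
#' @return the path, invisibly.
#' @export
writeThicknessStack <- function(map, path) {
  arr <- voxels(map)
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(i) matrix(arr[i, , ], nrow = dim(arr)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Read a 2D section image for stereology
#'
#' Accepts single-image TIFF or PNG. PNG intensities are mapped to the 0-255
#' scale; TIFF intensities are read without rescaling.
#'
#' @param path image path (.tif/.tiff/.png).
#' @param pixelSize pixel edge length in mm.
#' @param widthMM analysed section width W (mm); when NULL, the image width
#'   in mm is used as a fallback.
#' @return A [SectionImage-class].
#' @export
readSectionImage <- function(path, pixelSize, widthMM = NULL) {
  if (!file.exists(path))
    lsError("missing_file", sprintf("section image not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- round(png::readPNG(path) * 255)
  } else {
    lsError("unsupported_depth", sprintf("unsupported image format: .%s", ext))
  }
  if (length(dim(px)) == 3L) px <- px[, , 1] # first channel of an RGB image
  SectionImage(px, pixelSize = pixelSize, widthMM = widthMM)
}

metricsHeader <- c("sample_id", "porosity_pct", "smes_mm2_per_mm2",
                   "pore_count", "leaf_thickness_mm",
                   "mean_channel_diameter_mm", "max_channel_diameter_mm")

#' Write sample metrics to CSV
#'
#' One row per sample with a fixed header; an empty record list produces a
#' header-only file. Decimal points are locale-independent.
#'
#' @param records a data.frame with the metrics columns (see
#'   [metricsRecord()]), or a list of such one-row data.frames.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
writeMetrics <- function(records, path) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (is.null(records) || nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(metricsHeader)),
                                      metricsHeader))
  }
  missing <- setdiff(metricsHeader, names(records))
  for (m in missing) records[[m]] <- NA_real_
  write.csv(records[, metricsHeader, drop = FALSE], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Assemble a metrics record
#'
#' @param sample_id sample identifier.
#' @param porosity_pct porosity in percent.
#' @param smes S_mes in mm^2 mm^-2.
#' @param pore_count number of 2D pore records.
#' @param leaf_thickness_mm leaf thickness in mm.
#' @param mean_channel_diameter_mm mean air-channel diameter (mm).
#' @param max_channel_diameter_mm maximum air-channel diameter (mm).
#' @return one-row data.frame.
#' @export
metricsRecord <- function(sample_id, porosity_pct, smes, pore_count,
                          leaf_thickness_mm = NA_real_,
                          mean_channel_diameter_mm = NA_real_,
                          max_channel_diameter_mm = NA_real_) {
  stopifnot(porosity_pct >= 0, porosity_pct <= 100, smes >= 0, pore_count >= 0)
  data.frame(sample_id = sample_id, porosity_pct = porosity_pct,
             smes_mm2_per_mm2 = smes, pore_count = pore_count,
             leaf_thickness_mm = leaf_thickness_mm,
             mean_channel_diameter_mm = mean_channel_diameter_mm,
             max_channel_diameter_mm = max_channel_diameter_mm,
             stringsAsFactors = FALSE)
}

#' Write a depth-resolved porosity profile to CSV
#'
#' Emits (slice_index, depth_mm, depth_norm, porosity_pct) rows, with
#' depth_mm = (slice_index - 1) * voxel size and depth_norm scaled to 0..1
#' across the stack.
#'
#' @param profile profile data.frame from [porosityProfile()].
#' @param path destination CSV path.
#' @param sample_id optional sample identifier column value.
#' @return the path, invisibly.
#' @export
writeProfile <- function(profile, path, sample_id = NULL) {
  if (!is.null(sample_id)) profile <- cbind(sample_id = sample_id, profile)
  write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
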