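#' @include AllClasses.R io.R segmentation.R particles.R metrics3d.R thickness3d.R
NULL

#' Read a batch run configuration
#'
#' YAML configuration for [runPipeline()]. Recognised fields:
#' \code{voxel_size_mm} (required), \code{threshold_method} (one method per
#' batch), \code{smes_denominator}, \code{min_particle_factor}, \code{roi}
#' (one ROI \code{[y0, x0, h, w]} or a list of several, averaged as technical
#' replicates), \code{mask} ("auto" or a mask stack path),
#' \code{closing_radius}, \code{thickness} (logical), \code{output_dir},
#' \code{seed}.
#'
#' @param path YAML file path.
#' @return a validated config list of class "leafRunConfig".
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    lsError("missing_file", sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  runConfig(cfg)
}

#' Build a batch run configuration in code
#'
#' @param cfg named list with the fields documented in [readRunConfig()].
#' @return a validated config list of class "leafRunConfig".
#' @export
runConfig <- function(cfg) {
  defaults <- list(threshold_method = "isodata", smes_denominator = "projected",
                   min_particle_factor = 3, roi = NULL, mask = "auto",
                   closing_radius = 5, thickness = TRUE, output_dir = NULL,
                   seed = 1L)
  for (n in names(defaults)) if (is.null(cfg[[n]])) cfg[[n]] <- defaults[[n]]
  if (is.null(cfg$voxel_size_mm) || cfg$voxel_size_mm <= 0)
    lsError("bad_config", "voxel_size_mm is required and must be positive")
  if (length(cfg$threshold_method) != 1L)
    lsError("bad_config",
            "one threshold method must be used for all samples in a batch")
  if (!is.null(cfg$roi) && !is.list(cfg$roi)) cfg$roi <- list(cfg$roi)
  class(cfg) <- "leafRunConfig"
  cfg
}

processOneSample <- function(sampleInput, sampleId, cfg) {
  grid <- if (is(sampleInput, "VoxelGrid")) sampleInput
          else readStack(sampleInput, cfg$voxel_size_mm)
  mask <- if (is(cfg$mask, "BinaryVolume")) cfg$mask
          else if (identical(cfg$mask, "auto"))
            makeLeafMask(grid, closingRadius = cfg$closing_radius)
          else readBinaryStack(cfg$mask, cfg$voxel_size_mm, role = "mask")
  thr <- autoThreshold(grid, cfg$threshold_method)
  air <- binarize(grid, thr)
  comp <- extractAirspace(air, mask)
  comp <- removeSmallParticles(comp, cfg$min_particle_factor)

  rois <- cfg$roi
  if (is.null(rois)) rois <- list(c(1L, 1L, dim(grid)[2], dim(grid)[3]))
  roiMetrics <- lapply(rois, function(roi) {
    a <- cropROI(comp, roi)
    m <- cropROI(mask, roi)
    leafMetrics(a, m, sample_id = sampleId,
                smesDenominator = cfg$smes_denominator,
                thicknessMap = isTRUE(cfg$thickness))
  })
  # average the technical-replicate ROIs into one record per sample
  recs <- do.call(rbind, lapply(roiMetrics, `[[`, "record"))
  num <- vapply(recs[, -1], mean, numeric(1))
  record <- cbind(data.frame(sample_id = sampleId), as.data.frame(t(num)))
  profiles <- lapply(roiMetrics, `[[`, "profile")
  prof <- profiles[[1]]
  if (length(profiles) > 1)
    prof$porosity_pct <- rowMeans(sapply(profiles, `[[`, "porosity_pct"))
  provenance <- list(sample_id = sampleId,
                     threshold_method = cfg$threshold_method,
                     threshold_bin = thr@threshold,
                     threshold_raw = thr@thresholdRaw,
                     min_particle_factor = cfg$min_particle_factor,
                     smes_denominator = cfg$smes_denominator,
                     rois = rois,
                     voxel_size_mm = cfg$voxel_size_mm,
                     mask_source = if (identical(cfg$mask, "auto")) "auto" else "supplied")
  list(record = record, profile = prof, provenance = provenance)
}

#' Run the full analysis pipeline over a batch of samples
#'
#' Per sample: mask creation (or a supplied mask) -> automatic threshold ->
#' airspace compositing -> noise removal -> per-ROI pore analysis and 3D
#' metrics, averaged over the ROIs as technical replicates. Per-sample
#' failures are isolated and reported; the batch continues. With an output
#' directory configured, writes metrics.csv, profiles.csv and per-sample
#' provenance JSON.
#'
#' @param config a "leafRunConfig" from [runConfig()] or [readRunConfig()].
#' @param samples named list (or character vector of stack paths); elements
#'   may be paths or in-memory [VoxelGrid-class] objects.
#' @return list(metrics, profiles, provenance, summary, failures): metrics is
#'   one data.frame row per successful sample; summary is the mean and SEM of
#'   each metric over the batch.
#' @export
runPipeline <- function(config, samples) {
  stopifnot(inherits(config, "leafRunConfig"))
  if (length(samples) == 0) {
    warning("empty sample list; nothing to do")
    return(list(metrics = writeEmptyMetrics(), profiles = list(),
                provenance = list(), summary = NULL, failures = list()))
  }
  ids <- names(samples)
  if (is.null(ids))
    ids <- if (is.character(samples))
      tools::file_path_sans_ext(basename(unlist(samples)))
    else sprintf("sample%02d", seq_along(samples))
  if (!is.list(samples)) samples <- as.list(samples)

  results <- vector("list", length(samples))
  failures <- list()
  for (i in seq_along(samples)) {
    # single-bracket assignment: `results[[i]] <- NULL` would delete the
    # element and misalign results with ids
    results[i] <- list(tryCatch(processOneSample(samples[[i]], ids[i], config),
      error = function(e) {
        warning(sprintf("sample '%s' failed: %s", ids[i], conditionMessage(e)))
        failures[[ids[i]]] <<- conditionMessage(e)
        NULL
      }))
  }
  ok <- !vapply(results, is.null, logical(1))
  metrics <- if (any(ok))
    do.call(rbind, lapply(results[ok], `[[`, "record")) else writeEmptyMetrics()
  profiles <- lapply(results[ok], `[[`, "profile")
  names(profiles) <- ids[ok]
  provenance <- lapply(results[ok], `[[`, "provenance")
  names(provenance) <- ids[ok]
  summary <- if (any(ok)) summarizeMetrics(metrics) else NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    writeMetrics(metrics, file.path(config$output_dir, "metrics.csv"))
    if (length(profiles) > 0) {
      allProf <- do.call(rbind, lapply(names(profiles), function(n)
        cbind(sample_id = n, profiles[[n]])))
      write.csv(allProf, file.path(config$output_dir, "profiles.csv"),
                row.names = FALSE)
    }
    provDir <- file.path(config$output_dir, "provenance")
    dir.create(provDir, showWarnings = FALSE)
    for (n in names(provenance))
      jsonlite::write_json(provenance[[n]],
                           file.path(provDir, paste0(n, ".json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(metrics = metrics, profiles = profiles, provenance = provenance,
       summary = summary, failures = failures)
}

writeEmptyMetrics <- function() {
  as.data.frame(setNames(rep(list(numeric(0)), length(metricsHeader)),
                         metricsHeader))
}

#' Batch summary: mean and standard error per metric
#'
#' Descriptive mean +/- SEM over the samples of a batch, as used for
#' between-species comparisons of porosity and S_mes.
#'
#' @param metrics metrics data.frame from [runPipeline()].
#' @return data.frame(metric, mean, sem, n).
#' @export
summarizeMetrics <- function(metrics) {
  num <- metrics[, setdiff(names(metrics), "sample_id"), drop = FALSE]
  data.frame(metric = names(num),
             mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1)),
             sem = vapply(num, function(v) {
               v <- v[!is.na(v)]
               if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
             }, numeric(1)),
             n = vapply(num, function(v) sum(!is.na(v)), numeric(1)),
             row.names = NULL)
}
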