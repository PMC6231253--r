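#' @include AllClasses.R AllGenerics.R
NULL

makeHistogram <- function(values, bitDepth) {
  if (bitDepth == 16L) {
    bin <- values %/% 256L          # rebin 16-bit to 256 bins
    binWidth <- 256L
  } else {
    bin <- values
    binWidth <- 1L
  }
  counts <- tabulate(bin + 1L, nbins = 256L)
  structure(list(counts = counts, nbins = 256L, binWidth = binWidth),
            class = "leafHistogram")
}

#' @rdname intensityHistogram
#' @export
setMethod("intensityHistogram", "VoxelGrid", function(x)
  makeHistogram(as.vector(x@voxels), x@bitDepth))

#' @rdname intensityHistogram
#' @export
setMethod("intensityHistogram", "SectionImage", function(x)
  makeHistogram(as.integer(x@pixels),
                if (max(x@pixels) > 255) 16L else 8L))

# class means of a 256-bin histogram split after bin t (0-based): bins 0..t
# versus t+1..255; returns c(low, high) or NA for an empty class
classMeans <- function(counts, t) {
  bins <- 0:255
  lowN <- sum(counts[1:(t + 1)])
  highN <- sum(counts) - lowN
  low <- if (lowN > 0) sum(counts[1:(t + 1)] * bins[1:(t + 1)]) / lowN else NA_real_
  high <- if (highN > 0)
    sum(counts[(t + 2):256] * bins[(t + 2):256]) / highN else NA_real_
  c(low, high)
}

thresholdIsodata <- function(counts) {
  # Ridler-Calvard: iterate t <- floor of the midpoint of the two class
  # means, initialised at the histogram mean; floor breaks ties toward the
  # lower bin
  bins <- 0:255
  t <- floor(sum(counts * bins) / sum(counts))
  nonempty <- which(counts > 0) - 1L
  t <- min(max(t, min(nonempty)), max(nonempty) - 1L)
  for (i in 1:256) {
    m <- classMeans(counts, t)
    if (any(is.na(m))) break
    tn <- floor((m[1] + m[2]) / 2)
    tn <- min(max(tn, min(nonempty)), max(nonempty) - 1L)
    if (tn == t) break
    t <- tn
  }
  as.integer(t)
}

# Li minimum cross-entropy on 1-offset bin values (avoids log(0) at bin 0):
# exhaustive minimisation of the cross-entropy criterion
#   eta(t) = -(S_b ln mu_b + S_f ln mu_f),  S = sum of value-weighted counts.
# Li's iterative scheme (tau' = (mu_f - mu_b)/(ln mu_f - ln mu_b)) is only a
# speedup for this minimisation, and because the criterion is nearly flat
# across the inter-mode valley the fixed point can sit far from the argmin at
# a numerically identical objective; the global scan is the defining form.
# Ties resolve toward the lower bin.
thresholdLi <- function(counts) {
  v <- 1:256 # 1-offset bin values
  cumN <- cumsum(counts)
  cumS <- cumsum(counts * v)
  N <- cumN[256]; S <- cumS[256]
  best <- Inf
  bestT <- NA_integer_
  for (t in 1:255) {
    nb <- cumN[t]; nf <- N - nb
    if (nb == 0 || nf == 0) next
    sb <- cumS[t]; sf <- S - sb
    eta <- -(sb * log(sb / nb) + sf * log(sf / nf))
    if (eta < best - 1e-12) { best <- eta; bestT <- t }
  }
  # background = bins 0-based 0..t-1, so the threshold bin is t - 1
  as.integer(bestT - 1L)
}

# Kapur maximum entropy: argmax over t of the entropy of the normalised
# below-t distribution plus the entropy of the above-t distribution
thresholdMaxEntropy <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf
  bestT <- NA_integer_
  cum <- cumsum(p)
  for (t in 0:254) {
    P0 <- cum[t + 1]
    P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    q0 <- p[1:(t + 1)] / P0
    q1 <- p[(t + 2):256] / P1
    H <- -sum(q0[q0 > 0] * log(q0[q0 > 0])) - sum(q1[q1 > 0] * log(q1[q1 > 0]))
    if (H > best + 1e-12) { best <- H; bestT <- t } # ties toward the lower bin
  }
  as.integer(bestT)
}

#' Automatic histogram threshold selection
#'
#' Selects a threshold on the 256-bin intensity histogram using one of the
#' methods used in the leaf airspace pipeline: IsoData (Ridler-Calvard
#' iterated class-means midpoint), Li (exhaustive minimisation of the
#' minimum cross-entropy criterion) or maximum entropy (Kapur; exhaustive
#' argmax of the two-class entropy sum). Voxels at or below the returned raw
#' threshold are the low-attenuation (airspace) side.
#'
#' @param x a [VoxelGrid-class], [SectionImage-class] or a histogram from
#'   [intensityHistogram()].
#' @param method "isodata", "li" or "max_entropy". The same method should be
#'   used for every sample within a study.
#' @return A [ThresholdResult-class].
#' @export
autoThreshold <- function(x, method = c("isodata", "li", "max_entropy")) {
  if (length(method) != 1L || !method %in% c("isodata", "li", "max_entropy"))
    lsError("unknown_method",
            sprintf("unknown threshold method: %s",
                    paste(method, collapse = "/")))
  hist <- if (inherits(x, "leafHistogram")) x else intensityHistogram(x)
  if (sum(hist$counts > 0) < 2L)
    lsError("degenerate_histogram",
            "histogram has fewer than two populated bins; cannot threshold")
  t <- switch(method,
              isodata = thresholdIsodata(hist$counts),
              li = thresholdLi(hist$counts),
              max_entropy = thresholdMaxEntropy(hist$counts))
  raw <- (t + 1L) * hist$binWidth - 1L  # upper edge of the selected bin
  new("ThresholdResult", method = method, threshold = t,
      thresholdRaw = as.numeric(raw), polarity = "low")
}

#' Binarize a grayscale volume into an airspace volume
#'
#' Voxels on the low-intensity side of the threshold (intensity <= raw
#' threshold) become airspace: air attenuates X-rays less than tissue.
#'
#' @param grid a [VoxelGrid-class].
#' @param thr a [ThresholdResult-class] (or a single raw threshold value).
#' @return A [BinaryVolume-class] with role "airspace".
#' @export
binarize <- function(grid, thr) {
  raw <- if (is(thr, "ThresholdResult")) thr@thresholdRaw else as.numeric(thr)
  BinaryVolume(voxels(grid) <= raw, voxelSize = voxelSize(grid),
               role = "airspace")
}
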