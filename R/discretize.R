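#' Fixed-bin-count discretization of a region
#'
#' Maps in-mask intensities to integer gray levels `1..n_bins` with equal
#' bin widths spanning the in-mask min-max range:
#' `bin(v) = min(floor((I(v) - min) / ((max - min)/n_bins)) + 1, n_bins)`.
#' A constant region (zero range) maps every voxel to bin 1. Out-of-mask
#' voxels carry `NA`.
#'
#' @param image an [image_grid].
#' @param mask binary [image_grid] on the same grid, non-empty.
#' @param n_bins number of gray levels, >= 1.
#' @return object of class `discretized_region`: list with `labels` (integer
#'   array, `NA` outside the mask), `n_bins`, `range` (in-mask min/max) and
#'   the mask's geometry fields.
#' @export
discretize_fixed_bin_count <- function(image, mask, n_bins) {
  stopifnot(is_image_grid(image))
  assert_mask(mask)
  stop_if_misaligned(image, mask, "image and mask")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    stop("`n_bins` must be a positive integer", call. = FALSE)
  idx <- which(mask$voxels == 1)
  if (!length(idx)) stop("mask is empty; nothing to discretize", call. = FALSE)
  vals <- image$voxels[idx]
  lo <- min(vals); hi <- max(vals)
  labels <- array(NA_integer_, dim = dim(image$voxels))
  if (hi == lo || n_bins == 1L) {
    labels[idx] <- 1L
  } else {
    width <- (hi - lo) / n_bins
    labels[idx] <- pmin(as.integer(floor((vals - lo) / width)) + 1L, n_bins)
  }
  structure(list(labels = labels, n_bins = n_bins, range = c(lo, hi),
                 spacing = mask$spacing, origin = mask$origin),
            class = "discretized_region")
}

#' First-order intensity statistics of a region
#'
#' The 18 intensity statistics computed on the raw (undiscretized) in-mask
#' values; `Entropy` and `Uniformity` alone use a fixed-bin-count histogram
#' at `ref_bins` gray levels. Percentiles use linear interpolation between
#' order statistics; `Variance`, `Skewness` and `Kurtosis` are population
#' moments (kurtosis is not excess-corrected, so a Gaussian gives 3).
#' Regions below `min_voxels` return all-`NA` with a `too_small` attribute.
#'
#' @param image an [image_grid].
#' @param mask binary [image_grid] on the same grid.
#' @param ref_bins bin count for the entropy/uniformity histogram.
#' @param min_voxels minimum region size.
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(image, mask, ref_bins = 50, min_voxels = 27) {
  stopifnot(is_image_grid(image))
  assert_mask(mask)
  stop_if_misaligned(image, mask, "image and mask")
  idx <- which(mask$voxels == 1)
  nm <- first_order_names()
  if (length(idx) < min_voxels) {
    out <- rep(NA_real_, length(nm))
    names(out) <- nm
    attr(out, "too_small") <- TRUE
    return(out)
  }
  x <- image$voxels[idx]
  n <- length(x)
  vv <- prod(image$spacing)  # mm^3
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[5]]
  disc <- discretize_fixed_bin_count(image, mask, ref_bins)
  p <- tabulate(disc$labels[idx], nbins = disc$n_bins) / n
  p <- p[p > 0]
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  names(out) <- nm
  out
}

first_order_names <- function() c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
  "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
)
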