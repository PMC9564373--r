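# Separable 3D filtering primitives used by the LoG and wavelet image types.

# 1D convolution along one axis of a 3D array with a centred kernel.
# boundary: "mirror" reflects without repeating the edge sample (like cell
# boundaries in scipy's reflect mode with mode="mirror"), "wrap" is periodic.
conv_axis <- function(arr, kernel, axis, boundary = c("mirror", "wrap")) {
  boundary <- match.arg(boundary)
  d <- dim(arr)
  k <- length(kernel)
  r_lo <- (k - 1L) %/% 2L      # taps on the negative side
  r_hi <- k - 1L - r_lo
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  n <- dp[1]
  x <- matrix(x, nrow = n)

  idx <- function(i) {
    # map out-of-range 1-based indices into range per boundary rule
    if (boundary == "wrap") return(((i - 1L) %% n) + 1L)
    # mirror about the edge samples: ..., 3, 2, 1, 2, 3, ... (no duplication)
    if (n == 1L) return(rep(1L, length(i)))
    p <- (i - 1L) %% (2L * (n - 1L))
    p <- ifelse(p < 0, p + 2L * (n - 1L), p)
    ifelse(p >= n, 2L * (n - 1L) - p, p) + 1L
  }
  out <- matrix(0, nrow = n, ncol = ncol(x))
  base <- seq_len(n)
  for (j in seq_len(k)) {
    off <- j - 1L - r_lo
    # y[i] = sum_j kernel[j] * x[i + off]
    out <- out + kernel[j] * x[idx(base + off), , drop = FALSE]
  }
  out <- array(out, dim = dp)
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma_vox, deriv = 0) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (deriv == 0) return(g)
  # sampled second derivative of the (normalized) Gaussian
  g2 <- g * ((x^2 - sigma_vox^2) / sigma_vox^4)
  g2 - mean(g2)  # zero DC so constants map to exactly 0
}

#' Laplacian-of-Gaussian filter with sigma in physical millimetres
#'
#' Smooths with an isotropic Gaussian of standard deviation `sigma` mm
#' (converted to voxel units per axis through the grid spacing) and applies
#' the Laplacian, as the sum over axes of the second-derivative-of-Gaussian
#' response. Boundary handling is mirror reflection. The output shares the
#' input grid.
#'
#' @param image an [image_grid].
#' @param sigma Gaussian scale in mm, > 0.
#' @return filtered [image_grid].
#' @export
log_filter <- function(image, sigma) {
  stopifnot(is_image_grid(image))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number (mm)", call. = FALSE)
  sp <- image$spacing
  out <- array(0, dim = dim(image$voxels))
  for (a in 1:3) {
    part <- image$voxels
    for (b in 1:3) {
      # second derivative along axis a (in physical mm), smoothing along others
      kern <- gaussian_kernel_1d(sigma / sp[b], deriv = as.integer(b == a) * 2)
      if (b == a) kern <- kern / sp[b]^2  # voxel^-2 -> mm^-2
      part <- conv_axis(part, kern, b, boundary = "mirror")
    }
    out <- out + part
  }
  image_grid(out, image$spacing, image$origin)
}

# coiflet-1 orthonormal analysis filters (6 taps)
coif1_lo <- c(-0.015655728135464787, -0.07273261951285417, 0.3848648468648578,
              0.8525720202122554, 0.33789766245780922, -0.07273261951285417)
coif1_hi <- rev(coif1_lo) * c(1, -1, 1, -1, 1, -1)

# circular (periodic) filtering along one axis: y[i] = sum_k h[k] x[i + k - 1]
# reverse = TRUE applies the adjoint (correlation), used for reconstruction.
wavelet_axis <- function(arr, h, axis, reverse = FALSE) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  n <- dp[1]
  x <- matrix(x, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(x))
  base <- seq_len(n)
  for (k in seq_along(h)) {
    off <- if (reverse) -(k - 1L) else (k - 1L)
    ii <- ((base + off - 1L) %% n) + 1L
    out <- out + h[k] * x[ii, , drop = FALSE]
  }
  aperm(array(out, dim = dp), order(perm))
}

#' Single-level undecimated 3D coiflet-1 wavelet decomposition
#'
#' Separable stationary (undecimated) wavelet transform with the 6-tap
#' coiflet-1 analysis pair, applied along x, y and z with periodic boundary.
#' The 8 subbands stay on the original grid, so region masks apply without
#' resampling. Subband labels give the filter per axis in (x, y, z) order:
#' `HLL` is high-pass along x, low-pass along y and z.
#'
#' @param image an [image_grid]; every axis must be at least as long as the
#'   6-tap filter.
#' @return named list of 8 [image_grid] subbands
#'   (LLL, HLL, LHL, LLH, LHH, HLH, HHL, HHH).
#' @export
wavelet_decompose <- function(image) {
  stopifnot(is_image_grid(image))
  d <- dim(image$voxels)
  if (any(d < length(coif1_lo)))
    stop("every axis must have length >= ", length(coif1_lo),
         " for the coif1 transform", call. = FALSE)
  labels <- c("LLL", "HLL", "LHL", "LLH", "LHH", "HLH", "HHL", "HHH")
  out <- vector("list", 8)
  names(out) <- labels
  for (lab in labels) {
    sub <- image$voxels
    letters3 <- strsplit(lab, "")[[1]]
    for (a in 1:3) {
      h <- if (letters3[a] == "L") coif1_lo else coif1_hi
      sub <- wavelet_axis(sub, h, a)
    }
    out[[lab]] <- image_grid(sub, image$spacing, image$origin)
  }
  out
}

#' Reconstruct a volume from its undecimated coif1 subbands
#'
#' Inverse of [wavelet_decompose]: applies the adjoint filters and sums the
#' subbands; exact to floating-point because the orthonormal pair satisfies
#' the power-complementarity identity per axis.
#'
#' @param subbands named list returned by [wavelet_decompose].
#' @return reconstructed [image_grid].
#' @export
wavelet_reconstruct <- function(subbands) {
  labels <- names(subbands)
  acc <- NULL
  for (lab in labels) {
    sub <- subbands[[lab]]$voxels
    letters3 <- strsplit(lab, "")[[1]]
    for (a in 1:3) {
      h <- if (letters3[a] == "L") coif1_lo else coif1_hi
      sub <- wavelet_axis(sub, h, a, reverse = TRUE)
    }
    acc <- if (is.null(acc)) sub else acc + sub
  }
  ref <- subbands[[1]]
  image_grid(acc / 8, ref$spacing, ref$origin)
}
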