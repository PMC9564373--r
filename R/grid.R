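#' 3D image grid with physical geometry
#'
#' `image_grid` is the common carrier for CT volumes, dose distributions and
#' binary masks: a 3D numeric array in (x, y, z) axis order together with the
#' voxel spacing (mm) and the physical position of the first voxel centre
#' (origin, mm) in a right-handed patient frame. Voxel indices are 0-based in
#' physical mapping: the centre of voxel `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing`. All geometry-dependent computation in the
#' package (moments, LoG sigma, shape descriptors, DVH absolute volumes) works
#' in physical millimetres through this mapping.
#'
#' @param voxels 3D numeric array, axis order (x, y, z).
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(array(0, c(4, 4, 4)), spacing = c(3, 3, 3))
#' dim(g$voxels)
#' @export
image_grid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  v <- x$voxels
  cat(sprintf("  values in [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$voxels)

is_image_grid <- function(x) inherits(x, "image_grid")

#' Assert a grid is a valid dose grid (non-negative, finite, in Gy)
#' @param dose an `image_grid` of absorbed dose in Gy.
#' @return `dose`, invisibly, after validation.
#' @export
assert_dose_grid <- function(dose) {
  stopifnot(is_image_grid(dose))
  if (any(!is.finite(dose$voxels)))
    stop("dose grid contains non-finite values", call. = FALSE)
  if (any(dose$voxels < 0))
    stop("dose grid contains negative values", call. = FALSE)
  invisible(dose)
}

#' Assert a grid is a binary mask
#' @param mask an `image_grid` with values in {0, 1}.
#' @return `mask`, invisibly, after validation.
#' @export
assert_mask <- function(mask) {
  stopifnot(is_image_grid(mask))
  v <- mask$voxels
  if (any(v != 0 & v != 1))
    stop("mask is not binary", call. = FALSE)
  invisible(mask)
}

#' Binarize an image grid by thresholding
#' @param grid an `image_grid`.
#' @param threshold values > threshold become 1, others 0.
#' @return a binary `image_grid` with the same geometry.
#' @export
as_mask <- function(grid, threshold = 0.5) {
  stopifnot(is_image_grid(grid))
  image_grid((grid$voxels > threshold) * 1, grid$spacing, grid$origin)
}

# geometry equality within tolerance (spacing/origin in mm)
same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(what, " are not on the same grid (shape/spacing/origin mismatch); ",
         "resample first", call. = FALSE)
  invisible(TRUE)
}

# physical coordinates (mm) of in-mask voxels as an n x 3 matrix
mask_coords_mm <- function(mask) {
  idx <- which(mask$voxels == 1, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000
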