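#' Resample a volume onto a reference grid
#'
#' Samples `src` at the physical voxel-centre positions of `ref`. Intensity
#' images and dose use trilinear interpolation; masks use nearest-neighbour
#' (see [resample_dose_to] and [resample_mask_to]). Positions outside the
#' source voxel-centre extent receive `default`.
#'
#' @param src source [image_grid].
#' @param ref reference [image_grid] defining the output geometry.
#' @param method `"linear"` (trilinear) or `"nearest"`.
#' @param default value for out-of-extent voxels.
#' @return an [image_grid] on `ref`'s geometry. If the two geometries are
#'   identical the source voxels are returned unchanged (exact identity).
#' @export
resample_to <- function(src, ref, method = c("linear", "nearest"), default = 0) {
  stopifnot(is_image_grid(src), is_image_grid(ref))
  method <- match.arg(method)
  if (same_geometry(src, ref))
    return(image_grid(src$voxels, ref$spacing, ref$origin))

  ds <- dim(src$voxels)
  dr <- dim(ref$voxels)
  # physical extent overlap check (voxel-centre extents)
  for (a in 1:3) {
    s_lo <- src$origin[a]; s_hi <- src$origin[a] + (ds[a] - 1) * src$spacing[a]
    r_lo <- ref$origin[a]; r_hi <- ref$origin[a] + (dr[a] - 1) * ref$spacing[a]
    if (s_hi < r_lo || r_hi < s_lo)
      stop("source and reference grids have no physical overlap on axis ", a,
           call. = FALSE)
  }
  # continuous source indices (0-based) of each reference voxel centre, per axis
  u <- lapply(1:3, function(a) {
    pos <- ref$origin[a] + (seq_len(dr[a]) - 1) * ref$spacing[a]
    (pos - src$origin[a]) / src$spacing[a]
  })
  expand_axis <- function(v, axis) {
    if (axis == 1) array(v, dim = dr)
    else if (axis == 2) array(rep(v, each = dr[1]), dim = dr)
    else array(rep(v, each = dr[1] * dr[2]), dim = dr)
  }
  tol <- 1e-6
  inside <- expand_axis(u[[1]] >= -tol & u[[1]] <= ds[1] - 1 + tol, 1) &
    expand_axis(u[[2]] >= -tol & u[[2]] <= ds[2] - 1 + tol, 2) &
    expand_axis(u[[3]] >= -tol & u[[3]] <= ds[3] - 1 + tol, 3)

  gather <- function(ix, iy, iz) {
    # ix/iy/iz: 0-based integer index arrays, already clamped
    src$voxels[1L + ix + ds[1] * (iy + ds[2] * iz)]
  }
  clamp <- function(v, n) pmin(pmax(v, 0L), n - 1L)

  if (method == "nearest") {
    ix <- expand_axis(clamp(as.integer(round(u[[1]])), ds[1]), 1)
    iy <- expand_axis(clamp(as.integer(round(u[[2]])), ds[2]), 2)
    iz <- expand_axis(clamp(as.integer(round(u[[3]])), ds[3]), 3)
    out <- array(gather(ix, iy, iz), dim = dr)
  } else {
    f <- lapply(1:3, function(a) pmin(pmax(floor(u[[a]]), 0), ds[a] - 1))
    w <- lapply(1:3, function(a) pmin(pmax(u[[a]] - f[[a]], 0), 1))
    f0 <- lapply(1:3, function(a) clamp(as.integer(f[[a]]), ds[a]))
    f1 <- lapply(1:3, function(a) clamp(f0[[a]] + 1L, ds[a]))
    out <- array(0, dim = dr)
    for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
      wx <- if (bx == 0) 1 - w[[1]] else w[[1]]
      wy <- if (by == 0) 1 - w[[2]] else w[[2]]
      wz <- if (bz == 0) 1 - w[[3]] else w[[3]]
      ix <- if (bx == 0) f0[[1]] else f1[[1]]
      iy <- if (by == 0) f0[[2]] else f1[[2]]
      iz <- if (bz == 0) f0[[3]] else f1[[3]]
      wt <- expand_axis(wx, 1) * expand_axis(wy, 2) * expand_axis(wz, 3)
      out <- out + wt * gather(expand_axis(ix, 1), expand_axis(iy, 2),
                               expand_axis(iz, 3))
    }
  }
  out[!inside] <- default
  image_grid(out, ref$spacing, ref$origin)
}

#' Align a dose grid to a reference (CT) grid by trilinear interpolation
#'
#' Lung voxels outside the dose calculation box are assigned 0 Gy (they
#' received negligible dose); a warning reports how many reference voxels
#' fell outside the dose extent.
#'
#' @param dose dose [image_grid] (Gy).
#' @param ref reference [image_grid] (typically the planning CT).
#' @return dose resampled onto `ref`'s grid.
#' @export
resample_dose_to <- function(dose, ref) {
  assert_dose_grid(dose)
  out <- resample_to(dose, ref, method = "linear", default = NA_real_)
  n_out <- sum(is.na(out$voxels))
  if (n_out > 0)
    warning(n_out, " reference voxels lie outside the dose extent; set to 0 Gy",
            call. = FALSE)
  out$voxels[is.na(out$voxels)] <- 0
  out$voxels[out$voxels < 0] <- 0
  out
}

#' Align a binary mask to a reference grid by nearest-neighbour sampling
#' @param mask binary [image_grid].
#' @param ref reference [image_grid].
#' @return binary mask on `ref`'s grid.
#' @export
resample_mask_to <- function(mask, ref) {
  assert_mask(mask)
  out <- resample_to(mask, ref, method = "nearest", default = 0)
  as_mask(out, 0.5)
}
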