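# Dose features per region: scale-invariant 3D dose moments, DVH parameters
# and dose-map dosiomics.

#' Central spatial moment of a dose distribution
#'
#' `mu_pqr = sum_v (x_v - xbar)^p (y_v - ybar)^q (z_v - zbar)^r D(v)` over
#' in-mask voxels, with `(xbar, ybar, zbar)` the dose-weighted centroid and
#' all coordinates in physical millimetres.
#'
#' @param dose dose [image_grid] (Gy), aligned to `mask`.
#' @param mask non-empty binary [image_grid].
#' @param p,q,r non-negative integer orders.
#' @return the central moment (Gy * mm^(p+q+r)).
#' @export
central_moment <- function(dose, mask, p, q, r) {
  cm <- moment_context(dose, mask)
  sum(cm$dx^p * cm$dy^q * cm$dz^r * cm$w)
}

moment_context <- function(dose, mask) {
  assert_dose_grid(dose)
  assert_mask(mask)
  stop_if_misaligned(dose, mask, "dose and mask")
  idx <- which(mask$voxels == 1)
  if (!length(idx))
    stop("mask is empty; moments are undefined", call. = FALSE)
  w <- dose$voxels[idx]
  if (sum(w) <= 0)
    stop("total dose in the region is zero; moments are undefined",
         call. = FALSE)
  co <- mask_coords_mm(mask)
  cx <- sum(co[, 1] * w) / sum(w)
  cy <- sum(co[, 2] * w) / sum(w)
  cz <- sum(co[, 3] * w) / sum(w)
  list(dx = co[, 1] - cx, dy = co[, 2] - cy, dz = co[, 3] - cz, w = w)
}

#' Scale-invariant 3D dose moment
#'
#' `eta_pqr = mu_pqr / mu_000^((p+q+r)/3 + 1)`. The normalisation makes the
#' moment invariant to isotropic scaling of the dose object and to rigid
#' translation (the latter exactly, by the central-moment construction);
#' `eta_000` is identically 1.
#'
#' @inheritParams central_moment
#' @return the dimension-reduced moment (units Gy^(-(p+q+r)/3) * mm^0).
#' @export
scale_invariant_moment <- function(dose, mask, p, q, r) {
  cm <- moment_context(dose, mask)
  mu <- sum(cm$dx^p * cm$dy^q * cm$dz^r * cm$w)
  mu0 <- sum(cm$w)
  mu / mu0^((p + q + r) / 3 + 1)
}

#' The 63 scale-invariant dose moments of a region
#'
#' All order triples `(p, q, r)` with each order in 0..3, excluding
#' `(0, 0, 0)` whose value is constant 1.
#'
#' @inheritParams central_moment
#' @return named numeric vector of 63 values (`eta_p_q_r`).
#' @export
dose_moments <- function(dose, mask) {
  cm <- moment_context(dose, mask)
  mu0 <- sum(cm$w)
  # precompute coordinate powers once
  px <- lapply(0:3, function(p) cm$dx^p)
  py <- lapply(0:3, function(q) cm$dy^q)
  pz <- lapply(0:3, function(r) cm$dz^r)
  out <- numeric(0)
  for (p in 0:3) for (q in 0:3) for (r in 0:3) {
    if (p == 0 && q == 0 && r == 0) next
    mu <- sum(px[[p + 1]] * py[[q + 1]] * pz[[r + 1]] * cm$w)
    v <- mu / mu0^((p + q + r) / 3 + 1)
    names(v) <- sprintf("eta_%d_%d_%d", p, q, r)
    out <- c(out, v)
  }
  out
}

#' Cumulative dose-volume histogram of a region
#'
#' For each dose level d on a regular axis, the relative volume is the
#' percentage of region voxels with dose strictly greater than d; the
#' absolute volume applies the voxel volume in cc. The curve starts at 100%
#' for d < min dose . . . and reaches 0 beyond the region maximum.
#'
#' @param dose dose [image_grid] (Gy), aligned to `mask`.
#' @param mask non-empty binary [image_grid].
#' @param resolution dose axis step (Gy).
#' @return object of class `dvh_curve`: data.frame with columns `dose_gy`,
#'   `rel_volume_pct`, `abs_volume_cc`.
#' @export
cumulative_dvh <- function(dose, mask, resolution = 0.1) {
  assert_dose_grid(dose)
  assert_mask(mask)
  stop_if_misaligned(dose, mask, "dose and mask")
  idx <- which(mask$voxels == 1)
  if (!length(idx)) stop("mask is empty; DVH undefined", call. = FALSE)
  d <- dose$voxels[idx]
  vv <- voxel_volume_cc(dose)
  axis <- seq(0, max(d) + resolution, by = resolution)
  # fraction of voxels with dose > level, via the empirical CDF
  frac_gt <- 1 - stats::ecdf(d)(axis)
  out <- data.frame(dose_gy = axis,
                    rel_volume_pct = 100 * frac_gt,
                    abs_volume_cc = length(d) * vv * frac_gt)
  class(out) <- c("dvh_curve", "data.frame")
  out
}

dvh_vx_levels <- function() seq(5, 80, by = 5)
dvh_dx_levels <- function() c(1, 2, 5, seq(10, 95, by = 5), 98, 99)

#' DVH parameters of a region
#'
#' The frozen 59-member parameter set: `Vx` relative (% of region volume
#' receiving more than x Gy) and absolute (cc) for x in 5..80 Gy step 5
#' (16 + 16 values); `Dx` (Gy received by the hottest x% of the region,
#' the (100-x)th percentile of voxel doses with linear interpolation) for
#' x in {1, 2, 5, 10, ..., 95, 98, 99}% (23 values); and mean, median,
#' minimum and maximum dose (4 values). `Vx` uses the strict inequality
#' "more than x Gy".
#'
#' @inheritParams cumulative_dvh
#' @return named numeric vector of 59 values.
#' @export
dvh_parameters <- function(dose, mask) {
  assert_dose_grid(dose)
  assert_mask(mask)
  stop_if_misaligned(dose, mask, "dose and mask")
  idx <- which(mask$voxels == 1)
  if (!length(idx)) stop("mask is empty; DVH undefined", call. = FALSE)
  d <- dose$voxels[idx]
  vv <- voxel_volume_cc(dose)
  vx <- dvh_vx_levels()
  frac <- vapply(vx, function(x) mean(d > x), numeric(1))
  dx <- dvh_dx_levels()
  dvals <- stats::quantile(d, probs = 1 - dx / 100, names = FALSE, type = 7)
  out <- c(
    stats::setNames(100 * frac, sprintf("V%d_rel", vx)),
    stats::setNames(length(d) * vv * frac, sprintf("V%d_abs", vx)),
    stats::setNames(dvals, sprintf("D%d", dx)),
    MeanDose = mean(d), MedianDose = stats::median(d),
    MinDose = min(d), MaxDose = max(d)
  )
  stopifnot(length(out) == 59L)
  out
}

dvh_parameter_names <- function() c(
  sprintf("V%d_rel", dvh_vx_levels()), sprintf("V%d_abs", dvh_vx_levels()),
  sprintf("D%d", dvh_dx_levels()),
  "MeanDose", "MedianDose", "MinDose", "MaxDose"
)

#' Dose-map dosiomics of a region
#'
#' The 18 first-order plus 73 texture features of the radiomics engine
#' applied to the unfiltered dose distribution, discretized at a fixed bin
#' count (91 features). Names are `firstorder|x` / `family|x`.
#'
#' @inheritParams cumulative_dvh
#' @param n_bins fixed bin count for the dose-map discretization.
#' @param min_voxels regions below this size give all-`NA`.
#' @return named numeric vector of 91 values.
#' @export
dose_texture_features <- function(dose, mask, n_bins = 50, min_voxels = 27) {
  assert_dose_grid(dose)
  assert_mask(mask)
  fo <- first_order_features(dose, mask, ref_bins = n_bins,
                             min_voxels = min_voxels)
  names(fo) <- paste("firstorder", names(fo), sep = "|")
  if (isTRUE(attr(fo, "too_small"))) {
    tx <- rep(NA_real_, 73)
    names(tx) <- texture_feature_names()
  } else {
    disc <- discretize_fixed_bin_count(dose, mask, n_bins)
    tx <- texture_features(disc, min_voxels = min_voxels)
  }
  c(fo, tx)
}

dose_feature_names <- function(region = "region") {
  eta <- character(0)
  for (p in 0:3) for (q in 0:3) for (r in 0:3)
    if (p + q + r > 0) eta <- c(eta, sprintf("eta_%d_%d_%d", p, q, r))
  c(paste(region, "dose", "original", "na", "moments", eta, sep = "|"),
    paste(region, "dose", "original", "na", "dvh", dvh_parameter_names(),
          sep = "|"),
    paste(region, "dose", "original", "na", "firstorder",
          first_order_names(), sep = "|"),
    paste(region, "dose", "original", "b50", texture_feature_names(),
          sep = "|"))
}

#' Extract all 213 dose features for one region
#'
#' Concatenates the 63 scale-invariant dose moments, the 59 DVH parameters
#' and the 91 dose-map dosiomics features.
#'
#' @inheritParams dose_texture_features
#' @param region region name used in the emitted feature names.
#' @return named numeric vector of 213 values; all-`NA` for regions below
#'   `min_voxels` (moments and DVH included, since near-empty regions carry
#'   no stable dose summary).
#' @export
extract_all_dose_features <- function(dose, mask, n_bins = 50,
                                      min_voxels = 27, region = "region") {
  nm <- dose_feature_names(region)
  nvox <- sum(mask$voxels)
  if (nvox < min_voxels) {
    out <- rep(NA_real_, length(nm)); names(out) <- nm
    attr(out, "too_small") <- TRUE
    return(out)
  }
  moms <- tryCatch(unname(dose_moments(dose, mask)), error = function(e) {
    warning("dose moments undefined in region '", region, "': ",
            conditionMessage(e), call. = FALSE)
    rep(NA_real_, 63)
  })
  vals <- c(moms,
            unname(dvh_parameters(dose, mask)),
            unname(dose_texture_features(dose, mask, n_bins = n_bins,
                                         min_voxels = min_voxels)))
  names(vals) <- nm
  vals
}
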