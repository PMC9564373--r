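#' Partition the lung into incremental-dose-interval subregions (IDLSS)
#'
#' Intersects the whole-lung mask with contiguous dose bands to produce the
#' incremental-dose-interval lung subregions. With the default edges
#' `c(0, 10, 20, 30, 40, 50)` Gy this yields the five subregions
#' SR_0_10 ... SR_40_50. A lung voxel `v` is assigned to interval `i` iff
#' `edges[i] <= dose(v) < edges[i+1]` (half-open, so the bands are disjoint
#' and a dose of exactly 0 Gy falls in the first band). Lung voxels with dose
#' at or above the last edge are left unassigned and reported through
#' `excluded_fraction`, unless `extend_last = TRUE` extends the final band to
#' +Inf (prescriptions above the last edge do occur, e.g. 50-72 Gy plans).
#'
#' @param dose dose [image_grid] (Gy), aligned to `lung`'s grid.
#' @param lung binary whole-lung [image_grid].
#' @param edges strictly increasing dose band edges (Gy), length >= 2.
#' @param extend_last extend the last interval to +Inf instead of excluding
#'   hotter voxels.
#' @return an object of class `subregion_set`: list with `regions` (named
#'   list of binary masks, ascending dose order), `intervals` (data.frame of
#'   lo/hi/label), `whole_lung`, and `excluded_fraction`.
#' @examples
#' dose <- image_grid(array(15, c(6, 6, 6)))
#' lung <- image_grid(array(1, c(6, 6, 6)))
#' srs <- partition_lung(dose, lung)
#' sum(srs$regions$SR_10_20$voxels) # all lung voxels land in 10-20 Gy
#' @export
partition_lung <- function(dose, lung, edges = c(0, 10, 20, 30, 40, 50),
                           extend_last = FALSE) {
  assert_dose_grid(dose)
  assert_mask(lung)
  stop_if_misaligned(dose, lung, "dose and lung masks")
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("`edges` must be strictly increasing with length >= 2", call. = FALSE)

  n_int <- length(edges) - 1L
  hi_edges <- edges[-1]
  labels <- sprintf("SR_%s_%s", format_edge(edges[-length(edges)]),
                    format_edge(hi_edges))
  if (extend_last) {
    hi_edges[n_int] <- Inf
    labels[n_int] <- sprintf("SR_%s_Inf", format_edge(edges[n_int]))
  }

  lung_idx <- which(lung$voxels == 1)
  d <- dose$voxels[lung_idx]
  # bin i <=> edges[i] <= d < edges[i+1]; 0 = below first edge, n_int+1 = at/above last
  bin <- findInterval(d, edges, rightmost.closed = FALSE, left.open = FALSE)
  if (extend_last) bin[bin == n_int + 1L] <- n_int
  assigned <- bin >= 1L & bin <= n_int

  regions <- vector("list", n_int)
  names(regions) <- labels
  for (i in seq_len(n_int)) {
    m <- array(0, dim = dim(lung$voxels))
    m[lung_idx[bin == i]] <- 1
    regions[[i]] <- image_grid(m, lung$spacing, lung$origin)
  }
  excluded <- if (length(lung_idx)) mean(!assigned) else 0
  structure(list(
    regions = regions,
    intervals = data.frame(lo = edges[-length(edges)], hi = hi_edges,
                           label = labels, stringsAsFactors = FALSE),
    whole_lung = lung,
    excluded_fraction = excluded
  ), class = "subregion_set")
}

format_edge <- function(x) {
  out <- ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
                sub("\\.?0+$", "", sprintf("%.2f", x)))
  gsub("\\.", "p", out)
}

#' @export
print.subregion_set <- function(x, ...) {
  cat(sprintf("<subregion_set> %d subregions, excluded_fraction = %.4f\n",
              length(x$regions), x$excluded_fraction))
  s <- subregion_summary(x)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Per-subregion voxel counts and volumes
#'
#' @param srs a `subregion_set` from [partition_lung].
#' @param min_voxels minimum voxel count for reliable texture extraction;
#'   smaller regions are flagged (default 27, one 3x3x3 neighbourhood).
#' @return data.frame with region label, voxel count, volume (cc) and a
#'   `too_small` flag. The whole lung is included as the last row.
#' @export
subregion_summary <- function(srs, min_voxels = 27) {
  stopifnot(inherits(srs, "subregion_set"))
  vv <- voxel_volume_cc(srs$whole_lung)
  n <- vapply(srs$regions, function(m) sum(m$voxels), numeric(1))
  n <- c(n, WL = sum(srs$whole_lung$voxels))
  data.frame(region = names(n), n_voxels = as.integer(n),
             volume_cc = n * vv, too_small = n < min_voxels,
             stringsAsFactors = FALSE)
}
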