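# Gray-level texture-matrix families on a discretized region.
#
# All matrix constructions operate on the integer label array of a
# `discretized_region` (NA outside the mask), cropped to the mask bounding
# box. 3D connectivity uses the 13 unique voxel directions (26-neighbourhood
# up to sign); GLCM and GLRLM average feature values over the 13 directions.

offsets13 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) | (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, ])
})

crop_labels <- function(disc) {
  lab <- disc$labels
  present <- !is.na(lab)
  if (!any(present)) stop("discretized region is empty", call. = FALSE)
  d <- dim(lab)
  ax <- which(apply(present, 1, any))
  ay <- which(apply(present, 2, any))
  az <- which(apply(present, 3, any))
  lab[min(ax):max(ax), min(ay):max(ay), min(az):max(az), drop = FALSE]
}

# coordinate vectors of a full grid, flattened in array order
grid_coords <- function(d) {
  list(ix = rep(seq_len(d[1]), times = d[2] * d[3]),
       iy = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
       iz = rep(seq_len(d[3]), each = d[1] * d[2]))
}

# label pairs (a, b) for all voxel pairs separated by `off`, both in-mask;
# with indices = TRUE also returns the linear indices of each end.
label_pairs <- function(lab, off, indices = FALSE) {
  d <- dim(lab)
  rr <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(!lengths(rr))) return(NULL)
  a <- lab[rr[[1]], rr[[2]], rr[[3]], drop = FALSE]
  b <- lab[rr[[1]] + off[1], rr[[2]] + off[2], rr[[3]] + off[3], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  out <- list(a = a[keep], b = b[keep])
  if (indices) {
    lx <- length(rr[[1]]); ly <- length(rr[[2]]); lz <- length(rr[[3]])
    ix <- rep(rr[[1]], times = ly * lz)
    iy <- rep(rep(rr[[2]], each = lx), times = lz)
    iz <- rep(rr[[3]], each = lx * ly)
    lin_a <- ix + d[1] * (iy - 1L) + d[1] * d[2] * (iz - 1L)
    lin_b <- (ix + off[1]) + d[1] * (iy + off[2] - 1L) +
      d[1] * d[2] * (iz + off[3] - 1L)
    out$lin_a <- lin_a[keep]
    out$lin_b <- lin_b[keep]
  }
  out
}

all_pairs <- function(lab) {
  lapply(seq_len(nrow(offsets13)), function(r)
    label_pairs(lab, offsets13[r, ], indices = TRUE))
}

# ---- GLCM ------------------------------------------------------------------

glcm_matrix <- function(lab, ng, off) {
  pr <- label_pairs(lab, off)
  if (is.null(pr)) return(NULL)
  cnt <- tabulate(pr$a + ng * (pr$b - 1L), nbins = ng * ng)
  C <- matrix(cnt, ng, ng)
  C <- C + t(C)                      # symmetric co-occurrence
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

glcm_features_names <- function() c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Id", "Idm", "Idmn", "Idn", "InverseVariance",
  "MaximumProbability", "SumEntropy", "SumSquares"
)

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # difference and sum marginals
  k_diff <- abs(i - j)
  pxmy <- as.vector(rowsum(as.vector(p), as.vector(k_diff)))
  pxmy_k <- sort(unique(as.vector(k_diff)))
  k_sum <- i + j
  pxpy <- as.vector(rowsum(as.vector(p), as.vector(k_sum)))
  da <- sum(pxmy_k * pxmy)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  hxy <- ent(p)
  hx <- ent(px); hy <- ent(py)
  pp <- outer(px, py)
  hxy1 <- { m <- p > 0 & pp > 0; -sum(p[m] * log2(pp[m])) }
  hxy2 <- ent(pp)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  corr <- if (sdx * sdy > 0) (sum(i * j * p) - mux * muy) / (sdx * sdy) else 1
  off_diag <- i != j
  c(
    Autocorrelation = sum(i * j * p),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pxmy),
    DifferenceVariance = sum((pxmy_k - da)^2 * pxmy),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Id = sum(p / (1 + k_diff)),
    Idm = sum(p / (1 + k_diff^2)),
    Idmn = sum(p / (1 + k_diff^2 / ng^2)),
    Idn = sum(p / (1 + k_diff / ng)),
    InverseVariance = sum(p[off_diag] / k_diff[off_diag]^2),
    MaximumProbability = max(p),
    SumEntropy = ent(pxpy),
    SumSquares = sum((i - mux)^2 * p)
  )
}

glcm_features <- function(disc) {
  lab <- crop_labels(disc)
  glcm_features_lab(lab, disc$n_bins, all_pairs(lab))
}

glcm_features_lab <- function(lab, ng, pairs) {
  acc <- NULL; nd <- 0
  for (pr in pairs) {
    if (is.null(pr)) next
    cnt <- tabulate(pr$a + ng * (pr$b - 1L), nbins = ng * ng)
    C <- matrix(cnt, ng, ng)
    C <- C + t(C)
    if (sum(C) == 0) next
    f <- glcm_features_one(C / sum(C))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) {
    out <- rep(NA_real_, length(glcm_features_names()))
    names(out) <- glcm_features_names()
    return(out)
  }
  acc / nd
}

# ---- GLRLM -----------------------------------------------------------------

# run-length counts (gray level x run length) along one direction
glrlm_matrix <- function(lab, ng, off) {
  d <- dim(lab)
  lab0 <- lab
  lab0[is.na(lab0)] <- 0L
  co <- grid_coords(d)
  pred_out <- rep(FALSE, prod(d))
  for (a in 1:3) {
    if (off[a] == 0) next
    ca <- co[[a]] - off[a]
    pred_out <- pred_out | ca < 1L | ca > d[a]
  }
  sx <- co$ix[pred_out]; sy <- co$iy[pred_out]; sz <- co$iz[pred_out]
  start_lin <- sx + d[1] * (sy - 1L) + d[1] * d[2] * (sz - 1L)
  avail <- rep(.Machine$integer.max, length(sx))
  S <- list(sx, sy, sz)
  for (a in 1:3) {
    if (off[a] == 0) next
    avail <- pmin(avail, if (off[a] > 0) d[a] - S[[a]] + 1L else S[[a]])
  }
  Tmax <- max(avail)
  dlin <- off[1] + d[1] * off[2] + d[1] * d[2] * off[3]
  m <- length(start_lin)
  valmat <- matrix(0L, nrow = m, ncol = Tmax + 1L)  # sentinel column ends lines
  for (t in seq_len(Tmax)) {
    ok <- avail >= t
    valmat[ok, t] <- lab0[start_lin[ok] + (t - 1L) * dlin]
  }
  v <- as.vector(t(valmat))
  r <- rle(v)
  keep <- r$values > 0L
  gl <- r$values[keep]
  len <- r$lengths[keep]
  if (!length(gl)) return(NULL)
  lmax <- max(len)
  matrix(tabulate(gl + ng * (len - 1L), nbins = ng * lmax), ng, lmax)
}

glrlm_features_names <- function() c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)

# features shared by the run-length / size-zone / dependence constructions:
# P is a (gray level x size) count matrix, np the voxel count of the region.
size_matrix_features <- function(P, np, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  ns <- sum(P)
  p <- P / ns
  gl <- seq_len(nrow(P)); sz <- seq_len(ncol(P))
  pg <- rowSums(p); ps <- colSums(p)
  mug <- sum(gl * pg); mus <- sum(sz * ps)
  Gl <- matrix(gl, nrow(P), ncol(P))
  Sz <- matrix(sz, nrow(P), ncol(P), byrow = TRUE)
  ent <- { q <- p[p > 0]; -sum(q * log2(q)) }
  base <- c(
    sum(p / Sz^2), sum(p * Sz^2),
    sum(rowSums(P)^2) / ns, sum(rowSums(P)^2) / ns^2,
    sum(colSums(P)^2) / ns, sum(colSums(P)^2) / ns^2,
    ns / np,
    sum(pg * (gl - mug)^2), sum(ps * (sz - mus)^2), ent,
    sum(p / Gl^2), sum(p * Gl^2),
    sum(p / (Gl^2 * Sz^2)), sum(p * Gl^2 / Sz^2),
    sum(p * Sz^2 / Gl^2), sum(p * Gl^2 * Sz^2)
  )
  names(base) <- if (kind == "run") glrlm_features_names() else
    glszm_features_names()
  base
}

glrlm_features <- function(disc, lab = crop_labels(disc)) {
  ng <- disc$n_bins
  np <- sum(!is.na(lab))
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(offsets13))) {
    P <- glrlm_matrix(lab, ng, offsets13[r, ])
    if (is.null(P)) next
    f <- size_matrix_features(P, np, kind = "run")
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) {
    out <- rep(NA_real_, 16); names(out) <- glrlm_features_names()
    return(out)
  }
  acc / nd
}

# ---- GLSZM -----------------------------------------------------------------

glszm_features_names <- function() c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

# zones: 26-connected components of equal gray level
glszm_zones <- function(lab, ng, pairs = all_pairs(lab)) {
  in_mask <- which(!is.na(lab))
  n <- length(in_mask)
  rank_arr <- array(NA_integer_, dim = dim(lab))
  rank_arr[in_mask] <- seq_len(n)
  edges <- vector("list", length(pairs))
  for (r in seq_along(pairs)) {
    pr <- pairs[[r]]
    if (is.null(pr)) next
    eq <- pr$a == pr$b
    if (!any(eq)) next
    edges[[r]] <- rbind(rank_arr[pr$lin_a[eq]], rank_arr[pr$lin_b[eq]])
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(e) && length(e))
    g <- igraph::add_edges(g, as.vector(e))
  comp <- igraph::components(g)
  zone_level <- lab[in_mask][match(seq_len(comp$no), comp$membership)]
  list(level = zone_level, size = comp$csize)
}

glszm_matrix <- function(disc, lab = crop_labels(disc),
                         pairs = all_pairs(lab)) {
  z <- glszm_zones(lab, disc$n_bins, pairs)
  smax <- max(z$size)
  matrix(tabulate(z$level + disc$n_bins * (z$size - 1L),
                  nbins = disc$n_bins * smax), disc$n_bins, smax)
}

glszm_features <- function(disc, lab = crop_labels(disc),
                           pairs = all_pairs(lab)) {
  np <- sum(!is.na(lab))
  P <- glszm_matrix(disc, lab, pairs)
  size_matrix_features(P, np, kind = "zone")
}

# ---- GLDM ------------------------------------------------------------------

gldm_features_names <- function() c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"
)

# dependence count of an in-mask voxel: 1 (itself) + number of in-mask
# 26-neighbours with the same gray level (dependence threshold alpha = 0)
gldm_matrix <- function(disc, lab = crop_labels(disc),
                        pairs = all_pairs(lab)) {
  ng <- disc$n_bins
  dep <- array(0L, dim = dim(lab))
  for (r in seq_along(pairs)) {
    pr <- pairs[[r]]
    if (is.null(pr)) next
    eq <- which(pr$a == pr$b)
    if (!length(eq)) next
    ta <- tabulate(pr$lin_a[eq], nbins = length(dep))
    tb <- tabulate(pr$lin_b[eq], nbins = length(dep))
    dep <- dep + ta + tb
  }
  in_mask <- which(!is.na(lab))
  j <- dep[in_mask] + 1L
  i <- lab[in_mask]
  jmax <- max(j)
  matrix(tabulate(i + ng * (j - 1L), nbins = ng * jmax), ng, jmax)
}

gldm_features <- function(disc, lab = crop_labels(disc),
                          pairs = all_pairs(lab)) {
  P <- gldm_matrix(disc, lab, pairs)
  nz <- sum(P)
  p <- P / nz
  gl <- seq_len(nrow(P)); dp <- seq_len(ncol(P))
  pg <- rowSums(p); pd <- colSums(p)
  mug <- sum(gl * pg); mud <- sum(dp * pd)
  Gl <- matrix(gl, nrow(P), ncol(P))
  Dp <- matrix(dp, nrow(P), ncol(P), byrow = TRUE)
  q <- p[p > 0]
  out <- c(
    sum(p / Dp^2), sum(p * Dp^2),
    sum(rowSums(P)^2) / nz,
    sum(colSums(P)^2) / nz, sum(colSums(P)^2) / nz^2,
    sum(pg * (gl - mug)^2), sum(pd * (dp - mud)^2),
    -sum(q * log2(q)),
    sum(p / Gl^2), sum(p * Gl^2),
    sum(p / (Gl^2 * Dp^2)), sum(p * Gl^2 / Dp^2),
    sum(p * Dp^2 / Gl^2), sum(p * Gl^2 * Dp^2)
  )
  names(out) <- gldm_features_names()
  out
}

# ---- NGTDM -----------------------------------------------------------------

ngtdm_features_names <- function() c(
  "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"
)

ngtdm_table <- function(disc, lab = crop_labels(disc),
                        pairs = all_pairs(lab)) {
  ng <- disc$n_bins
  nsum <- array(0, dim = dim(lab))
  ncnt <- array(0L, dim = dim(lab))
  for (r in seq_along(pairs)) {
    pr <- pairs[[r]]
    if (is.null(pr)) next
    la <- pr$lin_a; lb <- pr$lin_b
    nsum[la] <- nsum[la] + pr$b
    nsum[lb] <- nsum[lb] + pr$a
    ncnt[la] <- ncnt[la] + 1L
    ncnt[lb] <- ncnt[lb] + 1L
  }
  in_mask <- which(!is.na(lab))
  valid <- in_mask[ncnt[in_mask] > 0]
  i <- lab[valid]
  abar <- nsum[valid] / ncnt[valid]
  s <- numeric(ng)
  if (length(i)) {
    agg <- rowsum(abs(i - abar), i)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  n_i <- tabulate(i, nbins = ng)
  list(s = s, n = n_i, nvp = length(valid), ng = ng)
}

ngtdm_features <- function(disc, lab = crop_labels(disc),
                           pairs = all_pairs(lab)) {
  tb <- ngtdm_table(disc, lab, pairs)
  p <- tb$n / tb$nvp
  s <- tb$s
  gl <- seq_len(tb$ng)
  act <- p > 0
  ngp <- sum(act)
  coarse <- { den <- sum(p * s); if (den > 0) 1 / den else 1e6 }
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(gl[act], gl[act], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s) / tb$nvp
  } else 0
  busy_den <- sum(abs(outer(gl[act] * p[act], gl[act] * p[act], `-`)))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  cplx <- if (tb$nvp > 0 && ngp > 0) {
    ia <- gl[act]; pa <- p[act]; sa <- s[act]
    M <- outer(ia, ia, function(a, b) abs(a - b)) *
      (outer(pa * sa, pa * sa, function(x, y) x + y) /
         outer(pa, pa, `+`))
    sum(M) / tb$nvp
  } else 0
  strength <- if (sum(s) > 0) {
    ia <- gl[act]; pa <- p[act]
    sum(outer(pa, pa, `+`) * outer(ia, ia, `-`)^2) / sum(s)
  } else 0
  out <- c(coarse, contrast, busyness, cplx, strength)
  names(out) <- ngtdm_features_names()
  out
}

# ---- combined 73-feature texture vector ------------------------------------

#' Texture features of a discretized region
#'
#' Computes the five matrix families on one discretized region: GLCM (22
#' features; symmetric, Chebyshev distance 1, feature values averaged over
#' the 13 unique 3D directions), GLRLM (16; 13 directions averaged), GLSZM
#' (16; zones are 26-connected equal-level components), GLDM (14; distance
#' 1, dependence threshold 0, dependence count includes the centre voxel)
#' and NGTDM (5; distance 1). Names are `family|feature`.
#'
#' @param disc a `discretized_region` from [discretize_fixed_bin_count].
#' @param min_voxels regions smaller than this return all-`NA`.
#' @return named numeric vector of 73 features.
#' @export
texture_features <- function(disc, min_voxels = 27) {
  stopifnot(inherits(disc, "discretized_region"))
  nm <- texture_feature_names()
  if (sum(!is.na(disc$labels)) < min_voxels) {
    out <- rep(NA_real_, length(nm)); names(out) <- nm
    attr(out, "too_small") <- TRUE
    return(out)
  }
  lab <- crop_labels(disc)
  pairs <- all_pairs(lab)
  out <- c(
    prefix_names(glcm_features_lab(lab, disc$n_bins, pairs), "glcm"),
    prefix_names(glrlm_features(disc, lab), "glrlm"),
    prefix_names(glszm_features(disc, lab, pairs), "glszm"),
    prefix_names(gldm_features(disc, lab, pairs), "gldm"),
    prefix_names(ngtdm_features(disc, lab, pairs), "ngtdm")
  )
  stopifnot(identical(names(out), nm))
  out
}

prefix_names <- function(x, family) {
  names(x) <- paste(family, names(x), sep = "|")
  x
}

texture_feature_names <- function() c(
  paste("glcm", glcm_features_names(), sep = "|"),
  paste("glrlm", glrlm_features_names(), sep = "|"),
  paste("glszm", glszm_features_names(), sep = "|"),
  paste("gldm", gldm_features_names(), sep = "|"),
  paste("ngtdm", ngtdm_features_names(), sep = "|")
)
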