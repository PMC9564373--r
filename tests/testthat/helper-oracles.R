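# Independent brute-force oracles: literal nested-loop implementations used
# to validate the vectorized engines on tiny regions.

# all 26 neighbour offsets and the 13 unique (up-to-sign) directions
oracle_offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})
oracle_offsets13 <- oracle_offsets26[
  oracle_offsets26[, 3] > 0 |
    (oracle_offsets26[, 3] == 0 & oracle_offsets26[, 2] > 0) |
    (oracle_offsets26[, 3] == 0 & oracle_offsets26[, 2] == 0 &
       oracle_offsets26[, 1] > 0), , drop = FALSE]

in_bounds <- function(i, j, k, d) {
  i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3]
}

# symmetric co-occurrence counts for one direction (counts both orders)
oracle_glcm <- function(lab, ng, off) {
  d <- dim(lab)
  C <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lab[i, j, k]
    if (is.na(a)) next
    for (s in c(1, -1)) {
      ii <- i + s * off[1]; jj <- j + s * off[2]; kk <- k + s * off[3]
      if (!in_bounds(ii, jj, kk, d)) next
      b <- lab[ii, jj, kk]
      if (is.na(b)) next
      C[a, b] <- C[a, b] + 1
    }
  }
  C
}

# run-length counts for one direction by literally walking every line
oracle_glrlm <- function(lab, ng, off) {
  d <- dim(lab)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    # line start: predecessor out of the grid
    if (in_bounds(i - off[1], j - off[2], k - off[3], d)) next
    pos <- c(i, j, k)
    current <- NA; len <- 0
    while (in_bounds(pos[1], pos[2], pos[3], d)) {
      v <- lab[pos[1], pos[2], pos[3]]
      if (!is.na(v) && !is.na(current) && v == current) {
        len <- len + 1
      } else {
        if (!is.na(current)) runs[[length(runs) + 1]] <- c(current, len)
        current <- v; len <- 1
      }
      pos <- pos + off
    }
    if (!is.na(current)) runs[[length(runs) + 1]] <- c(current, len)
  }
  if (!length(runs)) return(NULL)
  rl <- do.call(rbind, runs)
  P <- matrix(0, ng, max(rl[, 2]))
  for (r in seq_len(nrow(rl))) P[rl[r, 1], rl[r, 2]] <- P[rl[r, 1], rl[r, 2]] + 1
  P
}

# size-zone counts via breadth-first flood fill with 26-connectivity
oracle_glszm <- function(lab, ng) {
  d <- dim(lab)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (seen[i, j, k] || is.na(lab[i, j, k])) next
    level <- lab[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(oracle_offsets26))) {
        q <- p + oracle_offsets26[r, ]
        if (!in_bounds(q[1], q[2], q[3], d)) next
        if (seen[q[1], q[2], q[3]]) next
        v <- lab[q[1], q[2], q[3]]
        if (is.na(v) || v != level) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(level, size)
  }
  z <- do.call(rbind, zones)
  P <- matrix(0, ng, max(z[, 2]))
  for (r in seq_len(nrow(z))) P[z[r, 1], z[r, 2]] <- P[z[r, 1], z[r, 2]] + 1
  P
}

# dependence counts (centre voxel included) per voxel
oracle_gldm <- function(lab, ng) {
  d <- dim(lab)
  recs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lab[i, j, k]
    if (is.na(a)) next
    dep <- 1
    for (r in seq_len(nrow(oracle_offsets26))) {
      q <- c(i, j, k) + oracle_offsets26[r, ]
      if (!in_bounds(q[1], q[2], q[3], d)) next
      b <- lab[q[1], q[2], q[3]]
      if (!is.na(b) && b == a) dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(a, dep)
  }
  m <- do.call(rbind, recs)
  P <- matrix(0, ng, max(m[, 2]))
  for (r in seq_len(nrow(m))) P[m[r, 1], m[r, 2]] <- P[m[r, 1], m[r, 2]] + 1
  P
}

# NGTDM s_i / n_i by direct neighbourhood averaging
oracle_ngtdm <- function(lab, ng) {
  d <- dim(lab)
  s <- numeric(ng); n <- integer(ng); nvp <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lab[i, j, k]
    if (is.na(a)) next
    vals <- c()
    for (r in seq_len(nrow(oracle_offsets26))) {
      q <- c(i, j, k) + oracle_offsets26[r, ]
      if (!in_bounds(q[1], q[2], q[3], d)) next
      b <- lab[q[1], q[2], q[3]]
      if (!is.na(b)) vals <- c(vals, b)
    }
    if (!length(vals)) next
    nvp <- nvp + 1
    n[a] <- n[a] + 1L
    s[a] <- s[a] + abs(a - mean(vals))
  }
  list(s = s, n = n, nvp = nvp)
}

# central dose moment by plain triple loop over mask voxels
oracle_central_moment <- function(dose, mask, p, q, r) {
  d <- dim(mask$voxels)
  tot <- 0; cx <- 0; cy <- 0; cz <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask$voxels[i, j, k] != 1) next
    w <- dose$voxels[i, j, k]
    x <- (i - 1) * mask$spacing[1] + mask$origin[1]
    y <- (j - 1) * mask$spacing[2] + mask$origin[2]
    z <- (k - 1) * mask$spacing[3] + mask$origin[3]
    tot <- tot + w; cx <- cx + x * w; cy <- cy + y * w; cz <- cz + z * w
  }
  cx <- cx / tot; cy <- cy / tot; cz <- cz / tot
  mu <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask$voxels[i, j, k] != 1) next
    w <- dose$voxels[i, j, k]
    x <- (i - 1) * mask$spacing[1] + mask$origin[1]
    y <- (j - 1) * mask$spacing[2] + mask$origin[2]
    z <- (k - 1) * mask$spacing[3] + mask$origin[3]
    mu <- mu + (x - cx)^p * (y - cy)^q * (z - cz)^r * w
  }
  mu
}

# small random discretized region for oracle comparisons
random_disc <- function(dims, ng, seed, mask_frac = 0.85) {
  set.seed(seed)
  vox <- array(runif(prod(dims)), dim = dims)
  m <- array(as.numeric(runif(prod(dims)) < mask_frac), dim = dims)
  if (sum(m) < 2) m[seq_len(2)] <- 1
  img <- image_grid(vox, c(1, 1, 1))
  msk <- image_grid(m, c(1, 1, 1))
  discretize_fixed_bin_count(img, msk, ng)
}

# grid helpers
const_grid <- function(value, dims = c(5, 5, 5), spacing = c(1, 1, 1))
  image_grid(array(value, dims), spacing)
full_mask <- function(dims = c(5, 5, 5), spacing = c(1, 1, 1))
  image_grid(array(1, dims), spacing)

random_dose_region <- function(dims, seed, spacing = c(3, 3, 3)) {
  set.seed(seed)
  dose <- image_grid(array(runif(prod(dims), 0, 60), dims), spacing)
  mask <- image_grid(array(as.numeric(runif(prod(dims)) < 0.8), dims), spacing)
  if (sum(mask$voxels) < 2) mask$voxels[1:2] <- 1
  list(dose = dose, mask = mask)
}


gaussian_blob_region <- function(n, sigma_vox, spacing = 1) {
  half <- (n - 1) / 2
  co <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  # skewed two-lobe blob so that odd-order moments are non-trivial
  g <- exp(-((co$x - half)^2 + (co$y - half)^2 + (co$z - half)^2) /
             (2 * sigma_vox^2)) +
    0.5 * exp(-((co$x - half - sigma_vox)^2 + (co$y - half)^2 +
                  (co$z - half - 0.5 * sigma_vox)^2) / (2 * (0.7 * sigma_vox)^2))
  list(dose = image_grid(array(50 * g, c(n, n, n)), rep(spacing, 3)),
       mask = full_mask(c(n, n, n), rep(spacing, 3)))
}

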