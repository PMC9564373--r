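# The vectorized texture engines are validated against literal nested-loop
# enumeration oracles on tiny regions (helper-oracles.R).

toy_disc <- function() {
  # the 4x4x1 toy label grid with 2x2 blocks of levels 1..4
  lab <- matrix(c(1, 1, 2, 2,
                  1, 1, 2, 2,
                  3, 3, 4, 4,
                  3, 3, 4, 4), 4, 4, byrow = TRUE)
  img <- image_grid(array(lab, c(4, 4, 1)))
  discretize_fixed_bin_count(img, full_mask(c(4, 4, 1)), 4)
}

test_that("the toy block grid discretizes to its literal levels", {
  disc <- toy_disc()
  expected <- matrix(c(1, 1, 2, 2,
                       1, 1, 2, 2,
                       3, 3, 4, 4,
                       3, 3, 4, 4), 4, 4, byrow = TRUE)
  expect_equal(disc$labels[, , 1], matrix(as.integer(expected), 4, 4))
})

test_that("GLCM matrices equal exhaustive pair enumeration", {
  cases <- list(toy_disc(), random_disc(c(4, 4, 4), 4, seed = 1),
                random_disc(c(5, 5, 5), 3, seed = 2),
                random_disc(c(5, 3, 4), 6, seed = 3))
  for (disc in cases) {
    lab <- idlss:::crop_labels(disc)
    for (r in seq_len(nrow(oracle_offsets13))) {
      off <- oracle_offsets13[r, ]
      got <- idlss:::glcm_matrix(lab, disc$n_bins, off)
      ref <- oracle_glcm(lab, disc$n_bins, off)
      if (is.null(got)) got <- matrix(0, disc$n_bins, disc$n_bins)
      expect_equal(got * sum(ref), ref, info = paste(off, collapse = ","))
    }
  }
})

test_that("GLRLM matrices equal literal line walking", {
  cases <- list(toy_disc(), random_disc(c(4, 4, 4), 3, seed = 4),
                random_disc(c(5, 5, 5), 2, seed = 5))
  for (disc in cases) {
    lab <- idlss:::crop_labels(disc)
    for (r in seq_len(nrow(oracle_offsets13))) {
      off <- oracle_offsets13[r, ]
      got <- idlss:::glrlm_matrix(lab, disc$n_bins, off)
      ref <- oracle_glrlm(lab, disc$n_bins, off)
      expect_equal(dim(got), dim(ref))
      expect_equal(got, ref, info = paste(off, collapse = ","))
    }
  }
})

test_that("GLSZM matrices equal flood-fill zone enumeration", {
  cases <- list(toy_disc(), random_disc(c(4, 4, 4), 3, seed = 6),
                random_disc(c(5, 5, 5), 2, seed = 7),
                random_disc(c(3, 5, 5), 4, seed = 8))
  for (disc in cases) {
    got <- idlss:::glszm_matrix(disc)
    ref <- oracle_glszm(idlss:::crop_labels(disc), disc$n_bins)
    expect_equal(got, ref)
  }
})

test_that("GLDM matrices equal per-voxel dependence counting", {
  cases <- list(toy_disc(), random_disc(c(4, 4, 4), 3, seed = 9),
                random_disc(c(5, 5, 5), 2, seed = 10))
  for (disc in cases) {
    got <- idlss:::gldm_matrix(disc)
    ref <- oracle_gldm(idlss:::crop_labels(disc), disc$n_bins)
    expect_equal(got, ref)
  }
})

test_that("NGTDM tables equal direct neighbourhood averaging", {
  cases <- list(toy_disc(), random_disc(c(4, 4, 4), 4, seed = 11),
                random_disc(c(5, 5, 5), 3, seed = 12))
  for (disc in cases) {
    got <- idlss:::ngtdm_table(disc)
    ref <- oracle_ngtdm(idlss:::crop_labels(disc), disc$n_bins)
    expect_equal(got$s, ref$s, tolerance = 1e-12)
    expect_equal(got$n, ref$n)
    expect_equal(got$nvp, ref$nvp)
  }
})

test_that("a constant region degenerates as expected", {
  img <- const_grid(5, c(4, 4, 4))
  disc <- discretize_fixed_bin_count(img, full_mask(c(4, 4, 4)), 10)
  f <- texture_features(disc)
  expect_equal(unname(f["glcm|JointEntropy"]), 0)
  expect_equal(unname(f["glcm|JointEnergy"]), 1)
  expect_equal(unname(f["glcm|MaximumProbability"]), 1)
  # one run of length 4 per line: long-run emphasis from direct enumeration
  lab <- idlss:::crop_labels(disc)
  P <- oracle_glrlm(lab, disc$n_bins, c(1, 0, 0))
  lre_oracle <- sum(P * (col(P))^2) / sum(P)
  got <- idlss:::size_matrix_features(
    idlss:::glrlm_matrix(lab, disc$n_bins, c(1L, 0L, 0L)), 64, "run")
  expect_equal(unname(got["LongRunEmphasis"]), lre_oracle)
  # a single zone of size 64
  expect_equal(unname(f["glszm|ZonePercentage"]), 1 / 64)
})

test_that("GLCM rows of a normalized matrix sum to 1 overall", {
  disc <- random_disc(c(8, 8, 8), 4, seed = 13)
  lab <- idlss:::crop_labels(disc)
  p <- idlss:::glcm_matrix(lab, 4, c(1, 0, 0))
  expect_equal(sum(p), 1)
  expect_equal(p, t(p))  # symmetric
})

test_that("texture features count 73 and keep a deterministic order", {
  disc <- random_disc(c(5, 5, 5), 5, seed = 14)
  f1 <- texture_features(disc)
  f2 <- texture_features(disc)
  expect_length(f1, 73)
  expect_identical(f1, f2)
  expect_identical(names(f1), idlss:::texture_feature_names())
})

test_that("direction-averaged features are invariant to axis flips", {
  disc <- random_disc(c(5, 4, 5), 4, seed = 15)
  f0 <- texture_features(disc)
  for (axis in 1:3) {
    lab <- disc$labels
    idx <- lapply(dim(lab), seq_len)
    idx[[axis]] <- rev(idx[[axis]])
    flipped <- disc
    flipped$labels <- lab[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    ff <- texture_features(flipped)
    keep <- grepl("^(glcm|glrlm)\\|", names(f0))
    expect_equal(ff[keep], f0[keep], tolerance = 1e-12, info = axis)
  }
})

test_that("intensity shifts leave discretized texture features unchanged", {
  set.seed(16)
  img <- image_grid(array(rnorm(125), c(5, 5, 5)))
  msk <- full_mask(c(5, 5, 5))
  f0 <- texture_features(discretize_fixed_bin_count(img, msk, 8))
  img2 <- image_grid(img$voxels + 100, img$spacing, img$origin)
  f1 <- texture_features(discretize_fixed_bin_count(img2, msk, 8))
  expect_equal(f1, f0, tolerance = 1e-12)
})

test_that("too-small regions give missing texture values", {
  img <- const_grid(1, c(3, 3, 3))
  m <- image_grid(array(c(rep(1, 5), rep(0, 22)), c(3, 3, 3)))
  disc <- discretize_fixed_bin_count(img, m, 4)
  f <- texture_features(disc)
  expect_true(all(is.na(f)))
  expect_length(f, 73)
})
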