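test_that("central moments obey the defining identities", {
  rg <- random_dose_region(c(6, 6, 6), seed = 1)
  # order-1 central moments vanish by the centroid definition
  expect_equal(central_moment(rg$dose, rg$mask, 1, 0, 0), 0, tolerance = 1e-8)
  expect_equal(central_moment(rg$dose, rg$mask, 0, 1, 0), 0, tolerance = 1e-8)
  expect_equal(central_moment(rg$dose, rg$mask, 0, 0, 1), 0, tolerance = 1e-8)
  # mu_000 is the total dose
  expect_equal(central_moment(rg$dose, rg$mask, 0, 0, 0),
               sum(rg$dose$voxels[rg$mask$voxels == 1]))
})

test_that("a mirror-symmetric dose field has zero odd-order moments", {
  d <- c(7, 5, 5)
  co <- expand.grid(x = 0:6, y = 0:4, z = 0:4)
  dose <- image_grid(array(10 + (co$x - 3)^2, d))  # even in x about centre
  mask <- full_mask(d)
  for (p in c(1, 3))
    expect_equal(central_moment(dose, mask, p, 0, 0), 0, tolerance = 1e-7)
})

test_that("eta_000 is identically 1 and moments match brute force", {
  rg <- random_dose_region(c(6, 6, 6), seed = 2)
  expect_equal(scale_invariant_moment(rg$dose, rg$mask, 0, 0, 0), 1)
  dm <- dose_moments(rg$dose, rg$mask)
  expect_length(dm, 63)
  expect_false("eta_0_0_0" %in% names(dm))
  mu0 <- oracle_central_moment(rg$dose, rg$mask, 0, 0, 0)
  for (trip in list(c(2, 0, 0), c(1, 1, 1), c(3, 2, 1), c(0, 0, 3),
                    c(3, 3, 3), c(2, 1, 0))) {
    mu <- oracle_central_moment(rg$dose, rg$mask, trip[1], trip[2], trip[3])
    eta <- mu / mu0^(sum(trip) / 3 + 1)
    expect_equal(unname(dm[sprintf("eta_%d_%d_%d", trip[1], trip[2], trip[3])]),
                 eta, tolerance = 1e-10)
  }
})

test_that("order-1 eta moments vanish for every input", {
  for (seed in 1:3) {
    rg <- random_dose_region(c(5, 5, 5), seed = seed)
    dm <- dose_moments(rg$dose, rg$mask)
    expect_equal(unname(dm[c("eta_1_0_0", "eta_0_1_0", "eta_0_0_1")]),
                 c(0, 0, 0), tolerance = 1e-8)
  }
})

test_that("eta is exactly homogeneous in dose amplitude", {
  rg <- random_dose_region(c(6, 6, 6), seed = 3)
  dm1 <- dose_moments(rg$dose, rg$mask)
  dose2 <- image_grid(2 * rg$dose$voxels, rg$dose$spacing, rg$dose$origin)
  dm2 <- dose_moments(dose2, rg$mask)
  for (nm in names(dm1)) {
    s <- sum(as.integer(strsplit(sub("eta_", "", nm), "_")[[1]]))
    expect_equal(unname(dm2[nm]), unname(dm1[nm]) * 2^(-s / 3),
                 tolerance = 1e-9, info = nm)
  }
})

test_that("eta is exactly invariant to rigid translation", {
  rg <- random_dose_region(c(6, 6, 6), seed = 4)
  dm1 <- dose_moments(rg$dose, rg$mask)
  dose2 <- image_grid(rg$dose$voxels, rg$dose$spacing, origin = c(50, -20, 8))
  mask2 <- image_grid(rg$mask$voxels, rg$mask$spacing, origin = c(50, -20, 8))
  dm2 <- dose_moments(dose2, mask2)
  expect_equal(dm2, dm1, tolerance = 1e-9)
})

test_that("eta is invariant to isotropic object scaling within 3%", {
  small <- gaussian_blob_region(25, sigma_vox = 3.5)
  big <- gaussian_blob_region(49, sigma_vox = 7)  # same object, twice the size
  dm_s <- dose_moments(small$dose, small$mask)
  dm_b <- dose_moments(big$dose, big$mask)
  ref <- max(abs(dm_s))
  for (nm in names(dm_s)) {
    if (abs(dm_s[nm]) < 0.02 * ref) {
      expect_lt(abs(dm_b[nm] - dm_s[nm]), 0.03 * ref)
    } else {
      expect_lt(abs(dm_b[nm] - dm_s[nm]) / abs(dm_s[nm]), 0.03)
    }
  }
})

test_that("zero-dose or empty regions are undefined for moments", {
  zero <- const_grid(0, c(4, 4, 4))
  expect_error(dose_moments(zero, full_mask(c(4, 4, 4))), "zero")
  dose <- const_grid(1, c(4, 4, 4))
  empty <- image_grid(array(0, c(4, 4, 4)))
  expect_error(dose_moments(dose, empty), "empty")
})

test_that("the DVH of a uniform region is a step function", {
  dose <- const_grid(10, c(4, 4, 4))
  curve <- cumulative_dvh(dose, full_mask(c(4, 4, 4)))
  expect_equal(curve$rel_volume_pct[curve$dose_gy < 10], rep(100, sum(curve$dose_gy < 10)))
  expect_equal(curve$rel_volume_pct[curve$dose_gy >= 10], rep(0, sum(curve$dose_gy >= 10)))
})

test_that("a two-valued region gives the two-step DVH and parameters", {
  dose <- image_grid(array(rep(c(10, 20), each = 32), c(4, 4, 4)))
  mask <- full_mask(c(4, 4, 4))
  curve <- cumulative_dvh(dose, mask)
  mid <- curve$dose_gy >= 10 & curve$dose_gy < 20
  expect_equal(curve$rel_volume_pct[mid], rep(50, sum(mid)))
  pars <- dvh_parameters(dose, mask)
  expect_equal(unname(pars["V15_rel"]), 50)
  expect_equal(unname(pars["D99"]), 10, tolerance = 0.2)
  expect_equal(unname(pars["MeanDose"]), 15)
})

test_that("DVH curves match direct counting and are monotone", {
  rg <- random_dose_region(c(6, 6, 6), seed = 5)
  curve <- cumulative_dvh(rg$dose, rg$mask, resolution = 0.1)
  d <- rg$dose$voxels[rg$mask$voxels == 1]
  direct <- vapply(curve$dose_gy, function(lv) 100 * mean(d > lv), numeric(1))
  expect_equal(curve$rel_volume_pct, direct, tolerance = 1e-9)
  expect_true(all(diff(curve$rel_volume_pct) <= 1e-12))
  expect_true(all(curve$rel_volume_pct >= 0 & curve$rel_volume_pct <= 100))
  expect_equal(curve$rel_volume_pct[1], 100)  # every dose is > 0? only if min>0
})

test_that("DVH parameters of a uniform field collapse to the dose value", {
  dose <- const_grid(10, c(4, 4, 4))
  pars <- dvh_parameters(dose, full_mask(c(4, 4, 4)))
  expect_equal(unname(pars["V5_rel"]), 100)
  expect_equal(unname(pars["V80_rel"]), 0)
  expect_equal(unname(pars["D50"]), 10)
  expect_equal(unname(pars[c("MeanDose", "MinDose", "MaxDose")]),
               c(10, 10, 10))
})

test_that("the DVH parameter set has the frozen 59 names and orderings", {
  rg <- random_dose_region(c(5, 5, 5), seed = 6)
  pars <- dvh_parameters(rg$dose, rg$mask)
  expect_length(pars, 59)
  expect_identical(names(pars), idlss:::dvh_parameter_names())
  vx <- pars[sprintf("V%d_rel", seq(5, 80, 5))]
  expect_true(all(diff(vx) <= 1e-12))            # V_x non-increasing in x
  dx <- pars[sprintf("D%d", c(1, 2, 5, seq(10, 95, 5), 98, 99))]
  expect_true(all(diff(dx) <= 1e-12))            # D_x non-increasing in x
  expect_true(pars["MinDose"] <= pars["MeanDose"] &&
                pars["MeanDose"] <= pars["MaxDose"])
  # D_x equals the direct percentile of voxel doses
  d <- rg$dose$voxels[rg$mask$voxels == 1]
  expect_equal(unname(pars["D30"]), unname(quantile(d, 0.7, type = 7)))
})

test_that("dose-map dosiomics has 91 values consistent with the engine", {
  rg <- random_dose_region(c(8, 8, 8), seed = 7)
  f <- dose_texture_features(rg$dose, rg$mask, n_bins = 50)
  expect_length(f, 91)
  fo <- first_order_features(rg$dose, rg$mask, ref_bins = 50)
  expect_equal(unname(f[paste0("firstorder|", names(fo))]), unname(fo))
  tx <- texture_features(discretize_fixed_bin_count(rg$dose, rg$mask, 50))
  expect_equal(unname(f[names(tx)]), unname(tx))
})

test_that("a uniform dose region degenerates the dosiomics", {
  dose <- const_grid(25, c(4, 4, 4))
  f <- dose_texture_features(dose, full_mask(c(4, 4, 4)))
  expect_equal(unname(f["firstorder|Variance"]), 0)
  expect_equal(unname(f["glcm|JointEntropy"]), 0)
})

test_that("the full dose feature vector has 213 entries and is deterministic", {
  rg <- random_dose_region(c(6, 6, 6), seed = 8)
  f1 <- extract_all_dose_features(rg$dose, rg$mask, region = "SR_0_10")
  f2 <- extract_all_dose_features(rg$dose, rg$mask, region = "SR_0_10")
  expect_length(f1, 213)
  expect_identical(f1, f2)
  expect_true(all(startsWith(names(f1), "SR_0_10|dose|")))
  expect_equal(sum(grepl("\\|moments\\|", names(f1))), 63)
  expect_equal(sum(grepl("\\|dvh\\|", names(f1))), 59)
  expect_equal(sum(grepl("\\|firstorder\\|", names(f1))) +
                 sum(grepl("\\|b50\\|", names(f1))), 91)
})

test_that("six regions give 1278 uniquely named dose features", {
  regions <- c("WL", "SR_0_10", "SR_10_20", "SR_20_30", "SR_30_40", "SR_40_50")
  nm <- unlist(lapply(regions, idlss:::dose_feature_names))
  expect_length(nm, 1278)
  expect_false(anyDuplicated(nm) > 0)
})

test_that("tiny regions yield missing dose features", {
  dose <- const_grid(10, c(3, 3, 3))
  tiny <- image_grid(array(c(1, 1, 1, rep(0, 24)), c(3, 3, 3)))
  f <- extract_all_dose_features(dose, tiny)
  expect_true(all(is.na(f)))
  expect_length(f, 213)
})
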