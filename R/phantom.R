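# Synthetic CT / dose / lung phantom and cohort generator.
#
# The phantom emulates the study conditions of a thoracic IMRT plan at
# desk scale: a two-lobed lung mask inside a body-sized grid at 3 mm
# isotropic spacing, a dose distribution with a high-dose focus at the
# tumour and a smooth Gaussian falloff so that all five 0-50 Gy bands are
# populated inside the lung, CT texture with controllable heterogeneity,
# and (at cohort level) outcome labels drawn from a stated logistic model
# on planted per-patient characteristics.

#' Phantom specification
#'
#' @param grid_shape voxels per axis.
#' @param spacing_mm isotropic voxel spacing.
#' @param lung_centers_mm list of two ellipsoid centres (mm).
#' @param lung_semiaxes_mm list of two ellipsoid semi-axis triples (mm).
#' @param tumor_center_mm tumour centre (mm), inside a lung lobe.
#' @param tumor_radius_mm tumour radius.
#' @param prescription_gy prescription dose at the tumour; kept above 50 Gy
#'   so that every incremental band up to 50 Gy is populated.
#' @param falloff_mm Gaussian dose falloff scale outside the tumour.
#' @param dose_noise_gy amplitude (SD, Gy) of the correlated dose
#'   heterogeneity added in the low-dose lung (tapered to zero above
#'   `dose_noise_below_gy`, mirroring the homogeneous high-dose bath of
#'   conformal plans).
#' @param dose_corr_mm correlation length of the dose heterogeneity field;
#'   the spatial scale of the low-dose texture, resolvable by fine-binned
#'   subregion dose textures but washed out in whole-lung summaries.
#' @param dose_noise_window_gy the heterogeneity texture has full amplitude
#'   at and below `w[1]` Gy and ramps linearly to zero at `w[2]` Gy,
#'   emulating plans whose low-dose spill pattern varies between patients
#'   while the conformal high-dose bath does not.
#' @param ct_base_hu mean lung CT number.
#' @param ct_noise_hu SD of the correlated CT texture inside the lung.
#' @param ct_corr_mm correlation length of the CT texture.
#' @param seed RNG seed; same seed, bit-identical phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 40), spacing_mm = 3,
                         lung_centers_mm = list(c(36, 60, 60), c(84, 60, 60)),
                         lung_semiaxes_mm = list(c(21, 27, 39), c(21, 27, 39)),
                         tumor_center_mm = c(84, 60, 66),
                         tumor_radius_mm = 9,
                         prescription_gy = 60,
                         falloff_mm = 15,
                         dose_noise_gy = 0.4,
                         dose_corr_mm = 6,
                         dose_noise_window_gy = c(0, 20),
                         ct_base_hu = -800,
                         ct_noise_hu = 60,
                         ct_corr_mm = 6,
                         seed = 0) {
  if (prescription_gy <= 50)
    stop("prescription must exceed 50 Gy so all five bands are populated",
         call. = FALSE)
  stopifnot(length(grid_shape) == 3, spacing_mm > 0, tumor_radius_mm > 0,
            falloff_mm > 0)
  extent <- (grid_shape - 1) * spacing_mm
  if (any(tumor_center_mm < 0 | tumor_center_mm > extent))
    stop("tumour centre lies outside the grid", call. = FALSE)
  structure(as.list(environment())[names(formals(phantom_spec))],
            class = "phantom_spec")
}

# correlated Gaussian field with unit variance, via separable smoothing of
# white noise and empirical renormalization
correlated_field <- function(shape, spacing, corr_mm) {
  z <- array(stats::rnorm(prod(shape)), dim = shape)
  for (a in 1:3) {
    kern <- gaussian_kernel_1d(max(corr_mm / spacing, 0.3))
    z <- conv_axis(z, kern, a, boundary = "wrap")
  }
  z / stats::sd(z)
}

#' Generate one CT / dose / lung phantom
#'
#' @param spec a [phantom_spec].
#' @return list with `ct`, `dose`, `lung` ([image_grid]s) and the
#'   generating `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed, {
    d <- spec$grid_shape
    sp <- rep(spec$spacing_mm, 3)
    co <- grid_coords(d)
    X <- (co$ix - 1) * sp[1]
    Y <- (co$iy - 1) * sp[2]
    Z <- (co$iz - 1) * sp[3]
    inside <- rep(FALSE, prod(d))
    for (l in 1:2) {
      c0 <- spec$lung_centers_mm[[l]]
      ax <- spec$lung_semiaxes_mm[[l]]
      inside <- inside | (((X - c0[1]) / ax[1])^2 + ((Y - c0[2]) / ax[2])^2 +
                            ((Z - c0[3]) / ax[3])^2 <= 1)
    }
    lung <- image_grid(array(as.numeric(inside), dim = d), sp, c(0, 0, 0))

    tc <- spec$tumor_center_mm
    dist <- sqrt((X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2)
    excess <- pmax(dist - spec$tumor_radius_mm, 0)
    dose_v <- spec$prescription_gy * exp(-excess^2 / (2 * spec$falloff_mm^2))
    dose_v <- array(dose_v, dim = d)
    if (spec$dose_noise_gy > 0) {
      het <- correlated_field(d, spec$spacing_mm, spec$dose_corr_mm)
      w <- spec$dose_noise_window_gy
      taper <- pmin(pmax((w[2] - dose_v) / (w[2] - w[1]), 0), 1)
      dose_v <- dose_v + spec$dose_noise_gy * het * taper
    }
    dose_v[dose_v < 0] <- 0
    dose <- image_grid(dose_v, sp, c(0, 0, 0))

    tex <- correlated_field(d, spec$spacing_mm, spec$ct_corr_mm)
    ct_v <- array(40, dim = d)  # soft tissue background
    ct_v[inside] <- spec$ct_base_hu + spec$ct_noise_hu * tex[inside]
    tumor <- dist <= spec$tumor_radius_mm
    ct_v[array(tumor, dim = d)] <- 20
    ct <- image_grid(ct_v, sp, c(0, 0, 0))

    list(ct = ct, dose = dose, lung = lung, spec = spec)
  })
}

#' Cohort specification
#'
#' @param n number of patients (>= 20).
#' @param event_fraction target outcome prevalence (near-balanced cohorts:
#'   default 0.5).
#' @param beta named logistic coefficients on the standardized planted
#'   truths (`dose_heterogeneity` = correlation length of the low-dose dose
#'   texture, `ct_texture` = CT noise SD); the default plants the outcome
#'   signal in the spatial heterogeneity pattern of the low-dose lung,
#'   which fine-binned subregion dose textures resolve while whole-lung
#'   summaries (marginal dose distribution unchanged) do not.
#' @param label_noise_sd SD of extra Gaussian noise on the linear predictor.
#' @param seed cohort-level RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 126, event_fraction = 0.5,
                        beta = c(dose_heterogeneity = 2.5, ct_texture = 0.5),
                        label_noise_sd = 0.25, seed = 0) {
  if (n < 20) stop("cohort needs n >= 20", call. = FALSE)
  if (event_fraction <= 0 || event_fraction >= 1)
    stop("event fraction must be in (0, 1)", call. = FALSE)
  structure(as.list(environment())[names(formals(cohort_spec))],
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted outcome signal
#'
#' Per patient, phantom parameters are jittered (tumour position and size,
#' falloff scale, low-dose dose-heterogeneity amplitude, CT texture SD) and
#' the outcome is drawn from a logistic model on the standardized planted
#' truths, with the intercept solved so the expected event rate matches the
#' specification. The generating parameters are recorded for recovery tests.
#'
#' @param cspec a [cohort_spec].
#' @param pspec a [phantom_spec] serving as the template patient.
#' @param volumes generate the per-patient volumes (set `FALSE` to get only
#'   the planted truths and labels, e.g. for calibration checks at large n).
#' @return object of class `synthetic_cohort`: `patients` (list of
#'   ct/dose/lung), `labels`, `truths` (data.frame of planted parameters),
#'   `ids`.
#' @export
make_cohort <- function(cspec = cohort_spec(), pspec = phantom_spec(),
                        volumes = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(pspec, "phantom_spec"))
  n <- cspec$n
  pars <- local_seed(cspec$seed, {
    data.frame(
      dose_heterogeneity = stats::rlnorm(n, log(pspec$dose_corr_mm), 0.5),
      ct_texture = stats::rlnorm(n, log(pspec$ct_noise_hu), 0.3),
      falloff = pmax(stats::rnorm(n, pspec$falloff_mm, 3), 10),
      tumor_dx = stats::rnorm(n, 0, 4),
      tumor_dy = stats::rnorm(n, 0, 4),
      tumor_dz = stats::rnorm(n, 0, 4),
      tumor_radius = pmax(stats::rnorm(n, pspec$tumor_radius_mm, 1.5), 4)
    )
  })
  z <- scale(log(pars[, names(cspec$beta), drop = FALSE]))
  eta <- as.numeric(z %*% cspec$beta)
  eta <- eta + local_seed(cspec$seed + 10000L,
                          stats::rnorm(n, 0, cspec$label_noise_sd))
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                         cspec$event_fraction, c(-30, 30))$root
  labels <- local_seed(cspec$seed + 20000L,
                       stats::rbinom(n, 1, stats::plogis(b0 + eta)))
  patients <- vector("list", n)
  if (volumes) for (i in seq_len(n)) {
    sp_i <- pspec
    sp_i$dose_corr_mm <- pars$dose_heterogeneity[i]
    sp_i$ct_noise_hu <- pars$ct_texture[i]
    sp_i$falloff_mm <- pars$falloff[i]
    tc <- pspec$tumor_center_mm +
      c(pars$tumor_dx[i], pars$tumor_dy[i], pars$tumor_dz[i])
    extent <- (pspec$grid_shape - 1) * pspec$spacing_mm
    sp_i$tumor_center_mm <- pmin(pmax(tc, 0), extent)
    sp_i$tumor_radius_mm <- pars$tumor_radius[i]
    sp_i$seed <- cspec$seed * 100000L + i
    patients[[i]] <- make_phantom(sp_i)
  }
  structure(list(patients = patients, labels = labels, truths = pars,
                 ids = sprintf("P%03d", seq_len(n)),
                 cspec = cspec, pspec = pspec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d events (%.1f%%), grid %s\n",
              length(x$patients), sum(x$labels), 100 * mean(x$labels),
              paste(x$pspec$grid_shape, collapse = "x")))
  invisible(x)
}

#' Extract per-region feature tables for a whole cohort
#'
#' Runs the IDLSS partition on each patient and extracts the requested
#' feature blocks (dose features and/or radiomics) for the whole lung and
#' each subregion, assembling the patients x features matrix with canonical
#' region-prefixed names (`WL`, `SR_0_10`, ...).
#'
#' @param cohort a `synthetic_cohort`, or a list with elements `patients`
#'   (each a list with `ct`, `dose`, `lung`), `labels`, `ids`.
#' @param what `"dose"`, `"radiomics"` or both.
#' @param edges IDLSS dose band edges (Gy).
#' @param config [radiomics_config] for the radiomics block.
#' @param dose_bins dose-map discretization bin count.
#' @param min_voxels minimum region size; smaller subregions give missing
#'   values for that patient.
#' @return a [feature_table].
#' @export
extract_cohort_features <- function(cohort, what = c("dose"),
                                    edges = c(0, 10, 20, 30, 40, 50),
                                    config = radiomics_config(),
                                    dose_bins = 50, min_voxels = 27) {
  stopifnot(all(what %in% c("dose", "radiomics")))
  n <- length(cohort$patients)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    srs <- partition_lung(p$dose, p$lung, edges = edges)
    regions <- c(list(WL = srs$whole_lung), srs$regions)
    vals <- numeric(0)
    for (rg in names(regions)) {
      if ("radiomics" %in% what)
        vals <- c(vals, extract_all_radiomics(p$ct, regions[[rg]],
                                              config = config, region = rg))
      if ("dose" %in% what)
        vals <- c(vals, extract_all_dose_features(p$dose, regions[[rg]],
                                                  n_bins = dose_bins,
                                                  min_voxels = min_voxels,
                                                  region = rg))
    }
    rows[[i]] <- vals
  }
  x <- do.call(rbind, rows)
  feature_table(x, cohort$labels, cohort$ids)
}

#' Columns of a canonical feature group
#'
#' Maps the six group names to column subsets of a cohort feature table:
#' `WL-*` groups use whole-lung columns only, `SR-*` groups use the five
#' subregion blocks only (whole lung excluded); `RF` is the CT radiomics
#' block, `DF` the dose block, `RDF` both.
#'
#' @param feature_names character vector of canonical feature names.
#' @param group one of `"WL-RF"`, `"WL-DF"`, `"WL-RDF"`, `"SR-RF"`,
#'   `"SR-DF"`, `"SR-RDF"`.
#' @return character vector of matching names.
#' @export
feature_group_columns <- function(feature_names, group) {
  parts <- strsplit(feature_names, "|", fixed = TRUE)
  region <- vapply(parts, `[`, character(1), 1)
  modality <- vapply(parts, `[`, character(1), 2)
  spec <- strsplit(group, "-", fixed = TRUE)[[1]]
  if (length(spec) != 2 || !spec[1] %in% c("WL", "SR") ||
      !spec[2] %in% c("RF", "DF", "RDF"))
    stop("unknown feature group: ", group, call. = FALSE)
  reg_ok <- if (spec[1] == "WL") region == "WL" else startsWith(region, "SR_")
  mod_ok <- switch(spec[2], RF = modality == "CT", DF = modality == "dose",
                   RDF = modality %in% c("CT", "dose"))
  feature_names[reg_ok & mod_ok]
}
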