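#' Radiomics extraction configuration
#'
#' Freezes the feature-extraction protocol: which filtered image types are
#' used (original, Laplacian-of-Gaussian at the given sigmas in mm, and the
#' 8 subbands of the single-level undecimated coiflet-1 wavelet transform),
#' which fixed bin counts discretize each image type for texture computation,
#' and the reference bin count used by the first-order entropy/uniformity
#' histogram. Under the defaults the per-region feature count decomposes as
#' 14 shape (original image only) + 18 first-order x 12 image types +
#' 73 texture x 12 image types x 5 bin counts = 4610.
#'
#' @param log_sigmas LoG sigmas in mm (default 1, 3, 6; `NULL` disables).
#' @param wavelet include the 8 coif1 subbands as image types.
#' @param bin_counts fixed bin counts for texture discretization.
#' @param first_order_bins reference bin count for the first-order
#'   entropy/uniformity histogram.
#' @param min_voxels regions below this size give all-missing features.
#' @param families character subset of `c("shape", "firstorder", "texture")`.
#' @return object of class `radiomics_config`.
#' @export
radiomics_config <- function(log_sigmas = c(1, 3, 6), wavelet = TRUE,
                             bin_counts = c(20, 50, 100, 150, 200),
                             first_order_bins = 50, min_voxels = 27,
                             families = c("shape", "firstorder", "texture")) {
  stopifnot(all(families %in% c("shape", "firstorder", "texture")))
  if (length(log_sigmas) && any(log_sigmas <= 0))
    stop("LoG sigmas must be positive (mm)", call. = FALSE)
  if (any(bin_counts < 2))
    stop("texture bin counts must be >= 2", call. = FALSE)
  structure(list(log_sigmas = log_sigmas, wavelet = isTRUE(wavelet),
                 bin_counts = as.integer(bin_counts),
                 first_order_bins = as.integer(first_order_bins),
                 min_voxels = as.integer(min_voxels),
                 families = families),
            class = "radiomics_config")
}

wavelet_labels <- c("LLL", "HLL", "LHL", "LLH", "LHH", "HLH", "HHL", "HHH")

config_image_types <- function(config) {
  types <- "original"
  if (length(config$log_sigmas))
    types <- c(types, sprintf("log_sigma_%s", format_edge(config$log_sigmas)))
  if (config$wavelet)
    types <- c(types, paste0("wavelet_", wavelet_labels))
  types
}

#' Canonical radiomics feature names for a configuration
#'
#' Names follow `region|modality|filter|bin|family|feature`; the bin slot is
#' `na` for shape and first-order features (computed once per image type)
#' and `b<n>` for texture features.
#'
#' @param config a [radiomics_config].
#' @param region,modality name components.
#' @return character vector of feature names in extraction order.
#' @export
radiomics_feature_names <- function(config = radiomics_config(),
                                    region = "region", modality = "CT") {
  types <- config_image_types(config)
  nm <- character(0)
  if ("shape" %in% config$families)
    nm <- c(nm, paste(region, modality, "original", "na", "shape",
                      shape_feature_names(), sep = "|"))
  for (ty in types) {
    if ("firstorder" %in% config$families)
      nm <- c(nm, paste(region, modality, ty, "na", "firstorder",
                        first_order_names(), sep = "|"))
    if ("texture" %in% config$families)
      for (b in config$bin_counts)
        nm <- c(nm, paste(region, modality, ty, paste0("b", b),
                          texture_feature_names(), sep = "|"))
  }
  nm
}

compute_image_type <- function(image, type) {
  if (type == "original") return(image)
  if (startsWith(type, "log_sigma_")) {
    sig <- as.numeric(gsub("p", ".", sub("log_sigma_", "", type)))
    return(log_filter(image, sig))
  }
  if (startsWith(type, "wavelet_")) {
    lab <- sub("wavelet_", "", type)
    return(wavelet_decompose(image)[[lab]])
  }
  stop("unknown image type: ", type, call. = FALSE)
}

#' Extract the full radiomics feature vector for one region
#'
#' Runs the configured protocol on one image/mask pair: shape on the
#' original mask, first-order statistics per image type, and the 73 texture
#' features per image type per bin count. Deterministic: two runs on the
#' same input give bit-identical vectors.
#'
#' @param image an [image_grid] (e.g. planning CT).
#' @param mask binary [image_grid] on the same grid.
#' @param config a [radiomics_config].
#' @param region,modality components of the emitted feature names.
#' @return named numeric vector (length 4610 under the default config);
#'   all-`NA` (with attribute `too_small`) when the region is below the
#'   configured minimum size.
#' @export
extract_all_radiomics <- function(image, mask, config = radiomics_config(),
                                  region = "region", modality = "CT") {
  stopifnot(is_image_grid(image), inherits(config, "radiomics_config"))
  assert_mask(mask)
  stop_if_misaligned(image, mask, "image and mask")
  nm <- radiomics_feature_names(config, region, modality)
  nvox <- sum(mask$voxels)
  if (nvox < config$min_voxels) {
    out <- rep(NA_real_, length(nm)); names(out) <- nm
    attr(out, "too_small") <- TRUE
    return(out)
  }
  vals <- numeric(0)
  if ("shape" %in% config$families)
    vals <- c(vals, unname(shape_features(mask)))
  # wavelet subbands are produced by one transform; cache the decomposition
  wav <- if (config$wavelet &&
             any(c("firstorder", "texture") %in% config$families))
    wavelet_decompose(image) else NULL
  for (ty in config_image_types(config)) {
    img_t <- if (startsWith(ty, "wavelet_")) wav[[sub("wavelet_", "", ty)]]
    else compute_image_type(image, ty)
    if ("firstorder" %in% config$families)
      vals <- c(vals, unname(first_order_features(
        img_t, mask, ref_bins = config$first_order_bins,
        min_voxels = config$min_voxels)))
    if ("texture" %in% config$families)
      for (b in config$bin_counts) {
        disc <- discretize_fixed_bin_count(img_t, mask, b)
        vals <- c(vals, unname(texture_features(disc,
                                                min_voxels = config$min_voxels)))
      }
  }
  names(vals) <- nm
  vals
}
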