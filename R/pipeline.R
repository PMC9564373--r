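# End-to-end orchestration: volumes -> subregions -> features -> selection
# -> models -> report.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. Input is either a manifest
#' (data.frame or CSV path with columns `id`, `ct`, `dose`, `lung`, `label`
#' pointing at NIfTI/NRRD files) or a synthetic cohort object. The
#' command-line front end (`inst/cli/idlss.R`) builds this configuration
#' from a YAML file.
#'
#' @param manifest data.frame or CSV path describing the cohort files.
#' @param cohort a `synthetic_cohort` (alternative to `manifest`).
#' @param edges IDLSS dose band edges (Gy).
#' @param extract feature blocks: `"dose"`, `"radiomics"` or both.
#' @param radiomics a [radiomics_config].
#' @param dose_bins dose-map discretization bin count.
#' @param groups feature groups to model (see [feature_group_columns]).
#' @param n_splits evaluation splits.
#' @param n_sel_iterations screening iterations per selection.
#' @param selection_mode `"per_split"` (leak-free) or `"global"`.
#' @param out_dir output directory (created if needed).
#' @param seed base seed for all stochastic stages.
#' @param overwrite recompute cached feature CSVs.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, cohort = NULL,
                            edges = c(0, 10, 20, 30, 40, 50),
                            extract = c("radiomics", "dose"),
                            radiomics = radiomics_config(),
                            dose_bins = 50,
                            groups = c("WL-RF", "WL-DF", "WL-RDF",
                                       "SR-RF", "SR-DF", "SR-RDF"),
                            n_splits = 30, n_sel_iterations = 100,
                            selection_mode = "per_split",
                            out_dir = tempfile("idlss_run_"), seed = 0,
                            overwrite = FALSE) {
  if (is.null(manifest) && is.null(cohort))
    stop("provide a `manifest` or a `cohort`", call. = FALSE)
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "pipeline_config")
}

load_manifest_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest,
                                                          stringsAsFactors = FALSE)
  needed <- c("id", "ct", "dose", "lung", "label")
  if (!all(needed %in% colnames(manifest)))
    stop("manifest needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  patients <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    ct <- read_volume(manifest$ct[i])
    dose <- read_volume(manifest$dose[i])
    lung <- read_volume(manifest$lung[i], mask = TRUE)
    if (!same_geometry(dose, ct)) dose <- resample_dose_to(dose, ct)
    if (!same_geometry(lung, ct)) lung <- resample_mask_to(lung, ct)
    patients[[i]] <- list(ct = ct, dose = dose, lung = lung)
  }
  list(patients = patients, labels = as.integer(manifest$label),
       ids = as.character(manifest$id))
}

#' Run the full pipeline
#'
#' Data to report: loads or takes the cohort, partitions each lung by the
#' incremental dose intervals, extracts the configured feature blocks per
#' region, writes the feature CSVs (reused on rerun unless `overwrite`),
#' assembles the requested feature groups, and runs the repeated
#' stratified-split ridge evaluation with per-group stability selection.
#' Outputs land in `config$out_dir`: `features_radiomics.csv`,
#' `features_dose.csv`, `selection_<group>.json`, `report.json`.
#'
#' @param config a [pipeline_config].
#' @return the `eval_report`, invisibly, with the output paths in
#'   `attr(, "paths")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (!is.null(config$cohort)) config$cohort
  else load_manifest_cohort(config$manifest)

  tabs <- list()
  for (blk in config$extract) {
    path <- file.path(config$out_dir,
                      sprintf("features_%s.csv",
                              if (blk == "dose") "dose" else "radiomics"))
    if (file.exists(path) && !config$overwrite) {
      tabs[[blk]] <- read_feature_table(path)
    } else {
      tabs[[blk]] <- extract_cohort_features(
        cohort, what = blk, edges = config$edges, config = config$radiomics,
        dose_bins = config$dose_bins)
      write_feature_table(tabs[[blk]], path)
    }
  }
  x <- do.call(cbind, lapply(tabs, function(t) t$x))
  table <- feature_table(x, tabs[[1]]$labels, tabs[[1]]$ids)

  sets <- lapply(config$groups, function(g)
    feature_group_columns(colnames(table$x), g))
  names(sets) <- config$groups
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("no columns for groups: ",
            paste(config$groups[empty], collapse = ", "),
            " (were those blocks extracted?)", call. = FALSE)
    sets <- sets[!empty]
  }
  report <- repeated_evaluation(
    table, feature_sets = sets, n_splits = config$n_splits,
    n_sel_iterations = config$n_sel_iterations,
    selection_mode = config$selection_mode, seed_base = config$seed)

  for (g in names(report$selected %||% list())) {
    jsonlite::write_json(
      list(group = g, selected = report$selected[[g]]),
      file.path(config$out_dir,
                sprintf("selection_%s.json", gsub("[^A-Za-z0-9]", "_", g))),
      auto_unbox = TRUE, pretty = TRUE)
  }
  jsonlite::write_json(
    list(n_splits = report$n_splits, seed = config$seed,
         selection_mode = report$selection_mode,
         summary = report$summary, comparisons = report$comparisons,
         records = report$records),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, dataframe = "rows", digits = NA)
  attr(report, "paths") <- list(
    out_dir = config$out_dir,
    report = file.path(config$out_dir, "report.json"))
  invisible(report)
}
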