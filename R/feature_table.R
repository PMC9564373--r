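#' Patients-by-features table with binary outcome labels
#'
#' Light container for the modeling stages: a numeric matrix of feature
#' values (rows = patients), the patient IDs, and the binary outcome
#' (severe acute radiation pneumonitis yes/no, coded 1/0).
#'
#' @param x numeric matrix, patients x features, with column names.
#' @param labels binary outcome vector in {0, 1}, one per patient.
#' @param ids patient identifiers (default rownames of `x` or P001...).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(x, labels, ids = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("feature columns must have unique names", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x) || any(!labels %in% c(0L, 1L)))
    stop("`labels` must be one 0/1 value per patient", call. = FALSE)
  if (is.null(ids)) ids <- rownames(x) %||% sprintf("P%03d", seq_len(nrow(x)))
  if (anyDuplicated(ids)) stop("duplicate patient ids", call. = FALSE)
  rownames(x) <- ids
  structure(list(x = x, labels = labels, ids = as.character(ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features, %d events (%.1f%%)\n",
              nrow(x$x), ncol(x$x), sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

subset_table <- function(table, rows = NULL, cols = NULL) {
  x <- table$x
  labels <- table$labels
  ids <- table$ids
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]; labels <- labels[rows]; ids <- ids[rows]
  }
  if (!is.null(cols)) x <- x[, cols, drop = FALSE]
  feature_table(x, labels, ids)
}

#' Drop features with missing values
#'
#' Features that are missing in any patient (e.g. from subregions below the
#' minimum voxel count) are excluded before selection; the dropped names are
#' reported in a message and returned as an attribute.
#'
#' @param table a [feature_table].
#' @return the table without incomplete features (attribute `dropped`).
#' @export
drop_incomplete_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  bad <- colnames(table$x)[colSums(!is.finite(table$x)) > 0]
  if (length(bad)) {
    message("dropping ", length(bad), " features with missing values")
    table <- subset_table(table, cols = setdiff(colnames(table$x), bad))
  }
  attr(table, "dropped") <- bad
  table
}

#' Write / read a feature table as CSV
#'
#' One row per patient; the first two columns are `patient_id` and `label`,
#' the rest are the canonical feature names.
#'
#' @param table a [feature_table].
#' @param path CSV path.
#' @return `path` invisibly (write); a [feature_table] (read).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(patient_id = table$ids, label = table$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "label") %in% colnames(df)))
  x <- as.matrix(df[, setdiff(colnames(df), c("patient_id", "label")),
                    drop = FALSE])
  feature_table(x, df$label, df$patient_id)
}
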