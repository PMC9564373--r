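# Ridge classification with repeated stratified 70/30 evaluation.

#' Stratified train/test split
#'
#' Splits the cohort into train and test with the event fraction preserved:
#' per class, `round(train_fraction * class size)` patients go to training.
#' Deterministic per seed; disjoint and exhaustive.
#'
#' @param table a [feature_table].
#' @param train_fraction fraction in training (default 0.7).
#' @param seed RNG seed.
#' @return list with integer row indices `train` and `test` and the
#'   corresponding `train_ids` / `test_ids`.
#' @export
stratified_split <- function(table, train_fraction = 0.7, seed = 0) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$labels
  if (sum(y == 1L) < 2 || sum(y == 0L) < 2)
    stop("each class needs at least 2 patients to split", call. = FALSE)
  train <- local_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(train_fraction * length(idx)))
    }))
  })
  train <- sort(train)
  test <- setdiff(seq_along(y), train)
  list(train = train, test = test,
       train_ids = table$ids[train], test_ids = table$ids[test])
}

# rank-based AUC of continuous scores (equals trapezoidal ROC with ties
# averaged / the Mann-Whitney statistic)
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment for cross-validation
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  local_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Fit a ridge classifier with cross-validated regularization
#'
#' Standardizes the features on the training data, fits L2-penalized least
#' squares on the {0, 1} labels (glmnet, alpha = 0), and picks the
#' regularization strength from a log-spaced grid (1e-3..1e3, 13 points) by
#' stratified 5-fold cross-validation maximizing the mean AUC of the
#' continuous prediction; ties prefer the stronger penalty. The model is
#' refit on the full training set at the chosen strength. The continuous
#' prediction ranks patients; 0.5 is the classification threshold.
#'
#' @param train a [feature_table] of training patients (both classes
#'   present, >= 10 patients).
#' @param lambda_grid penalty grid (decreasing internally).
#' @param n_folds CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return object of class `ridge_model`: coefficients on the standardized
#'   scale, intercept, chosen `lambda`, standardization parameters, CV AUC
#'   per grid point.
#' @export
fit_ridge_cv <- function(train, lambda_grid = 10^seq(-3, 3, length.out = 13),
                         n_folds = 5, seed = 0) {
  stopifnot(inherits(train, "feature_table"))
  y <- train$labels
  if (length(unique(y)) < 2)
    stop("training data contains a single class", call. = FALSE)
  if (nrow(train$x) < 10)
    stop("need at least 10 training patients", call. = FALSE)
  x <- train$x
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  padded <- ncol(xs) < 2
  if (padded) xs <- cbind(xs, `.pad` = 0)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  folds <- stratified_folds(y, n_folds, seed)
  cv_auc <- matrix(NA_real_, nrow = n_folds, ncol = length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || sum(folds == f) < 1) next
    fit <- glmnet::glmnet(xs[tr, , drop = FALSE], y[tr], alpha = 0,
                          lambda = lambda_grid, family = "gaussian",
                          standardize = FALSE)
    pred <- stats::predict(fit, xs[!tr, , drop = FALSE], s = lambda_grid)
    cv_auc[f, ] <- apply(pred, 2, auc_score, labels = y[!tr])
  }
  mean_auc <- colMeans(cv_auc, na.rm = TRUE)
  # grid is decreasing, so which.max already prefers the stronger penalty on ties
  best <- which.max(mean_auc)
  lambda <- lambda_grid[best]
  fit <- glmnet::glmnet(xs, y, alpha = 0, lambda = lambda_grid,
                        family = "gaussian", standardize = FALSE)
  cf <- as.numeric(stats::coef(fit, s = lambda))
  beta <- cf[-1]
  if (padded) beta <- beta[-length(beta)]
  structure(list(
    beta = stats::setNames(beta, colnames(train$x)),
    intercept = cf[1],
    lambda = lambda,
    center = ctr, scale = scl,
    lambda_grid = lambda_grid,
    cv_auc = stats::setNames(mean_auc, format(lambda_grid))
  ), class = "ridge_model")
}

#' Predict continuous risk scores from a ridge model
#' @param object a `ridge_model`.
#' @param table a [feature_table] with the model's feature columns.
#' @param ... unused.
#' @return numeric scores (affine in the standardized inputs).
#' @export
predict.ridge_model <- function(object, table, ...) {
  x <- if (inherits(table, "feature_table")) table$x else as.matrix(table)
  missing <- setdiff(names(object$beta), colnames(x))
  if (length(missing))
    stop("features absent from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- x[, names(object$beta), drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  as.numeric(object$intercept + xs %*% object$beta)
}

#' Classification metrics of a fitted model on a dataset
#'
#' AUC from the continuous scores (rank-based, ties averaged); accuracy,
#' precision, recall and F1 from thresholding the continuous prediction at
#' 0.5. Precision is 0 (with a message) when no patient is predicted
#' positive; F1 is 0 when precision + recall is 0.
#'
#' @param model a `ridge_model`.
#' @param table a [feature_table].
#' @return named numeric vector: auc, accuracy, precision, recall, f1.
#' @export
evaluate_model <- function(model, table) {
  stopifnot(inherits(model, "ridge_model"), inherits(table, "feature_table"))
  scores <- stats::predict(model, table)
  metric_record(scores, table$labels)
}

metric_record <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp == 0) {
    message("no positive predictions; precision set to 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(auc = auc_score(scores, labels),
    accuracy = (tp + tn) / length(labels),
    precision = precision, recall = recall, f1 = f1)
}

#' Compare two models by their per-split metric vectors
#'
#' Two-sided two-sample Student's t-test (equal variances) on the per-split
#' metric values, typically test AUCs over the 30 splits. Returns p = 1 when
#' both vectors are identical constants (degenerate variance).
#'
#' @param a,b equal-length numeric vectors of per-split metrics.
#' @return the p-value.
#' @export
compare_models <- function(a, b) {
  if (length(a) != length(b))
    stop("metric vectors differ in length", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1.0 else 0.0)
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Repeated stratified-split evaluation of feature groups
#'
#' The evaluation protocol: for each of `n_splits` stratified 70/30 splits
#' and each named feature group, run feature selection (leak-free by
#' default: on the training split only), fit the cross-validated ridge
#' model, and record train and test metrics. With
#' `selection_mode = "global"` selection instead runs once per group on the
#' full table before splitting, the literal single-pass reading of the
#' procedure; both modes are exposed because the protocol is ambiguous on
#' this point.
#'
#' @param table a [feature_table].
#' @param feature_sets named list of character vectors of feature names
#'   (e.g. the six groups WL-RF/WL-DF/WL-RDF/SR-RF/SR-DF/SR-RDF); `NULL`
#'   entries mean "all columns".
#' @param n_splits number of train/test splits (default 30; split s uses
#'   seed `seed_base + s`).
#' @param train_fraction training fraction per class.
#' @param select run the stability selection inside each group.
#' @param selection_mode `"per_split"` (leak-free default) or `"global"`.
#' @param n_sel_iterations screening iterations per selection run.
#' @param seed_base base RNG seed.
#' @return object of class `eval_report`: `records` (one row per split x
#'   group x cohort), `summary` (mean/STD per metric), `comparisons`
#'   (pairwise test-AUC t-test p-values), `selected` (per group, last or
#'   global selection).
#' @export
repeated_evaluation <- function(table, feature_sets = list(all = NULL),
                                n_splits = 30, train_fraction = 0.7,
                                select = TRUE,
                                selection_mode = c("per_split", "global"),
                                n_sel_iterations = 100, seed_base = 0) {
  stopifnot(inherits(table, "feature_table"))
  selection_mode <- match.arg(selection_mode)
  if (is.null(names(feature_sets)))
    stop("`feature_sets` must be a named list", call. = FALSE)
  table <- drop_incomplete_features(table)
  groups <- lapply(feature_sets, function(fs) {
    if (is.null(fs)) colnames(table$x)
    else intersect(fs, colnames(table$x))
  })

  global_sel <- NULL
  if (select && selection_mode == "global") {
    global_sel <- lapply(groups, function(cols) {
      select_features(subset_table(table, cols = cols),
                      n_iterations = n_sel_iterations)
    })
  }

  records <- list()
  last_sel <- stats::setNames(vector("list", length(groups)), names(groups))
  for (s in seq_len(n_splits) - 1L) {
    sp <- stratified_split(table, train_fraction, seed = seed_base + s)
    for (g in names(groups)) {
      train_tab <- subset_table(table, rows = sp$train, cols = groups[[g]])
      test_tab <- subset_table(table, rows = sp$test, cols = groups[[g]])
      feats <- if (!select) {
        groups[[g]]
      } else if (selection_mode == "global") {
        global_sel[[g]]$selected
      } else {
        sel <- select_features(train_tab, n_iterations = n_sel_iterations,
                               seeds = (seed_base + s) * 100000L +
                                 seq_len(n_sel_iterations) - 1L)
        last_sel[[g]] <- sel
        sel$selected
      }
      if (!length(feats)) {
        # nothing survived selection (null-signal data): fall back to the
        # most frequent screened candidate, or the first column
        fallback <- if (select && selection_mode == "per_split" &&
                        length(last_sel[[g]]$candidates))
          last_sel[[g]]$candidates[1] else groups[[g]][1]
        message("split ", s, " group ", g,
                ": selection empty; falling back to ", fallback)
        feats <- fallback
      }
      model <- fit_ridge_cv(subset_table(train_tab, cols = feats),
                            seed = seed_base + s)
      for (cohort in c("train", "test")) {
        tab <- if (cohort == "train") train_tab else test_tab
        met <- evaluate_model(model, subset_table(tab, cols = feats))
        records[[length(records) + 1L]] <- data.frame(
          model = g, split = s, cohort = cohort, t(met),
          n_features = length(feats), lambda = model$lambda,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  metrics <- c("auc", "accuracy", "precision", "recall", "f1")
  summary <- do.call(rbind, lapply(split(
    records, list(records$model, records$cohort), sep = "|"),
    function(df) {
      data.frame(model = df$model[1], cohort = df$cohort[1],
                 metric = metrics,
                 mean = vapply(metrics, function(m) mean(df[[m]]), numeric(1)),
                 sd = vapply(metrics, function(m) stats::sd(df[[m]]), numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  gnames <- names(groups)
  comparisons <- NULL
  if (length(gnames) > 1) {
    cmb <- utils::combn(gnames, 2)
    comparisons <- data.frame(
      model_a = cmb[1, ], model_b = cmb[2, ],
      p_value = apply(cmb, 2, function(pair) {
        av <- records$auc[records$model == pair[1] & records$cohort == "test"]
        bv <- records$auc[records$model == pair[2] & records$cohort == "test"]
        compare_models(av, bv)
      }), stringsAsFactors = FALSE)
  }
  structure(list(records = records, summary = summary,
                 comparisons = comparisons,
                 selected = if (select) {
                   if (selection_mode == "global")
                     lapply(global_sel, `[[`, "selected")
                   else lapply(last_sel, `[[`, "selected")
                 },
                 n_splits = n_splits, seed_base = seed_base,
                 selection_mode = if (select) selection_mode else "none"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d splits, models: %s\n", x$n_splits,
              paste(unique(x$records$model), collapse = ", ")))
  s <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %-5s AUC %.3f +/- %.3f\n", s$model[i], s$cohort[i],
                s$mean[i], s$sd[i]))
  invisible(x)
}
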