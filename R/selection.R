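# Stability feature selection: repeated stratified subsampling, variance
# filtering, z-scoring, t-test screening, frequency ranking, and Pearson
# redundancy pruning.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# per-class subsample sizes: overall floor(fraction * n) with the class
# ratio preserved to the nearest integer (126 patients -> 88)
stratified_subsample_sizes <- function(labels, fraction) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  k1 <- max(1L, round(fraction * n1))
  k0 <- max(1L, round(fraction * n0))
  c(k0 = k0, k1 = k1)
}

# vectorized two-sided Welch t-test of every column between classes
welch_columns <- function(x, y) {
  x1 <- x[y == 1L, , drop = FALSE]
  x0 <- x[y == 0L, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p)
}

#' One screening iteration of the stability selection
#'
#' Draws a stratified subsample of the given fraction of patients (class
#' ratio preserved to the nearest integer; 70% of 126 near-balanced cases is
#' 88), removes zero-variance features, z-scores the rest on the subsample,
#' and keeps features whose two-sided Welch t-test between outcome classes
#' has p <= `p_max`.
#'
#' @param table a [feature_table] (complete features only).
#' @param seed RNG seed for the subsample draw.
#' @param p_max t-test retention cutoff (default 0.1).
#' @param fraction subsample fraction (default 0.7).
#' @return character vector of retained feature names; attributes `tstat`
#'   (named t statistics of the retained features) and `n_subsample`.
#' @export
screen_iteration <- function(table, seed, p_max = 0.1, fraction = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$labels
  if (sum(y == 1L) < 2 || sum(y == 0L) < 2)
    stop("need at least 2 patients per class to screen", call. = FALSE)
  k <- stratified_subsample_sizes(y, fraction)
  rows <- local_seed(seed, c(sample(which(y == 0L), k["k0"]),
                             sample(which(y == 1L), k["k1"])))
  xs <- table$x[rows, , drop = FALSE]
  ys <- y[rows]
  sds <- apply(xs, 2, stats::sd)
  keep_var <- sds > 0
  xs <- xs[, keep_var, drop = FALSE]
  # z-scoring on the subsample; the t statistic is invariant to this affine
  # rescaling, but the standardized matrix is what downstream steps would see
  xs <- scale(xs)
  tt <- welch_columns(xs, ys)
  kept <- which(tt$p <= p_max)
  out <- colnames(xs)[kept]
  attr(out, "tstat") <- stats::setNames(tt$t[kept], out)
  attr(out, "n_subsample") <- length(rows)
  out
}

#' Frequency ranking of screened feature sets
#'
#' Counts how often each feature survived the screening iterations and keeps
#' the `k = max(ceiling(0.10 * n_total_features), 10)` most frequent ones
#' (10% of the total feature count, with a floor of 10). Ties at the cutoff
#' are broken by the larger mean |t| across the iterations in which the
#' feature appeared, then lexicographically.
#'
#' @param iteration_sets list of character vectors from [screen_iteration]
#'   (their `tstat` attributes, when present, feed the tie-break).
#' @param n_total_features the feature count entering selection.
#' @return character vector of candidate names, most frequent first;
#'   attribute `frequency` holds the occurrence counts of all seen features.
#' @export
frequency_rank <- function(iteration_sets, n_total_features) {
  stopifnot(length(iteration_sets) >= 1)
  all_names <- unlist(iteration_sets, use.names = FALSE)
  if (!length(all_names)) {
    out <- character(0); attr(out, "frequency") <- integer(0)
    return(out)
  }
  freq <- table(all_names)
  tsum <- numeric(length(freq)); names(tsum) <- names(freq)
  tcnt <- integer(length(freq)); names(tcnt) <- names(freq)
  for (s in iteration_sets) {
    ts <- attr(s, "tstat")
    if (is.null(ts)) next
    tsum[names(ts)] <- tsum[names(ts)] + abs(ts)
    tcnt[names(ts)] <- tcnt[names(ts)] + 1L
  }
  mean_t <- ifelse(tcnt > 0, tsum / pmax(tcnt, 1L), 0)
  k <- max(ceiling(0.10 * n_total_features), 10L)
  ord <- order(-as.integer(freq), -mean_t, names(freq))
  out <- names(freq)[ord][seq_len(min(k, length(freq)))]
  attr(out, "frequency") <- stats::setNames(as.integer(freq)[ord],
                                            names(freq)[ord])
  out
}

#' Pearson redundancy pruning of candidate features
#'
#' Computes all pairwise Pearson correlations among the candidates on the
#' selection dataset, walks the pairs with |R| above the threshold in
#' descending |R| (ties lexicographic), and from each still-active pair
#' removes the member with the higher mean absolute correlation to all other
#' candidates (computed once up front). Constant candidates have undefined
#' correlation and are dropped with a warning.
#'
#' @param table a [feature_table].
#' @param candidates character vector of candidate feature names.
#' @param threshold |R| above which a pair counts as redundant (default 0.5).
#' @return character vector of surviving names (original candidate order);
#'   attribute `removed` lists the pruned features.
#' @export
redundancy_prune <- function(table, candidates, threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  candidates <- as.character(candidates)
  missing <- setdiff(candidates, colnames(table$x))
  if (length(missing))
    stop("candidates not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(candidates) < 2) return(candidates)
  x <- table$x[, candidates, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant candidates with undefined correlation: ",
            paste(candidates[sds == 0], collapse = ", "), call. = FALSE)
    candidates <- candidates[sds > 0]
    if (length(candidates) < 2) return(candidates)
    x <- x[, candidates, drop = FALSE]
  }
  C <- abs(stats::cor(x))
  diag(C) <- 0
  mean_corr <- rowMeans(C) * ncol(C) / (ncol(C) - 1)  # exclude self
  pairs <- which(upper.tri(C) & C > threshold, arr.ind = TRUE)
  if (!nrow(pairs)) return(candidates)
  pr <- data.frame(a = candidates[pairs[, 1]], b = candidates[pairs[, 2]],
                   r = C[pairs], stringsAsFactors = FALSE)
  pr <- pr[order(-pr$r, pr$a, pr$b), ]
  active <- stats::setNames(rep(TRUE, length(candidates)), candidates)
  removed <- character(0)
  for (i in seq_len(nrow(pr))) {
    a <- pr$a[i]; b <- pr$b[i]
    if (!active[a] || !active[b]) next
    drop <- if (mean_corr[a] > mean_corr[b]) a
    else if (mean_corr[b] > mean_corr[a]) b
    else max(a, b)  # equal mean correlation: drop the lexicographically later
    active[drop] <- FALSE
    removed <- c(removed, drop)
  }
  out <- candidates[active[candidates]]
  attr(out, "removed") <- removed
  out
}

#' Full stability feature selection
#'
#' Orchestrates the five-step procedure: `n_iterations` screening rounds
#' (stratified 70% subsample, variance filter, z-scoring, Welch t-test at
#' `p_max`), frequency ranking with the 10%-or-at-least-10 rule, and Pearson
#' redundancy pruning at `r_max`. Fully deterministic given `seeds`
#' (iteration i uses `seeds[i]`; default `0:(n_iterations-1)`).
#'
#' @param table a [feature_table]; features with missing values are dropped
#'   first (logged).
#' @param n_iterations number of screening subsamples (default 100).
#' @param seeds integer vector of per-iteration seeds.
#' @param p_max t-test cutoff.
#' @param r_max redundancy correlation threshold.
#' @param fraction subsample fraction.
#' @return object of class `selection_result`: list with `selected`,
#'   `candidates`, `frequency`, `removed_redundant`, `n_iterations`,
#'   `n_features_in`.
#' @export
select_features <- function(table, n_iterations = 100, seeds = NULL,
                            p_max = 0.1, r_max = 0.5, fraction = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  table <- drop_incomplete_features(table)
  if (is.null(seeds)) seeds <- seq_len(n_iterations) - 1L
  stopifnot(length(seeds) == n_iterations)
  sets <- lapply(seeds, function(s)
    screen_iteration(table, seed = s, p_max = p_max, fraction = fraction))
  candidates <- frequency_rank(sets, n_total_features = ncol(table$x))
  selected <- redundancy_prune(table, candidates, threshold = r_max)
  structure(list(
    selected = as.character(selected),
    candidates = as.character(candidates),
    frequency = attr(candidates, "frequency"),
    removed_redundant = attr(selected, "removed") %||% character(0),
    n_iterations = n_iterations,
    n_features_in = ncol(table$x),
    dropped_incomplete = attr(table, "dropped")
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d selected of %d candidates (%d features in, %d iterations)\n",
    length(x$selected), length(x$candidates), x$n_features_in, x$n_iterations))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = "\n  "), "\n")
  invisible(x)
}
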