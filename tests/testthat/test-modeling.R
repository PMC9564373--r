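gaussian_table <- function(n = 200, p = 10, delta = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
  x[, 1] <- x[, 1] + delta * y
  feature_table(x, y)
}

test_that("the stratified split keeps the event distribution", {
  tab <- make_table(n = 126)  # 64 events / 62 non-events
  sp <- stratified_split(tab, seed = 0)
  expect_equal(sum(tab$labels[sp$train]), 45)   # round(0.7 * 64)
  expect_equal(length(sp$train) - sum(tab$labels[sp$train]), 43)
  expect_setequal(c(sp$train, sp$test), seq_len(126))
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("splits are deterministic per seed and differ across seeds", {
  tab <- gaussian_table()
  expect_identical(stratified_split(tab, seed = 3),
                   stratified_split(tab, seed = 3))
  expect_false(identical(stratified_split(tab, seed = 3)$train,
                         stratified_split(tab, seed = 4)$train))
})

test_that("well-separated classes reach near-perfect training AUC", {
  tab <- gaussian_table(n = 200, delta = 6)
  model <- fit_ridge_cv(tab, seed = 0)
  expect_gte(unname(evaluate_model(model, tab)["auc"]), 0.99)
})

test_that("null features give chance-level test AUC on average", {
  aucs <- vapply(1:50, function(s) {
    tab <- gaussian_table(n = 200, p = 10, delta = 0, seed = s)
    sp <- stratified_split(tab, seed = s)
    m <- fit_ridge_cv(idlss:::subset_table(tab, rows = sp$train), seed = s)
    unname(evaluate_model(m, idlss:::subset_table(tab, rows = sp$test))["auc"])
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("duplicating a feature splits the L2 weight and keeps the fit", {
  # exact duplicates share the ridge weight equally; in the small-penalty
  # limit the fitted values coincide with the (unique) least-squares
  # projection, so predictions are unchanged by duplication
  tab <- gaussian_table(n = 100, p = 5, delta = 2, seed = 2)
  x2 <- cbind(tab$x, dup = tab$x[, 1])
  tab2 <- feature_table(x2, tab$labels)
  # at a strictly positive penalty the minimizer is unique and symmetric
  m_a <- fit_ridge_cv(tab, lambda_grid = 0.5, seed = 0)
  m_b <- fit_ridge_cv(tab2, lambda_grid = 0.5, seed = 0)
  expect_equal(unname(m_b$beta["dup"]), unname(m_b$beta["g01"]),
               tolerance = 1e-3)  # glmnet coordinate-descent precision
  # in the small-penalty limit the fitted values are the unique
  # least-squares projection, unchanged by duplication
  m1 <- fit_ridge_cv(tab, lambda_grid = 1e-7, seed = 0)
  m2 <- fit_ridge_cv(tab2, lambda_grid = 1e-7, seed = 0)
  expect_equal(unname(m2$beta["dup"] + m2$beta["g01"]),
               unname(m1$beta["g01"]), tolerance = 1e-3)
  p1 <- predict(m1, tab)
  p2 <- predict(m2, tab2)
  expect_lt(max(abs(p1 - p2)), 1e-5)
})

test_that("single-class training data is rejected", {
  tab <- gaussian_table(n = 40)
  tab$labels <- rep(1L, 40)
  expect_error(fit_ridge_cv(tab), "single class")
})

test_that("metric records follow the confusion-matrix formulas", {
  # scores (.9,.8,.3,.1) with labels (1,1,0,0): perfect ranking
  rec <- idlss:::metric_record(c(0.9, 0.8, 0.3, 0.1), c(1L, 1L, 0L, 0L))
  expect_equal(unname(rec["auc"]), 1)
  expect_equal(unname(rec["accuracy"]), 1)
  # TP=2 FP=1 FN=1 TN=2
  rec2 <- idlss:::metric_record(c(0.9, 0.8, 0.6, 0.2, 0.4, 0.1),
                                c(1L, 1L, 0L, 1L, 1L, 0L))
  expect_equal(unname(rec2["precision"]), 2 / 3)
  expect_equal(unname(rec2["recall"]), 1 / 2)
  expect_equal(unname(rec2["f1"]), 4 / 7)
  # identical scores: tie-averaged AUC is 0.5
  rec3 <- suppressMessages(
    idlss:::metric_record(rep(0.4, 6), c(1L, 0L, 1L, 0L, 1L, 0L)))
  expect_equal(unname(rec3["auc"]), 0.5)
  expect_equal(unname(rec3["precision"]), 0)  # no positive predictions
})

test_that("the rank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5)
    s <- rnorm(40) + y
    expect_equal(idlss:::auc_score(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("model comparison handles degenerate and separated inputs", {
  expect_equal(compare_models(rep(0.8, 30), rep(0.8, 30)), 1.0)
  expect_error(compare_models(1:5, 1:6), "length")
  set.seed(4)
  a <- rnorm(30, 0.9, 0.01)
  b <- rnorm(30, 0.6, 0.01)   # 30 SDs apart
  expect_lt(compare_models(a, b), 1e-3)
})

test_that("unknown feature names are a schema error at prediction", {
  tab <- gaussian_table(n = 60, p = 4, delta = 1)
  m <- fit_ridge_cv(tab, seed = 0)
  bad <- feature_table(matrix(rnorm(60), 15, 4,
                              dimnames = list(NULL, sprintf("h%02d", 1:4))),
                       rep(c(0L, 1L), length.out = 15))
  expect_error(evaluate_model(m, bad), "absent")
})

test_that("repeated evaluation yields one record per split, group and cohort", {
  tab <- gaussian_table(n = 60, p = 8, delta = 2, seed = 5)
  rep <- suppressMessages(repeated_evaluation(
    tab, list(A = c("g01", "g02"), B = c("g03", "g04")),
    n_splits = 6, select = FALSE))
  expect_equal(nrow(rep$records), 6 * 2 * 2)
  expect_true(all(rep$records$auc >= 0 & rep$records$auc <= 1))
  # summary means recompute exactly from the records
  for (i in seq_len(nrow(rep$summary))) {
    s <- rep$summary[i, ]
    sub <- rep$records[rep$records$model == s$model &
                         rep$records$cohort == s$cohort, s$metric]
    expect_equal(s$mean, mean(sub))
    expect_equal(s$sd, sd(sub))
  }
  expect_equal(nrow(rep$comparisons), 1)
})

test_that("repeated evaluation is deterministic given the base seed", {
  tab <- gaussian_table(n = 60, p = 6, delta = 1.5, seed = 6)
  r1 <- suppressMessages(repeated_evaluation(tab, list(all = NULL),
                                             n_splits = 4,
                                             n_sel_iterations = 10,
                                             seed_base = 2))
  r2 <- suppressMessages(repeated_evaluation(tab, list(all = NULL),
                                             n_splits = 4,
                                             n_sel_iterations = 10,
                                             seed_base = 2))
  expect_identical(r1$records, r2$records)
})

test_that("a test-labels canary feature cannot leak into default-mode models", {
  # the canary equals the outcome for the patients of one split's test set
  # and is noise elsewhere; leak-free selection and standardization must not
  # discover it, so the test AUC stays near chance
  set.seed(7)
  n <- 80
  y <- rep(c(0L, 1L), each = 40)
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, sprintf("n%02d", 1:6)))
  tab0 <- feature_table(x, y)
  sp <- stratified_split(tab0, seed = 0)
  canary <- rnorm(n)
  canary[sp$test] <- y[sp$test] * 10
  tab <- feature_table(cbind(x, canary = canary), y)
  rep <- suppressMessages(repeated_evaluation(
    tab, list(all = NULL), n_splits = 1, n_sel_iterations = 20,
    seed_base = 0))
  auc_test <- rep$records$auc[rep$records$cohort == "test"]
  expect_lt(auc_test, 0.75)
})

test_that("extreme regularization shrinks toward chance-level separation", {
  tab <- gaussian_table(n = 120, p = 6, delta = 1, seed = 8)
  m_small <- fit_ridge_cv(tab, lambda_grid = 1e-3, seed = 0)
  m_big <- fit_ridge_cv(tab, lambda_grid = 1e6, seed = 0)
  expect_lt(max(abs(m_big$beta)), max(abs(m_small$beta)) * 1e-2)
})
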