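test_that("the stratified subsample of the near-balanced cohort has 88 cases", {
  tab <- make_table(n = 126)  # 64 events / 62 non-events
  kept <- screen_iteration(tab, seed = 0)
  expect_equal(attr(kept, "n_subsample"), 88)
  # class ratio preserved to the nearest integer: 45 events, 43 non-events
  k <- idlss:::stratified_subsample_sizes(tab$labels, 0.7)
  expect_equal(unname(k["k1"]), 45)
  expect_equal(unname(k["k0"]), 43)
})

test_that("zero-variance features never survive screening", {
  tab <- make_table(p = 20)
  tab$x[, "f007"] <- 3.14
  for (seed in 0:4)
    expect_false("f007" %in% screen_iteration(tab, seed = seed))
})

test_that("screening is deterministic per seed and matches a direct t-test", {
  tab <- make_table(n = 60, p = 30, n_signal = 2, seed = 2)
  s1 <- screen_iteration(tab, seed = 5)
  s2 <- screen_iteration(tab, seed = 5)
  expect_identical(s1, s2)
  # recompute the subsample and Welch p-values independently
  rows <- idlss:::local_seed(5, {
    y <- tab$labels
    k <- idlss:::stratified_subsample_sizes(y, 0.7)
    c(sample(which(y == 0L), k["k0"]), sample(which(y == 1L), k["k1"]))
  })
  p_direct <- apply(tab$x[rows, ], 2, function(col) {
    if (sd(col) == 0) return(NA_real_)
    stats::t.test(col[tab$labels[rows] == 1],
                  col[tab$labels[rows] == 0])$p.value
  })
  expect_setequal(s1, names(p_direct)[!is.na(p_direct) & p_direct <= 0.1])
})

test_that("raising the p cutoff never shrinks the surviving set", {
  tab <- make_table(n = 80, p = 40, n_signal = 3, seed = 3)
  for (seed in 0:3) {
    tight <- screen_iteration(tab, seed = seed, p_max = 0.05)
    loose <- screen_iteration(tab, seed = seed, p_max = 0.1)
    expect_true(all(tight %in% loose))
  }
})

test_that("a strongly separated feature is retained in nearly every iteration", {
  # class means 3 pooled SDs apart: t-test power at n = 88 is essentially 1
  tab <- make_table(n = 126, p = 50, n_signal = 1, effect = 3, seed = 4)
  hits <- sum(vapply(0:99, function(s)
    "f001" %in% screen_iteration(tab, seed = s), logical(1)))
  expect_gte(hits, 99)
})

test_that("frequency ranking keeps the 10%-or-at-least-10 head of the list", {
  sets <- c(replicate(90, c("A", "B"), simplify = FALSE),
            replicate(10, c("A", "C"), simplify = FALSE))
  r50 <- frequency_rank(sets, n_total_features = 50)
  expect_equal(r50[1], "A")                 # 100 occurrences, ranked first
  expect_length(r50, min(10, 3))            # only 3 distinct features seen
  expect_equal(attr(r50, "frequency")[["A"]], 100L)
  # k rules
  sets2 <- list(sprintf("g%02d", 1:30))
  expect_length(frequency_rank(sets2, n_total_features = 200), 20)  # 10%
  expect_length(frequency_rank(sets2, n_total_features = 40), 10)   # floor
  expect_length(frequency_rank(sets2, n_total_features = 101), 11)  # ceiling
})

test_that("frequency ties break by mean |t| then name", {
  s1 <- structure(c("A", "B"), tstat = c(A = 1, B = 5))
  s2 <- structure(c("A", "B"), tstat = c(A = 2, B = 4))
  r <- frequency_rank(list(s1, s2), n_total_features = 10)
  expect_equal(r[1:2], c("B", "A"))   # same frequency, larger mean |t| first
  s3 <- structure(c("A", "B"), tstat = c(A = 3, B = 3))
  r2 <- frequency_rank(list(s3), n_total_features = 10)
  expect_equal(r2[1:2], c("A", "B"))  # full tie: lexicographic
})

test_that("redundancy pruning removes one of a duplicated pair", {
  tab <- make_table(n = 60, p = 10, seed = 5)
  tab$x[, "f002"] <- tab$x[, "f001"]
  out <- redundancy_prune(tab, c("f001", "f002", "f003"))
  expect_length(out, 2)
  expect_true("f003" %in% out)
  expect_length(intersect(out, c("f001", "f002")), 1)
})

test_that("pruning keeps independent features and respects the threshold", {
  set.seed(6)
  n <- 200
  x <- cbind(X = rnorm(n), Z = rnorm(n))
  x <- cbind(x, Y = x[, "X"] + rnorm(n, sd = 0.05))  # near-duplicate of X
  tab <- feature_table(x[, c("X", "Y", "Z")], rbinom(n, 1, 0.5))
  out <- redundancy_prune(tab, c("X", "Y", "Z"))
  expect_true("Z" %in% out)
  expect_length(out, 2)
  # X and Y form the only high-R pair; the one more correlated on average
  # with the rest goes
  C <- abs(cor(tab$x))
  mean_corr <- (rowSums(C) - 1) / 2
  expect_false(names(which.max(mean_corr[c("X", "Y")])) %in% out)
  # all-pairs-below-threshold input returns unchanged
  tab2 <- make_table(n = 100, p = 5, seed = 7)
  expect_equal(redundancy_prune(tab2, colnames(tab2$x)),
               colnames(tab2$x))
})

test_that("no surviving pair exceeds the correlation threshold", {
  set.seed(8)
  n <- 80
  base <- matrix(rnorm(n * 4), n, 4)
  x <- cbind(base, base + matrix(rnorm(n * 4, sd = 0.3), n, 4))
  colnames(x) <- sprintf("c%02d", 1:8)
  tab <- feature_table(x, rbinom(n, 1, 0.5))
  out <- redundancy_prune(tab, colnames(x), threshold = 0.5)
  C <- abs(cor(tab$x[, out, drop = FALSE]))
  diag(C) <- 0
  expect_lt(max(C), 0.5 + 1e-12)
})

test_that("constant candidates are dropped with a warning", {
  tab <- make_table(n = 50, p = 5, seed = 9)
  tab$x[, "f004"] <- 1
  expect_warning(out <- redundancy_prune(tab, colnames(tab$x)), "constant")
  expect_false("f004" %in% out)
})

test_that("the full selection is deterministic and recovers planted signal", {
  tab <- make_table(n = 126, p = 200, n_signal = 5, effect = 1.5, seed = 10)
  s1 <- select_features(tab, n_iterations = 50)
  s2 <- select_features(tab, n_iterations = 50)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$frequency, s2$frequency)
  planted <- sprintf("f%03d", 1:5)
  expect_gte(length(intersect(planted, s1$candidates)), 4)
})

test_that("selection output is invariant to feature column order", {
  tab <- make_table(n = 80, p = 30, n_signal = 3, seed = 11)
  perm <- sample(ncol(tab$x))
  tab2 <- feature_table(tab$x[, perm], tab$labels, tab$ids)
  s1 <- select_features(tab, n_iterations = 20)
  s2 <- select_features(tab2, n_iterations = 20)
  expect_setequal(s1$selected, s2$selected)
})

test_that("features with missing values are excluded before selection", {
  tab <- make_table(n = 60, p = 20, n_signal = 2, seed = 12)
  tab$x[3, "f010"] <- NA
  expect_message(s <- select_features(tab, n_iterations = 10), "missing")
  expect_false("f010" %in% s$candidates)
  expect_equal(s$n_features_in, 19)
})
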