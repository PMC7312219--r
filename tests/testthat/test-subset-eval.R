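# Stratified CV, confusion metrics, and the portfolio fitness oracle.

test_that("stratified folds partition instances with exact balance", {
  labels <- rep(c(0L, 1L), each = 80)
  f <- stratified_folds(labels, k = 10, seed = 1)
  expect_equal(attr(f, "k"), 10)
  tab <- table(f, labels)
  expect_true(all(tab == 8))
  expect_setequal(unique(f), 1:10)
  expect_length(f, 160)                       # every instance exactly once
})

test_that("fold count drops to the smaller class size when needed", {
  labels <- c(rep(0L, 30), rep(1L, 9))
  f <- stratified_folds(labels, k = 10, seed = 1)
  expect_equal(attr(f, "k"), 9)
  expect_error(stratified_folds(c(0L, 1L, 0L), k = 5), "at least 2")
})

test_that("confusion metrics match hand counts and flag absent classes", {
  y <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  expect_equal(confusion_metrics(y, y),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  all_pos <- confusion_metrics(y, rep(1L, 8))
  expect_equal(all_pos$accuracy, 0.5)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  # TP=3, FN=1, TN=2, FP=2
  yt <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  yp <- c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L)
  m <- confusion_metrics(yt, yp)
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  no_pos <- confusion_metrics(rep(0L, 4), rep(0L, 4))
  expect_true(is.na(no_pos$sensitivity))
  expect_equal(no_pos$specificity, 1)
})

test_that("well-separated clouds score accuracy 1; structure is respected", {
  ft <- gaussian_table(80, C = 3, informative = 1, delta = 6, seed = 2)
  sc <- evaluate_subset(ft, 1, portfolio_spec(n_trees = 25), k = 10,
                        seed = 1)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)
  expect_equal(sc$accuracy, max(unlist(sc$per_family_accuracies)))
  # fold-seed stability on the separable case
  sc2 <- evaluate_subset(ft, 1, portfolio_spec(n_trees = 25), k = 10,
                         seed = 99)
  expect_lte(abs(sc$accuracy - sc2$accuracy), 0.1)
})

test_that("permuted labels stay within chance-level bounds at n = 200", {
  ft <- gaussian_table(100, C = 3, informative = 1, delta = 0, seed = 4)
  for (s in 1:3) {
    ft2 <- ft
    ft2$labels <- eegselect:::with_seed(100 + s, sample(ft$labels))
    acc <- evaluate_subset(ft2, 2, portfolio_spec(n_trees = 25), k = 10,
                           seed = 1)$accuracy
    expect_gte(acc, 0.35)
    expect_lte(acc, 0.65)
  }
})

test_that("evaluate_subset is deterministic and validates its inputs", {
  ft <- gaussian_table(20, C = 3, informative = 1, delta = 1, seed = 6)
  s1 <- evaluate_subset(ft, c(1, 2), k = 5, seed = 3)
  s2 <- evaluate_subset(ft, c(1, 2), k = 5, seed = 3)
  expect_identical(s1, s2)
  expect_gte(s1$accuracy, 0)
  expect_lte(s1$accuracy, 1)
  expect_error(evaluate_subset(ft, integer(0)), "empty")
  expect_error(evaluate_subset(ft, 7), "montage")
})

test_that("informative channels outscore noise channels by >= 0.2", {
  gaps <- vapply(1:5, function(s) {
    ft <- planted_table(seed = s, n_per_class = 20, snr = 3)
    pf <- portfolio_spec(n_trees = 25)
    evaluate_subset(ft, 2, pf, k = 10, seed = 1)$accuracy -
      evaluate_subset(ft, 4, pf, k = 10, seed = 1)$accuracy
  }, 0)
  expect_gte(mean(gaps), 0.2)
})

test_that("the memoizing evaluator caches by subset", {
  ft <- gaussian_table(20, C = 3, informative = 1, delta = 2, seed = 6)
  ev <- make_evaluator(ft, portfolio_spec(n_trees = 25), k = 5, seed = 1)
  a <- ev(c(1, 3))
  b <- ev(c(3, 1))               # same subset, different order
  expect_identical(a, b)
  st <- attr(ev, "stats")()
  expect_equal(st$calls, 2L)
  expect_equal(st$distinct, 1L)
})
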