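# Operating-point calibration and (nested) cross-validation.

test_that("cutoff_for_sensitivity picks the most specific qualifying threshold", {
  s <- c(0.9, 0.8, 0.7, 0.4); l <- c(1, 1, 1, 0)
  expect_equal(cutoff_for_sensitivity(s, l, 1.0), 0.7)
  expect_equal(cutoff_for_sensitivity(s, l, 2 / 3), 0.8)
  expect_equal(cutoff_for_sensitivity(c(1, 1, 0.2), c(1, 1, 0), 0.5), 1.0)
  expect_error(cutoff_for_sensitivity(s, l, 0), "target")
  expect_error(cutoff_for_sensitivity(s, l, 1.2), "target")
  expect_error(cutoff_for_sensitivity(s, c(0, 0, 0, 0), 0.5), "positive")
})

test_that("cutoff calibration agrees with exhaustive threshold enumeration", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), sample(1:3, 1))  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (!any(labels == 1)) labels[1] <- 1
    target <- runif(1, 0.05, 1)
    expect_identical(cutoff_for_sensitivity(scores, labels, target),
                     oracle_cutoff(scores, labels, target))
  }
})

test_that("weight calibration returns the smallest qualifying grid weight", {
  # stub trainer with sensitivity exactly 1 - 1/(1+w) at cut-off 0.5
  n_pos <- 2520
  labels <- c(rep(1, n_pos), rep(0, 100))
  trainer <- function(w) {
    k <- round(n_pos * (1 - 1 / (1 + w)))
    c(rep(1, k), rep(0, n_pos - k), rep(0, 100))
  }
  op <- weight_for_sensitivity(trainer, labels, target = 0.9)
  expect_s3_class(op, "operating_point")
  expect_equal(op$positive_weight, 9)
  expect_gte(op$achieved_sensitivity, 0.9)
  # target met already at weight 1
  op1 <- weight_for_sensitivity(trainer, labels, target = 0.5)
  expect_equal(op1$positive_weight, 1)
  # unreachable target carries the best achieved value
  err <- tryCatch(weight_for_sensitivity(trainer, labels, target = 0.99),
                  calibration_failure = function(e) e)
  expect_s3_class(err, "calibration_failure")
  expect_equal(err$best_achieved, 1 - 1 / 21, tolerance = 1e-3)
})

test_that("achieved sensitivity meets the target on synthetic scores", {
  co <- small_cohort()
  X <- build_design(co); y <- co$ebus_positive
  folds <- assign_folds(nrow(X), 3, 5, seed = 2)
  trainer <- function(w) nested_cv_scores(logistic_trainer(w), X, y, folds)
  op <- weight_for_sensitivity(trainer, y, target = 0.9,
                               weight_grid = c(1, 3, 9, 20))
  expect_gte(op$achieved_sensitivity, 0.9)
})

test_that("outer folds are near-equal partitions, inner samples random", {
  fa <- assign_folds(9, 3, 2, seed = 1)
  expect_equal(as.integer(table(fa$outer)), rep(3L, 3))
  fa10 <- assign_folds(10, 3, 3, seed = 1)
  expect_equal(sort(as.integer(table(fa10$outer))), c(3L, 3L, 4L))
  # outer folds partition the records
  expect_equal(sum(table(fa10$outer)), 10)
  # inner ids exist exactly on the outer training sets
  for (j in 1:3) {
    expect_true(all(is.na(fa10$inner[fa10$outer == j, j])))
    expect_true(all(!is.na(fa10$inner[fa10$outer != j, j])))
  }
  expect_identical(assign_folds(50, 3, 5, seed = 7),
                   assign_folds(50, 3, 5, seed = 7))
  expect_error(assign_folds(10, 3, 5), "n >= k")
})

test_that("a data-independent trainer reduces nested CV to plain k-fold scoring", {
  set.seed(33)
  X <- cbind(intercept = 1, x = rnorm(60))
  y <- rbinom(60, 1, plogis(X[, "x"]))
  fixed_scorer <- function(nX) plogis(as.matrix(nX)[, "x"])
  trainer <- function(Xs, ys) fixed_scorer
  fa <- assign_folds(60, 3, 4, seed = 5)
  expect_equal(nested_cv_scores(trainer, X, y, fa), fixed_scorer(X))
})

test_that("inner selection is sensitivity-first", {
  set.seed(34)
  X <- cbind(intercept = 1, x = rnorm(60))
  y <- rbinom(60, 1, 0.5)
  # candidates alternate: constant-0 scorer (sens 0, spec 1) then
  # constant-1 scorer (sens 1, spec 0); the sensitive one must win
  calls <- 0L
  trainer <- function(Xs, ys) {
    calls <<- calls + 1L
    if (calls %% 2L == 1L) function(nX) rep(0, nrow(as.matrix(nX)))
    else function(nX) rep(1, nrow(as.matrix(nX)))
  }
  fa <- assign_folds(60, 3, 4, seed = 6)
  expect_equal(nested_cv_scores(trainer, X, y, fa), rep(1, 60))
})

test_that("every record is scored once, out of fold, deterministically", {
  co <- small_cohort()
  X <- build_design(co)[1:150, ]
  y <- co$ebus_positive[1:150]
  fa <- assign_folds(150, 3, 5, seed = 8)
  trainer <- function(Xs, ys) {
    fit_probabilistic_backend("tree_ensemble", Xs, ys, seed = 8,
                              hyperparams = list(num_trees = 50))
  }
  s1 <- nested_cv_scores(trainer, X, y, fa)
  s2 <- nested_cv_scores(trainer, X, y, fa)
  expect_identical(s1, s2)
  expect_false(anyNA(s1))
})

test_that("raising the target sensitivity never raises specificity", {
  co <- small_cohort()
  X <- build_design(co); y <- co$ebus_positive
  folds <- assign_folds(nrow(X), 3, 5, seed = 3)
  scores <- nested_cv_scores(logistic_trainer(9), X, y, folds)
  specs <- vapply(c(0.945, 0.979, 0.993), function(tg) {
    cut <- cutoff_for_sensitivity(scores, y, tg)
    mean(scores[y == 0] < cut)
  }, numeric(1))
  expect_true(all(diff(specs) <= 0))
})
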