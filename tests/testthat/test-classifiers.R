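# Design encoding, case weights, the IRLS logistic and its Wald tests.

test_that("build_design uses echelon-1 reference coding with interactions", {
  co <- tiny_cohort()
  X <- build_design(co)
  expect_identical(colnames(X)[1:8],
                   c("intercept", "suv_max", "ct_sd", "suv_max_primary",
                     "ech2", "ech3", "suv_x_ech2", "suv_x_ech3"))
  # echelon-1 row: all echelon and interaction columns zero
  expect_equal(unname(X[1, c("ech2", "ech3", "suv_x_ech2", "suv_x_ech3")]),
               c(0, 0, 0, 0))
  # echelon-2 row with suv 4.2
  expect_equal(unname(X[2, c("ech2", "ech3", "suv_x_ech2", "suv_x_ech3")]),
               c(1, 0, 4.2, 0))
  # echelon-3 row with suv 2.1
  expect_equal(unname(X[3, c("ech2", "ech3", "suv_x_ech2", "suv_x_ech3")]),
               c(0, 1, 0, 2.1))
})

test_that("case weights normalise to the sample size", {
  w <- make_weights(c(1, 0), 9)
  expect_equal(w$raw, c(9, 1))
  expect_equal(w$normalised, c(1.8, 0.2))
  expect_equal(make_weights(c(1, 0, 1), 1)$normalised, c(1, 1, 1))
  # a constant weight cancels in the normalisation
  expect_equal(make_weights(c(1, 1, 1), 9)$normalised, c(1, 1, 1))
  expect_equal(sum(make_weights(rbinom(50, 1, 0.4), 7)$normalised), 50)
  expect_error(make_weights(c(1, 0), 0), "positive_weight")
})

test_that("intercept-only fits have the closed-form weighted logit", {
  X <- matrix(1, 4, 1, dimnames = list(NULL, "intercept"))
  y <- c(1, 1, 1, 0)
  expect_equal(unname(fit_weighted_logistic(X, y)$coefficients),
               log(3), tolerance = 1e-8)
  m2 <- fit_weighted_logistic(X, y, make_weights(y, 2))
  expect_equal(unname(m2$coefficients), log(6), tolerance = 1e-8)
})

test_that("IRLS agrees with an independent likelihood maximiser", {
  set.seed(10)
  for (rep in 1:4) {
    n <- sample(c(60, 200, 500), 1)
    X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n),
               x3 = rbinom(n, 1, 0.4))
    eta <- -0.3 + 0.8 * X[, "x1"] - 0.5 * X[, "x2"] + 0.7 * X[, "x3"]
    y <- rbinom(n, 1, plogis(eta))
    w <- make_weights(y, sample(c(1, 3, 9), 1))
    fit <- fit_weighted_logistic(X, y, w)
    ref <- oracle_logistic(X, y, w$normalised)
    expect_equal(unname(fit$coefficients), ref, tolerance = 1e-6)
  }
})

test_that("uniform weights reproduce the standard glm fit", {
  set.seed(11)
  n <- 300
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = runif(n))
  y <- rbinom(n, 1, plogis(0.5 * X[, "x1"]))
  fit <- fit_weighted_logistic(X, y)
  ref <- glm.fit(X, y, family = binomial())
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
})

test_that("complete separation is reported, not returned", {
  X <- cbind(intercept = 1, x = c(-2, -1, 1, 2, 3, 4))
  y <- c(0, 0, 1, 1, 1, 1)
  expect_error(fit_weighted_logistic(X, y), "separation")
})

test_that("rank-deficient designs are rejected", {
  X <- cbind(intercept = 1, x = c(1, 2, 3, 4), x2 = c(2, 4, 6, 8))
  expect_error(fit_weighted_logistic(X, c(0, 1, 0, 1)), "singular")
})

test_that("predicted probabilities follow the inverse logit", {
  X <- matrix(1, 1, 1, dimnames = list(NULL, "intercept"))
  m <- fit_weighted_logistic(rbind(X, X, X, X), c(1, 1, 1, 0))
  expect_equal(predict_prob(m, X), 0.75, tolerance = 1e-7)
  m0 <- m; m0$coefficients[] <- 0
  expect_equal(predict_prob(m0, X), 0.5)
  # monotone in a positively weighted covariate
  set.seed(3)
  co <- small_cohort()
  Xd <- build_design(co)
  fit <- fit_weighted_logistic(Xd, co$ebus_positive)
  row <- Xd[1, ]
  suvs <- seq(1, 20, by = 0.5)
  probs <- vapply(suvs, function(s) {
    r <- row; r["suv_max"] <- s
    predict_prob(fit, matrix(r, 1, dimnames = list(NULL, names(row))))
  }, numeric(1))
  expect_true(all(diff(probs) >= 0))
})

test_that("raising the positive weight raises the implied positive rate", {
  set.seed(4)
  X <- matrix(1, 100, 1, dimnames = list(NULL, "intercept"))
  y <- rbinom(100, 1, 0.3)
  rates <- vapply(c(1, 2, 4, 8), function(w) {
    plogis(fit_weighted_logistic(X, y, make_weights(y, w))$coefficients)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("Wald tests cover single and joint terms", {
  # hand-built model: beta/se = 2 gives chi-square 4
  m <- structure(list(coefficients = c(a = 0.8, b = 0),
                      vcov = diag(c(0.16, 1)), converged = TRUE),
                 class = "wlogit")
  dimnames(m$vcov) <- list(c("a", "b"), c("a", "b"))
  wt <- wald_tests(m, terms = list(a = "a", b = "b"))
  expect_equal(wt$chisq[wt$term == "a"], 4)
  expect_equal(wt$p[wt$term == "a"], pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(wt$p[wt$term == "a"], 0.0455, tolerance = 1e-3)
  expect_equal(wt$chisq[wt$term == "b"], 0)
  expect_equal(wt$p[wt$term == "b"], 1)

  # joint 2-df Wald against a likelihood-ratio oracle on a simulated fit
  set.seed(5)
  n <- 500
  X <- cbind(intercept = 1, f1 = rbinom(n, 1, 0.5), f2 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.2 + 0.5 * X[, "f1"] + 0.3 * X[, "f2"]))
  fit <- fit_weighted_logistic(X, y)
  wt <- wald_tests(fit, terms = list(pair = c("f1", "f2")))
  lr <- 2 * (fit$loglik -
               fit_weighted_logistic(X[, "intercept", drop = FALSE], y)$loglik)
  expect_equal(wt$df[1], 2L)
  expect_equal(wt$chisq[1], lr, tolerance = 0.2)
})

test_that("logistic models round-trip through the text serialisation", {
  co <- small_cohort()
  fit <- fit_weighted_logistic(build_design(co), co$ebus_positive,
                               make_weights(co$ebus_positive, 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  save_logistic_model(fit, f)
  back <- load_logistic_model(f)
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$converged, fit$converged)
  X1 <- build_design(co)[1:5, ]
  expect_identical(predict_prob(back, X1), predict_prob(fit, X1))
})

test_that("coefficient signs on default synthetic cohorts match the model regime", {
  co <- small_cohort()
  fit <- fit_weighted_logistic(build_design(co), co$ebus_positive,
                               make_weights(co$ebus_positive, 9))
  expect_gt(fit$coefficients[["suv_max"]], 0)
  expect_gt(fit$coefficients[["ct_sd"]], 0)
  expect_lt(fit$coefficients[["suv_max_primary"]], 0)
})
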