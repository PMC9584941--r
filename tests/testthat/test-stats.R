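# Confusion metrics, weighted McNemar, Fisher, Kruskal-Wallis, AUC and the
# log-SUV linear models.

test_that("confusion tallies the standard 2x2 table", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  cc2 <- confusion(c(1, 0), c(1, 0))
  expect_equal(cc2$fp + cc2$fn, 0)
  expect_error(confusion(numeric(), numeric()), "empty")
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("metrics reproduce the published operating points", {
  # expert rater: 275/102/16/282 over 675 nodes
  m <- metrics(nodalpet:::.as_confusion(275, 102, 16, 282))
  expect_equal(round(m$sensitivity, 3), 0.945)
  expect_equal(round(m$specificity, 3), 0.734)
  expect_equal(round(m$mcr, 4), 0.1748)
  # fixed SUV 2.5 threshold: 282/188/9/196
  m2 <- metrics(nodalpet:::.as_confusion(282, 188, 9, 196))
  expect_equal(round(m2$sensitivity, 3), 0.969)
  expect_equal(round(m2$specificity, 3), 0.510)
  expect_equal(round(m2$mcr, 4), 0.2919)
  # perfect classifier
  m3 <- metrics(nodalpet:::.as_confusion(5, 0, 0, 5))
  expect_equal(unlist(m3), c(sensitivity = 1, specificity = 1, mcr = 0,
                             fdr = 0))
  # undefined metrics are markers, not errors
  expect_true(is.na(metrics(nodalpet:::.as_confusion(0, 0, 0, 4))$sensitivity))
})

test_that("confusion tables reconstruct from MCR and FN counts", {
  cc <- reconstruct_confusion(0.1333, 16, 675, 291)
  expect_equal(cc$tp, 275)
  expect_equal(cc$fp, 74)
  expect_equal(cc$tp + cc$fp, 349)  # called positive by the classifier
  cc2 <- reconstruct_confusion(0.2978, 2, 675, 291)
  expect_equal(cc2$tp, 289)
  expect_equal(cc2$fp, 199)
  expect_equal(cc2$tp + cc2$fp, 488)
  cc3 <- reconstruct_confusion(0, 0, 20, 8)
  expect_equal(cc3$fp + cc3$fn, 0)
  expect_error(reconstruct_confusion(0.9, 0, 100, 95), "negative|inconsistent")
})

test_that("reconstruction round-trips a genuine tally", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    labels <- rbinom(n, 1, 0.4)
    calls <- ifelse(runif(n) < 0.8, labels, 1 - labels)
    cc <- confusion(labels, calls)
    m <- metrics(cc)
    back <- reconstruct_confusion(m$mcr, cc$fn, cc$n, sum(labels))
    expect_equal(unclass(back), unclass(cc))
  }
})

test_that("weighted exact McNemar matches hand arithmetic and the oracle", {
  # one A-only vs five B-only discordant pairs at weight 1
  labels <- rep(1, 10)
  calls_a <- c(1, 0, 0, 0, 0, 0, 1, 1, 1, 1)
  calls_b <- c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  res <- mcnemar_exact_weighted(calls_a, calls_b, labels, 1)
  expect_equal(res$b_star, 1)
  expect_equal(res$c_star, 5)
  expect_equal(res$p_value, 2 * (choose(6, 0) + choose(6, 1)) / 2^6)
  expect_equal(res$p_value, 0.21875)
  # symmetric discordance -> p = 1 at any weight
  for (w in c(1, 9, 20)) {
    r <- mcnemar_exact_weighted(c(1, 0, 1, 0), c(0, 1, 1, 0),
                                c(1, 1, 1, 0), w)
    expect_equal(r$p_value, 1)
  }
  # zero discordance flag
  r0 <- mcnemar_exact_weighted(c(1, 0), c(1, 0), c(1, 0), 9)
  expect_true(r0$zero_discordance)
  expect_equal(r0$p_value, 1)
})

test_that("weight 1 recovers the classical exact McNemar on random instances", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    labels <- rbinom(n, 1, 0.5)
    calls_a <- ifelse(runif(n) < 0.7, labels, 1 - labels)
    calls_b <- ifelse(runif(n) < 0.7, labels, 1 - labels)
    res <- mcnemar_exact_weighted(calls_a, calls_b, labels, 1)
    b <- sum(calls_a == labels & calls_b != labels)
    cc <- sum(calls_a != labels & calls_b == labels)
    expect_equal(res$p_value, oracle_mcnemar_p(b, cc))
  }
})

test_that("weighting shifts discordance mass toward label-1 records", {
  labels <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  calls_a <- c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0)  # misses both positives
  calls_b <- labels                            # perfect
  p1 <- mcnemar_exact_weighted(calls_a, calls_b, labels, 1)$p_value
  p9 <- mcnemar_exact_weighted(calls_a, calls_b, labels, 9)$p_value
  expect_lt(p9, p1)
})

test_that("the weighted McNemar holds its size under a null simulation", {
  set.seed(43)
  n <- 100
  rejections <- vapply(1:2000, function(r) {
    labels <- rbinom(n, 1, 0.45)
    calls_a <- ifelse(runif(n) < 0.8, labels, 1 - labels)
    calls_b <- ifelse(runif(n) < 0.8, labels, 1 - labels)
    mcnemar_exact_weighted(calls_a, calls_b, labels, 1)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.06)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1)  # zero margin
  set.seed(44)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) > 40 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis H matches rank arithmetic and is rank-invariant", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-10)
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1)
  # monotone transformation leaves H unchanged
  kw2 <- kruskal_wallis(exp(c(1, 2, 3, 4, 5, 6)), rep(c("a", "b"), each = 3))
  expect_equal(kw2$H, kw$H)
  # hand-rolled tie-corrected oracle on random data
  set.seed(45)
  for (rep in 1:20) {
    g <- sample(1:3, 60, replace = TRUE)
    x <- round(rnorm(60), 1)
    r <- rank(x)
    n <- 60
    Rj <- tapply(r, g, sum); nj <- tapply(r, g, length)
    H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
    ties <- table(x)
    H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
    expect_equal(kruskal_wallis(x, g)$H, H, tolerance = 1e-10)
  }
  expect_equal(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))$p, 1)
})

test_that("AUC equals pairwise counting with half credit for ties", {
  expect_equal(auc_with_ci(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  set.seed(46)
  for (rep in 1:10) {
    n <- sample(c(50, 200, 500), 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    res <- auc_with_ci(scores, labels)
    expect_equal(res$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_true(res$ci_lower >= 0 && res$ci_upper <= 1)
    expect_true(res$ci_lower <= res$auc && res$auc <= res$ci_upper)
  }
  # null scores give AUC near 1/2
  set.seed(47)
  null <- auc_with_ci(runif(4000), rbinom(4000, 1, 0.5))
  expect_equal(null$auc, 0.5, tolerance = 0.03)
  expect_true(is.na(auc_with_ci(1:4, rep(1, 4))$auc))
})

test_that("paired AUC comparison is symmetric and null-calibrated", {
  set.seed(48)
  n <- 300
  labels <- rbinom(n, 1, 0.45)
  sa <- labels + rnorm(n)
  sb <- labels + rnorm(n)
  expect_equal(compare_auc_paired(sa, sa, labels)$chisq, 0)
  expect_equal(compare_auc_paired(sa, sa, labels)$p, 1)
  ab <- compare_auc_paired(sa, sb, labels)
  ba <- compare_auc_paired(sb, sa, labels)
  expect_equal(ab$chisq, ba$chisq)
  expect_equal(ab$p, ba$p)
  # DeLong variance of the difference against a bootstrap estimate
  d_obs <- ab$auc_a - ab$auc_b
  var_delong <- d_obs^2 / ab$chisq
  boots <- vapply(1:2000, function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    oracle_auc(sa[idx], labels[idx]) - oracle_auc(sb[idx], labels[idx])
  }, numeric(1))
  expect_equal(var_delong, var(boots, na.rm = TRUE), tolerance = 0.25)
})

test_that("log-SUV models recover structure and report Type III F tests", {
  co <- small_cohort()
  fit <- fit_log_suv_model(co, form = "primary_covariance")
  expect_setequal(fit$f_tests$term, c("log_primary", "echelon"))
  expect_true(all(fit$f_tests$F >= 0))
  expect_true(fit$R > 0 && fit$R <= 1)
  # balanced two-level factor: F equals t^2 of the coefficient
  set.seed(49)
  df <- data.frame(
    patient_id = rep(sprintf("Q%02d", 1:20), each = 2),
    echelon = rep(c(1, 2), 20),
    suv_max = exp(1.5 + rep(c(0, -0.3), 20) + rnorm(40, 0, 0.3)),
    suv_max_primary = exp(rnorm(40, 2.6, 0.5)),
    short_diameter_cm = 1.5, conglomerate = 0, station4R_left_primary = 0,
    histology_adeno = 0, primary_right_sided = 1,
    largest_suv_echelon2 = 3, ebus_positive = 1, truth_positive = 1)
  fit2 <- fit_log_suv_model(as_cohort(df), form = "primary_covariance")
  tval <- fit2$echelon_effects[1, 1] / fit2$echelon_effects[1, 2]
  expect_equal(fit2$f_tests$F[fit2$f_tests$term == "echelon"], tval^2,
               tolerance = 1e-10)
  # intra-patient form runs and tests both class variables
  fit3 <- fit_log_suv_model(co, form = "intra_patient")
  expect_setequal(fit3$f_tests$term, c("patient", "echelon"))
  # unidentifiable: one node per patient
  one <- df[seq(1, 40, by = 2), ]
  one$echelon <- rep(c(1, 2), 10)
  expect_error(fit_log_suv_model(as_cohort(one), form = "intra_patient"),
               "unidentifiable")
})

test_that("FDR is non-decreasing in false positives at fixed true positives", {
  fdrs <- vapply(0:20, function(fp) {
    metrics(nodalpet:::.as_confusion(10, fp, 2, 30))$fdr
  }, numeric(1))
  expect_true(all(diff(fdrs) > 0))
})
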