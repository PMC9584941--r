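# Confusion metrics, weighted exact McNemar, Fisher exact, Kruskal-Wallis,
# DeLong AUC machinery and the log-SUV linear models.
#
# Confusion cells are kept real-valued so that expected (fractional) counts
# from the combined-test arithmetic flow through the same metric code.

#' Tally a 2x2 confusion table
#'
#' @param labels binary 0/1 reference labels.
#' @param calls binary 0/1 classifier calls, same length.
#' @return list of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (length(labels) != length(calls)) {
    stop("labels and calls differ in length", call. = FALSE)
  }
  stopifnot(all(labels %in% c(0, 1)), all(calls %in% c(0, 1)))
  structure(list(tp = sum(labels == 1 & calls == 1),
                 fp = sum(labels == 0 & calls == 1),
                 fn = sum(labels == 1 & calls == 0),
                 tn = sum(labels == 0 & calls == 0),
                 n = length(labels)),
            class = "confusion_counts")
}

.as_confusion <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn),
            class = "confusion_counts")
}

#' Sensitivity, specificity, misclassification and false discovery rate
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `mcr = (fp+fn)/n` and `fdr = fp/(fp+tp)` (false positives over all
#' positive calls).  A metric with a zero denominator is returned as `NA`
#' (undefined marker) rather than raising.
#'
#' @param cc a `confusion_counts` object (cells may be fractional).
#' @return list `sensitivity`, `specificity`, `mcr`, `fdr`.
#' @export
metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  list(sensitivity = safe_div(cc$tp, cc$tp + cc$fn),
       specificity = safe_div(cc$tn, cc$tn + cc$fp),
       mcr = safe_div(cc$fp + cc$fn, cc$n),
       fdr = safe_div(cc$fp, cc$fp + cc$tp))
}

#' Reconstruct a confusion table from a misclassification rate and FN count
#'
#' Inverts the published reporting format (misclassification rate plus the
#' number of false negatives, with known totals): the misclassified count is
#' `round(mcr * n)`, so `fp = round(mcr * n) - fn`, `tp = n_positive - fn`,
#' `tn = n - n_positive - fp`.
#'
#' @param mcr misclassification rate.
#' @param fn number of false negatives.
#' @param n total number of nodes.
#' @param n_positive number of reference-positive nodes.
#' @return a `confusion_counts` object.
#' @examples
#' # 94.5%-sensitivity operating point: MCR 0.1333, 16 FN, 675 nodes,
#' # 291 EBUS-positives -> 349 called positive
#' cc <- reconstruct_confusion(0.1333, 16, 675, 291)
#' cc$tp + cc$fp
#' @export
reconstruct_confusion <- function(mcr, fn, n, n_positive) {
  stopifnot(mcr >= 0, mcr <= 1, fn >= 0, n_positive <= n)
  mis <- round(mcr * n)
  if (mis < fn) stop("inconsistent inputs: round(mcr*n) < fn", call. = FALSE)
  fp <- mis - fn
  tp <- n_positive - fn
  tn <- n - n_positive - fp
  if (tp < 0 || tn < 0) {
    stop("inconsistent inputs: negative derived cell", call. = FALSE)
  }
  .as_confusion(tp, fp, fn, tn)
}

#' Weighted exact McNemar test for paired classifiers
#'
#' Compares two classifiers against the same reference labels.  Each record
#' where exactly one classifier is correct contributes to a discordant
#' count; records with reference label 1 carry weight `weight_mcn` and
#' label-0 records weight 1, so that missing a truly positive node can be
#' weighted more heavily than a false alarm.  Weights are normalised to sum
#' to the number of records over the whole sample, the weighted discordant
#' counts are rounded to the nearest integers, and the two-sided exact
#' binomial p-value `min(1, 2 P(Bin(b*+c*, 1/2) <= min(b*, c*)))` is
#' returned.  With `weight_mcn = 1` this is the classical exact McNemar
#' test.
#'
#' @param calls_a,calls_b binary 0/1 calls of the two classifiers.
#' @param labels binary 0/1 reference labels.
#' @param weight_mcn relative weight of label-1 records (> 0).
#' @return list of class `mcnemar_result`: weighted discordant counts
#'   `discordant_a_only` (A correct, B wrong) and `discordant_b_only`,
#'   rounded counts `b_star`, `c_star`, `weight_mcn`, `p_value`,
#'   `zero_discordance` flag.
#' @export
mcnemar_exact_weighted <- function(calls_a, calls_b, labels,
                                   weight_mcn = 1) {
  n <- length(labels)
  stopifnot(length(calls_a) == n, length(calls_b) == n, weight_mcn > 0,
            all(labels %in% c(0, 1)))
  w <- ifelse(labels == 1, weight_mcn, 1)
  w <- w * n / sum(w)
  ok_a <- calls_a == labels
  ok_b <- calls_b == labels
  b <- sum(w[ok_a & !ok_b])   # A correct only
  cc <- sum(w[!ok_a & ok_b])  # B correct only
  b_star <- round(b)
  c_star <- round(cc)
  m <- b_star + c_star
  if (m == 0) {
    p <- 1
  } else {
    p <- min(1, 2 * pbinom(min(b_star, c_star), m, 0.5))
  }
  structure(list(discordant_a_only = b, discordant_b_only = cc,
                 b_star = b_star, c_star = c_star,
                 weight_mcn = weight_mcn, p_value = p,
                 zero_discordance = (m == 0)),
            class = "mcnemar_result")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] (sum of hypergeometric
#' probabilities of tables, at fixed margins, no more probable than the
#' observed one).  A table with a zero margin carries no information and
#' returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}

#' Kruskal-Wallis rank test
#'
#' Wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-square reference with groups - 1 df).
#'
#' @param values numeric observations.
#' @param groups group membership, same length.
#' @return list `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' AUC with DeLong 95% Wald confidence interval
#'
#' Mann-Whitney AUC (ties get half credit) with the DeLong paired-components
#' variance estimator; the Wald interval `auc +/- 1.96 se` is clipped to
#' \[0, 1\].  Returns `NA` markers when only one class is present.
#'
#' @param scores numeric classifier scores.
#' @param labels binary 0/1 labels.
#' @return list `auc`, `se`, `ci_lower`, `ci_upper`.
#' @export
auc_with_ci <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    return(list(auc = NA_real_, se = NA_real_,
                ci_lower = NA_real_, ci_upper = NA_real_))
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  # a degenerate (perfectly separating) score set has DeLong variance 0
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  se <- sqrt(v)
  list(auc = a, se = se,
       ci_lower = max(0, a - qnorm(0.975) * se),
       ci_upper = min(1, a + qnorm(0.975) * se))
}

#' Paired DeLong comparison of two AUCs
#'
#' Chi-square test (1 df) of the difference between the AUCs of two score
#' sets on the same records: `chisq = (auc_a - auc_b)^2 / var(diff)` with
#' the DeLong paired variance.  A zero-variance contrast returns `NA`
#' markers.
#'
#' @param scores_a,scores_b score vectors on the same records.
#' @param labels binary 0/1 labels.
#' @return list `auc_a`, `auc_b`, `chisq`, `df`, `p`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  n <- length(labels)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  if (identical(scores_a, scores_b)) {
    return(list(auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)),
                chisq = 0, df = 1L, p = 1))
  }
  tt <- tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
    error = function(e) NULL)
  if (is.null(tt) || !is.finite(tt$statistic)) {
    return(list(auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)),
                chisq = NA_real_, df = 1L, p = NA_real_))
  }
  z <- as.numeric(tt$statistic)
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       chisq = z^2, df = 1L, p = tt$p.value)
}

#' Linear models for log SUVmax of involved nodes
#'
#' Two forms, both fitted to the involved nodes of a cohort (latent truth
#' when available, otherwise the EBUS result):
#'
#' * `primary_covariance`: `log(suv_max) ~ log(suv_max_primary) + echelon`,
#'   the covariance model whose slope quantifies how node uptake tracks the
#'   primary tumour and whose echelon effects capture the uptake decline
#'   along the drainage.
#' * `intra_patient`: `log(suv_max) ~ patient + echelon`, the within-patient
#'   analysis of variance of the uptake decline.
#'
#' Type III F tests are computed per term by refitting without that term's
#' columns (drop-last model comparison, equivalent under the reference
#' coding used).
#'
#' @param cohort an `ln_cohort`.
#' @param form `"primary_covariance"` or `"intra_patient"`.
#' @param use_truth use `truth_positive` to select involved nodes when the
#'   column is present (default), else `ebus_positive`.
#' @return list of class `log_suv_fit`: `form`, `coefficients` (matrix of
#'   estimate/se), `slope` (covariance form), `echelon_effects`, `f_tests`
#'   (data frame term/F/df1/df2/p), `R` (correlation of fitted and observed),
#'   `sigma`, `n`.
#' @export
fit_log_suv_model <- function(cohort,
                              form = c("primary_covariance", "intra_patient"),
                              use_truth = TRUE) {
  form <- match.arg(form)
  lab <- if (use_truth && "truth_positive" %in% names(cohort)) {
    cohort$truth_positive
  } else cohort$ebus_positive
  d <- cohort[lab == 1, , drop = FALSE]
  if (length(unique(d$echelon)) < 2L) {
    stop("need involved nodes on at least 2 echelons", call. = FALSE)
  }
  d <- data.frame(log_suv = log(d$suv_max),
                  log_primary = log(d$suv_max_primary),
                  echelon = factor(d$echelon),
                  patient = factor(d$patient_id))
  if (form == "primary_covariance") {
    full <- lm(log_suv ~ log_primary + echelon, data = d)
    terms_drop <- list(log_primary = log_suv ~ echelon,
                       echelon = log_suv ~ log_primary)
  } else {
    if (all(table(d$patient) == 1L)) {
      stop("intra-patient model unidentifiable: one node per patient",
           call. = FALSE)
    }
    full <- lm(log_suv ~ patient + echelon, data = d)
    if (any(is.na(coef(full)[grep("^echelon", names(coef(full)))]))) {
      stop("intra-patient model unidentifiable: echelon aliased with patient",
           call. = FALSE)
    }
    terms_drop <- list(patient = log_suv ~ echelon,
                       echelon = log_suv ~ patient)
  }
  f_tests <- do.call(rbind, lapply(names(terms_drop), function(nm) {
    red <- lm(terms_drop[[nm]], data = d)
    a <- anova(red, full)
    data.frame(term = nm, F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
               p = a$`Pr(>F)`[2], stringsAsFactors = FALSE)
  }))
  sm <- summary(full)
  cf <- sm$coefficients[, c("Estimate", "Std. Error"), drop = FALSE]
  ech_idx <- grep("^echelon", rownames(cf))
  structure(list(
    form = form,
    coefficients = cf,
    slope = if (form == "primary_covariance") {
      c(estimate = cf["log_primary", 1], se = cf["log_primary", 2])
    } else NULL,
    echelon_effects = cf[ech_idx, , drop = FALSE],
    f_tests = f_tests,
    R = sqrt(sm$r.squared),
    sigma = sm$sigma,
    n = nrow(d)
  ), class = "log_suv_fit")
}
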