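# Closed-form algebra of an OR-combined pair of diagnostic tests and the
# expected-error arithmetic at an assumed prevalence.  A node is deemed
# positive by the combined test if at least one component test is positive,
# so under independence the sensitivities compose as
# SE_ab = SE_a + SE_b - SE_a*SE_b and the specificities as SP_ab = SP_a*SP_b.

.check_prob <- function(x, nm) {
  if (!is.numeric(x) || any(x < 0 | x > 1)) {
    stop(nm, " must be a probability in [0, 1]", call. = FALSE)
  }
}

#' Sensitivity of an OR-combined test under independence
#'
#' @param se_a,se_b component sensitivities in \[0, 1\].
#' @return `se_a + se_b - se_a * se_b`.
#' @examples
#' combined_sensitivity(0.945, 0.85)  # 0.99175
#' @export
combined_sensitivity <- function(se_a, se_b) {
  .check_prob(se_a, "se_a"); .check_prob(se_b, "se_b")
  se_a + se_b - se_a * se_b
}

#' Specificity of an OR-combined test under independence
#'
#' @param sp_a,sp_b component specificities in \[0, 1\].
#' @return `sp_a * sp_b`.
#' @export
combined_specificity <- function(sp_a, sp_b) {
  .check_prob(sp_a, "sp_a"); .check_prob(sp_b, "sp_b")
  sp_a * sp_b
}

#' Back-calculated prevalence from observed test positives
#'
#' With an imperfect reference of known sensitivity, the number of truly
#' involved nodes is estimated as observed positives divided by that
#' sensitivity.
#'
#' @param n_observed_positive observed positive count (>= 0).
#' @param assumed_sensitivity sensitivity of the observing test (> 0).
#' @return list `prevalence` (real) and `prevalence_rounded` (integer
#'   companion).
#' @examples
#' prevalence_from_positives(291, 0.85)  # 342.35 -> 342
#' @export
prevalence_from_positives <- function(n_observed_positive,
                                      assumed_sensitivity) {
  stopifnot(n_observed_positive >= 0)
  .check_prob(assumed_sensitivity, "assumed_sensitivity")
  if (assumed_sensitivity == 0) {
    stop("assumed_sensitivity must be > 0", call. = FALSE)
  }
  p <- n_observed_positive / assumed_sensitivity
  list(prevalence = p, prevalence_rounded = round(p))
}

#' Expected error counts of a test at an assumed prevalence
#'
#' Given the prevalence of truly involved nodes, the test sensitivity and
#' the number of nodes the test calls positive:
#' `expected_fn = prevalence * (1 - sensitivity)`,
#' `expected_tp = prevalence - expected_fn`,
#' `expected_fp = n_called_positive - expected_tp` (floored at 0, with an
#' `inconsistent` flag when flooring was needed), and
#' `expected_misclassifications = expected_fp + expected_fn`.
#'
#' @param prevalence expected number of truly involved nodes (> 0).
#' @param sensitivity test sensitivity in \[0, 1\].
#' @param n_called_positive number of nodes called positive by the test.
#' @return list of class `combined_test_result`: `prevalence`,
#'   `sensitivity`, `n_called_positive`, `expected_fn`, `expected_tp`,
#'   `expected_fp`, `expected_misclassifications`, `inconsistent`.
#' @examples
#' # classifier (94.5%) OR EBUS (85%) at prevalence 342, 349 called positive
#' expected_errors(342, combined_sensitivity(0.945, 0.85), 349)
#' @export
expected_errors <- function(prevalence, sensitivity, n_called_positive) {
  stopifnot(prevalence > 0, n_called_positive >= 0)
  .check_prob(sensitivity, "sensitivity")
  fn <- prevalence * (1 - sensitivity)
  tp <- prevalence - fn
  fp_raw <- n_called_positive - tp
  fp <- max(0, fp_raw)
  structure(list(prevalence = prevalence, sensitivity = sensitivity,
                 n_called_positive = n_called_positive,
                 expected_fn = fn, expected_tp = tp, expected_fp = fp,
                 expected_misclassifications = fp + fn,
                 inconsistent = fp_raw < 0),
            class = "combined_test_result")
}

#' @export
print.combined_test_result <- function(x, ...) {
  cat(sprintf(
    "Combined-test expectation at prevalence %.1f (sensitivity %.1f%%):\n",
    x$prevalence, 100 * x$sensitivity))
  cat(sprintf("  expected FN %.1f, TP %.1f, FP %.1f; misclassifications %.1f\n",
              x$expected_fn, x$expected_tp, x$expected_fp,
              x$expected_misclassifications))
  if (x$inconsistent) cat("  (FP floored at 0: called positives < expected TP)\n")
  invisible(x)
}

#' Element-wise OR combination of binary calls
#'
#' @param calls_a,calls_b binary 0/1 vectors of equal length.
#' @return binary vector, positive where at least one input is positive.
#' @export
combine_calls <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length", call. = FALSE)
  }
  stopifnot(all(calls_a %in% c(0, 1)), all(calls_b %in% c(0, 1)))
  as.numeric(calls_a == 1 | calls_b == 1)
}

#' Full combined-test analysis of a classifier with EBUS-TBNA
#'
#' Composes the analytic chain: prevalence back-calculated from the observed
#' EBUS positives, combined sensitivity of classifier OR EBUS under
#' independence, and expected errors at that prevalence.  By default the
#' called-positive count is the classifier-alone positive count (the
#' printed-arithmetic convention); `augment_positives` adds the
#' EBUS-only positives to the called-positive bookkeeping instead.
#'
#' @param se_classifier classifier sensitivity.
#' @param ebus_sensitivity assumed EBUS-TBNA sensitivity.
#' @param n_observed_positive observed EBUS-positive nodes.
#' @param n_called_positive nodes called positive by the classifier alone.
#' @param extra_ebus_only_positives EBUS-positive, classifier-negative nodes
#'   to add when `augment_positives = TRUE`.
#' @param augment_positives include the EBUS-only positives in the
#'   called-positive count (default `FALSE`).
#' @return a `combined_test_result` with additional fields `se_combined` and
#'   `prevalence_rounded`.
#' @export
combined_test_analysis <- function(se_classifier, ebus_sensitivity,
                                   n_observed_positive, n_called_positive,
                                   extra_ebus_only_positives = 0,
                                   augment_positives = FALSE) {
  prev <- prevalence_from_positives(n_observed_positive, ebus_sensitivity)
  se_ab <- combined_sensitivity(se_classifier, ebus_sensitivity)
  n_called <- n_called_positive +
    if (augment_positives) extra_ebus_only_positives else 0
  res <- expected_errors(prev$prevalence_rounded, se_ab, n_called)
  res$se_combined <- se_ab
  res$prevalence_rounded <- prev$prevalence_rounded
  res
}
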