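# Operating-point calibration (case weights and probability cut-offs that
# hit a target sensitivity) and threefold / nested cross-validation with a
# sensitivity-first inner selection rule.

.sens_spec_at <- function(scores, labels, cutoff) {
  calls <- as.numeric(scores >= cutoff)
  pos <- labels == 1
  c(sensitivity = if (any(pos)) mean(calls[pos] == 1) else 0,
    specificity = if (any(!pos)) mean(calls[!pos] == 0) else 0)
}

#' Probability cut-off achieving a target sensitivity
#'
#' A score at or above the cut-off is called positive.  Returns the largest
#' observed score value `c` such that the sensitivity of the rule
#' `score >= c` is at least `target`; because sensitivity is non-increasing
#' in the cut-off this is the most specific operating point meeting the
#' target on the calibration sample.
#'
#' @param scores numeric classifier scores.
#' @param labels binary 0/1 reference labels; at least one positive.
#' @param target target sensitivity in (0, 1].
#' @return the cut-off value.
#' @examples
#' cutoff_for_sensitivity(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 1, 0), 1)    # 0.7
#' cutoff_for_sensitivity(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 1, 0), 2/3)  # 0.8
#' @export
cutoff_for_sensitivity <- function(scores, labels, target) {
  if (!is.numeric(target) || target <= 0 || target > 1) {
    stop("target sensitivity must be in (0, 1]", call. = FALSE)
  }
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (!any(labels == 1)) stop("no positive labels", call. = FALSE)
  pos_scores <- scores[labels == 1]
  for (c0 in sort(unique(scores), decreasing = TRUE)) {
    if (mean(pos_scores >= c0) >= target) return(c0)
  }
  min(scores)  # unreachable: the smallest score always gives sensitivity 1
}

#' Positive-class weight achieving a target sensitivity
#'
#' Walks an increasing weight grid and returns the smallest weight whose
#' (cross-validated) sensitivity at the fixed cut-off reaches the target.
#' The trainer is responsible for producing honest scores: it receives one
#' candidate weight and returns a score per record (typically out-of-fold
#' scores from [nested_cv_scores()] with that weight).
#'
#' @param trainer function of one argument (the positive-class weight)
#'   returning a numeric score vector aligned with `labels`.
#' @param labels binary 0/1 reference labels.
#' @param target target sensitivity in (0, 1].
#' @param cutoff fixed probability cut-off (default 0.5).
#' @param weight_grid increasing candidate weights (default 1..20, which
#'   covers the printed calibration weights 3 and 9).
#' @return list of class `operating_point`: `target_sensitivity`,
#'   `positive_weight`, `cutoff`, `achieved_sensitivity`,
#'   `achieved_specificity`.  If no grid weight reaches the target, an error
#'   of class `calibration_failure` carrying the best achieved sensitivity
#'   is raised.
#' @export
weight_for_sensitivity <- function(trainer, labels, target, cutoff = 0.5,
                                   weight_grid = 1:20) {
  if (!is.numeric(target) || target <= 0 || target > 1) {
    stop("target sensitivity must be in (0, 1]", call. = FALSE)
  }
  weight_grid <- sort(unique(weight_grid))
  best <- -Inf
  best_weight <- weight_grid[1L]
  for (w in weight_grid) {
    scores <- trainer(w)
    ss <- .sens_spec_at(scores, labels, cutoff)
    if (ss[["sensitivity"]] >= target) {
      return(structure(list(target_sensitivity = target,
                            positive_weight = w, cutoff = cutoff,
                            achieved_sensitivity = ss[["sensitivity"]],
                            achieved_specificity = ss[["specificity"]]),
                       class = "operating_point"))
    }
    if (ss[["sensitivity"]] > best) {
      best <- ss[["sensitivity"]]
      best_weight <- w
    }
  }
  stop(structure(class = c("calibration_failure", "error", "condition"),
                 list(message = sprintf(
                   "no weight in grid reaches sensitivity %.4g (best %.4g at weight %g)",
                   target, best, best_weight),
                   call = sys.call(-1), best_achieved = best,
                   best_weight = best_weight)))
}

#' Outer folds and inner random samples for nested cross-validation
#'
#' Outer assignment: each record gets a uniform random key; sorting the keys
#' splits the records into `k` contiguous blocks of near-equal size (sizes
#' differ by at most one).  Inner assignment: within each outer training
#' set, records are assigned independently and uniformly to one of `m`
#' samples, so inner-sample sizes are random.  Everything is deterministic
#' given the seed.
#'
#' @param n number of records (`n >= k * m`).
#' @param k number of outer folds (default 3).
#' @param m number of inner samples (default 5).
#' @param seed integer seed.
#' @return list of class `fold_assignment`: `outer` (fold id per record),
#'   `inner` (n-by-k matrix; entry \[i, j\] is record i's inner-sample id
#'   within outer training set j, `NA` when record i lies in fold j), `k`,
#'   `m`, `seed`.
#' @export
assign_folds <- function(n, k = 3L, m = 5L, seed = 1L) {
  stopifnot(n >= k * m, k >= 2L, m >= 1L)
  set.seed(seed)
  key <- runif(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  outer <- integer(n)
  outer[order(key)] <- rep(seq_len(k), times = sizes)
  inner <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    tr <- which(outer != j)
    inner[tr, j] <- sample.int(m, length(tr), replace = TRUE)
  }
  structure(list(outer = outer, inner = inner, k = k, m = m, seed = seed),
            class = "fold_assignment")
}

#' Out-of-fold scores by nested cross-validation
#'
#' For each outer fold, `m` candidate models are trained, each on the other
#' `m - 1` inner samples of the outer training set.  Candidates are ranked
#' on their own training data at the fixed cut-off, by highest sensitivity
#' first and highest specificity second, ties broken by the lowest
#' inner-sample id; the winner scores the held-out outer fold.  Every record
#' thus receives exactly one score from a model that never saw it.
#'
#' If an inner sample of a fold turns out empty, that fold's inner
#' assignment is redrawn with an incremented seed (reported via `message`).
#'
#' @param trainer function `(X, y) -> scorer`, where the scorer maps a
#'   design matrix to probabilities (see [fit_probabilistic_backend()]; for
#'   the weighted logistic use a closure around [fit_weighted_logistic()]).
#' @param X design matrix.
#' @param y binary 0/1 labels.
#' @param assignment a [assign_folds()] result for `nrow(X)` records.
#' @param cutoff probability cut-off used by the inner selection rule.
#' @return numeric vector of out-of-fold scores, one per record.
#' @export
nested_cv_scores <- function(trainer, X, y, assignment, cutoff = 0.5) {
  stopifnot(inherits(assignment, "fold_assignment"),
            nrow(X) == length(y), length(assignment$outer) == length(y))
  X <- as.matrix(X)
  scores <- rep(NA_real_, length(y))
  for (j in seq_len(assignment$k)) {
    tr <- which(assignment$outer != j)
    te <- which(assignment$outer == j)
    inner <- assignment$inner[tr, j]
    bump <- 0L
    while (length(unique(inner)) < assignment$m) {
      bump <- bump + 1L
      message("fold ", j, ": empty inner sample, redrawing (attempt ",
              bump, ")")
      set.seed(assignment$seed + bump * assignment$k + j)
      inner <- sample.int(assignment$m, length(tr), replace = TRUE)
    }
    best <- NULL
    best_key <- c(-Inf, -Inf)
    for (s in seq_len(assignment$m)) {
      fit_idx <- tr[inner != s]
      scorer <- trainer(X[fit_idx, , drop = FALSE], y[fit_idx])
      ss <- .sens_spec_at(scorer(X[fit_idx, , drop = FALSE]), y[fit_idx],
                          cutoff)
      key <- c(ss[["sensitivity"]], ss[["specificity"]])
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best <- scorer
        best_key <- key
      }
    }
    scores[te] <- best(X[te, , drop = FALSE])
  }
  scores
}
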