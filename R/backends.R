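# Probabilistic classifier backends behind a common scorer contract:
# a scorer is a function mapping a design matrix to probabilities in [0,1],
# with the fitted backend attached as an attribute.

.strip_intercept <- function(X) {
  X <- as.matrix(X)
  keep <- !(colnames(X) %in% "intercept")
  X[, keep, drop = FALSE]
}

#' Fit a tree-ensemble or feed-forward classifier backend
#'
#' Both backends return a scorer: a function mapping a design matrix (as
#' from [build_design()]; an intercept column is ignored) to predicted
#' probabilities of EBUS-positivity in \[0, 1\].  The seed fixes the fit, so
#' identical calls give identical scores.
#'
#' * `tree_ensemble`: a probability random forest ([ranger::ranger()],
#'   default 200 trees) with out-of-bag permutation importance retained for
#'   [variable_importance()].  Case weights are not used by this backend;
#'   its operating point is calibrated through the probability cut-off
#'   alone.
#' * `feedforward`: a single-hidden-layer perceptron ([nnet::nnet()],
#'   default 8 units, weight decay 0.01) trained on the cross-entropy loss;
#'   case weights are supported.
#'
#' Degenerate input with constant labels yields a constant scorer at the
#' observed label.
#'
#' @param kind `"tree_ensemble"` or `"feedforward"`.
#' @param X design matrix.
#' @param y binary 0/1 labels.
#' @param weights optional [make_weights()] object or numeric vector
#'   (ignored by the tree ensemble).
#' @param hyperparams named list; recognised entries `num_trees` (tree
#'   ensemble), `hidden_units`, `decay`, `maxit` (feed-forward).
#' @param seed integer seed.
#' @return a scorer function with attributes `kind` and `fit`.
#' @export
fit_probabilistic_backend <- function(kind = c("tree_ensemble", "feedforward"),
                                      X, y, weights = NULL,
                                      hyperparams = list(), seed = 1L) {
  kind <- match.arg(kind)
  X <- .strip_intercept(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) == 1L) {
    const <- unique(y)
    scorer <- function(newX) rep(const, nrow(as.matrix(newX)))
    attr(scorer, "kind") <- paste0(kind, "_constant")
    return(scorer)
  }
  w <- .as_weight_vector(weights, nrow(X))
  if (kind == "tree_ensemble") {
    df <- as.data.frame(X)
    df$.y <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = hyperparams$num_trees %||% 200L,
      max.depth = hyperparams$max_depth %||% NULL,
      importance = "permutation", seed = seed,
      num.threads = 1L
    )
    scorer <- function(newX) {
      newX <- .strip_intercept(newX)
      unname(predict(fit, data = as.data.frame(newX),
                     num.threads = 1L)$predictions[, "1"])
    }
  } else {
    set.seed(seed)
    fit <- nnet::nnet(x = X, y = y, weights = w,
                      size = hyperparams$hidden_units %||% 8L,
                      decay = hyperparams$decay %||% 0.01,
                      maxit = hyperparams$maxit %||% 500L,
                      entropy = TRUE, trace = FALSE)
    scorer <- function(newX) {
      newX <- .strip_intercept(newX)
      p <- as.numeric(predict(fit, newX))
      pmin(pmax(p, 0), 1)
    }
  }
  attr(scorer, "kind") <- kind
  attr(scorer, "fit") <- fit
  scorer
}

#' Variable importance of a fitted backend
#'
#' For the tree ensemble: the number of splitting rules using each input
#' variable (from the ensemble structure) and the out-of-bag permutation
#' loss reduction (which can be negative for uninformative variables).  For
#' backends without an introspectable structure, a permutation-importance
#' fallback on supplied data is used and flagged: each column is permuted 5
#' times and the mean increase in cross-entropy loss reported; split counts
#' are then `NA`.
#'
#' @param scorer a scorer from [fit_probabilistic_backend()].
#' @param X,y evaluation data, required for the permutation fallback.
#' @param seed seed for the permutation fallback.
#' @return data frame `variable`, `split_count`, `loss_reduction`, with
#'   attribute `method` (`"oob_permutation"` or `"permutation_fallback"`).
#' @export
variable_importance <- function(scorer, X = NULL, y = NULL, seed = 1L) {
  fit <- attr(scorer, "fit")
  if (inherits(fit, "ranger")) {
    vars <- names(fit$variable.importance)
    counts <- setNames(integer(length(vars)), vars)
    for (tr in seq_len(fit$num.trees)) {
      sv <- ranger::treeInfo(fit, tree = tr)$splitvarName
      tb <- table(sv[!is.na(sv)])
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
    out <- data.frame(variable = vars,
                      split_count = as.integer(counts),
                      loss_reduction = unname(fit$variable.importance),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$loss_reduction), ]
    rownames(out) <- NULL
    attr(out, "method") <- "oob_permutation"
    return(out)
  }
  if (is.null(X) || is.null(y)) {
    stop("permutation fallback requires X and y", call. = FALSE)
  }
  X <- .strip_intercept(X)
  set.seed(seed)
  eps <- 1e-12
  xent <- function(p) -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  base <- xent(scorer(X))
  loss <- vapply(colnames(X), function(cl) {
    mean(vapply(1:5, function(r) {
      Xp <- X
      Xp[, cl] <- sample(Xp[, cl])
      xent(scorer(Xp)) - base
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(variable = colnames(X),
                    split_count = NA_integer_,
                    loss_reduction = unname(loss),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$loss_reduction), ]
  rownames(out) <- NULL
  attr(out, "method") <- "permutation_fallback"
  out
}
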