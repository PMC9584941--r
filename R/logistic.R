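# Case-weighted logistic regression fitted by iteratively reweighted least
# squares.  Case weights implement the sensitivity calibration: EBUS-positive
# nodes receive weight > 1 against weight 1 for negatives, and the weights
# are normalised to sum to the sample size so that likelihood magnitudes
# and the Fisher information remain on the unweighted scale.

#' Case weights for sensitivity calibration
#'
#' Raw weight `positive_weight` for label-1 records and 1 for label-0
#' records, then normalised so the weights sum to the number of records.
#'
#' @param labels binary 0/1 vector.
#' @param positive_weight relative weight of positive records (> 0).
#' @return list of class `case_weights` with `raw` and `normalised` vectors.
#' @examples
#' make_weights(c(1, 0), 9)$normalised  # 1.8, 0.2
#' @export
make_weights <- function(labels, positive_weight) {
  if (!is.numeric(positive_weight) || positive_weight <= 0) {
    stop("positive_weight must be > 0", call. = FALSE)
  }
  stopifnot(length(labels) > 0L, all(labels %in% c(0, 1)))
  raw <- ifelse(labels == 1, positive_weight, 1)
  structure(list(raw = raw,
                 normalised = raw * length(labels) / sum(raw),
                 positive_weight = positive_weight),
            class = "case_weights")
}

.as_weight_vector <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "case_weights")) return(weights$normalised)
  stopifnot(is.numeric(weights), length(weights) == n, all(weights > 0))
  weights
}

.weighted_loglik <- function(beta, X, y, w) {
  eta <- drop(X %*% beta)
  # numerically stable log-likelihood via log1p(exp(.))
  sum(w * (y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))))
}

#' Weighted logistic regression via IRLS
#'
#' Maximises the case-weighted Bernoulli log-likelihood
#' `sum_i w_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` by iteratively
#' reweighted least squares with step-halving whenever a step decreases the
#' likelihood.  Convergence is declared when the largest coefficient change
#' falls below `tol`.  The covariance is the inverse of the weighted Fisher
#' information at the optimum.  Complete separation is detected when any
#' coefficient exceeds 30 on internally standardised inputs and raised as an
#' error, as is rank deficiency of the weighted design.
#'
#' @param X numeric design matrix (include an intercept column; see
#'   [build_design()]).
#' @param y binary 0/1 response.
#' @param weights `NULL` (unit weights), a [make_weights()] object, or a
#'   positive numeric vector.
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter maximum IRLS iterations.
#' @param on_separation `"error"` (default) raises on detected separation;
#'   `"saturate"` stops iterating at the divergence guard and returns the
#'   current finite coefficients (predictions then saturate towards 0/1),
#'   the behaviour wanted inside cross-validation loops where a separated
#'   subsample should still score its leave-out fold.
#' @return object of class `wlogit` with elements `coefficients`, `vcov`,
#'   `converged`, `separated`, `iterations`, `loglik`, `weights`.
#' @examples
#' X <- matrix(1, 4, 1, dimnames = list(NULL, "intercept"))
#' fit_weighted_logistic(X, c(1, 1, 1, 0))$coefficients  # log(3)
#' @export
fit_weighted_logistic <- function(X, y, weights = NULL,
                                  tol = 1e-8, max_iter = 100L,
                                  on_separation = c("error", "saturate")) {
  on_separation <- match.arg(on_separation)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  w <- .as_weight_vector(weights, nrow(X))
  p <- ncol(X)
  # scale used only for separation detection
  scale <- apply(X, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1

  beta <- rep(0, p)
  ll <- .weighted_loglik(beta, X, y, w)
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    wi <- w * mu * (1 - mu)
    wi <- pmax(wi, 1e-10)
    z <- eta + (y - mu) / (mu * (1 - mu) + 1e-10)
    qrW <- qr(X * sqrt(wi))
    if (qrW$rank < p) {
      stop("singular weighted design: rank ", qrW$rank, " < ", p,
         call. = FALSE)
    }
    beta_new <- qr.coef(qrW, sqrt(wi) * z)
    step <- beta_new - beta
    ll_new <- .weighted_loglik(beta_new, X, y, w)
    halvings <- 0L
    while (ll_new < ll && halvings < 30L) {
      step <- step / 2
      beta_new <- beta + step
      ll_new <- .weighted_loglik(beta_new, X, y, w)
      halvings <- halvings + 1L
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- ll_new
    if (any(abs(beta * scale) > 30)) {
      if (on_separation == "error") {
        stop("complete separation detected: coefficients diverging",
             call. = FALSE)
      }
      separated <- TRUE
      break
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  mu <- plogis(drop(X %*% beta))
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  V <- tryCatch(solve(info), error = function(e) {
    if (separated) return(matrix(NA_real_, p, p))
    stop("singular Fisher information at the optimum", call. = FALSE)
  })
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 vcov = V, converged = converged, separated = separated,
                 iterations = iter, loglik = ll, weights = w),
            class = "wlogit")
}

#' Cross-validation trainer for the weighted logistic classifier
#'
#' Convenience wrapper producing the `(X, y) -> scorer` closure expected by
#' [nested_cv_scores()]: each call fits the weighted logistic model on the
#' supplied subsample and returns a probability scorer.  Subsamples behave
#' worse than full data, so the trainer is deliberately robust: linearly
#' dependent (for example constant) columns of the subsample are dropped
#' before fitting, and a separated subsample saturates instead of failing,
#' so that it can still score its leave-out fold.
#'
#' @param positive_weight relative case weight of positive records.
#' @return a trainer function `(X, y) -> function(newX) -> probabilities`.
#' @export
logistic_trainer <- function(positive_weight = 1) {
  force(positive_weight)
  function(X, y) {
    X <- as.matrix(X)
    qx <- qr(X)
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    m <- fit_weighted_logistic(X[, keep, drop = FALSE], y,
                               make_weights(y, positive_weight),
                               on_separation = "saturate")
    function(newX) predict_prob(m, as.matrix(newX)[, keep, drop = FALSE])
  }
}

#' Predicted probability of EBUS-positivity
#'
#' @param model a fitted [fit_weighted_logistic()] model.
#' @param X design matrix (or single row) aligned to the model coefficients.
#' @return vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "wlogit"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients) && nrow(X) == length(model$coefficients)) {
    X <- t(X)
  }
  plogis(drop(X %*% model$coefficients))
}

#' @export
print.wlogit <- function(x, ...) {
  cat("Weighted logistic model (IRLS):",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coefficients, se = se), 4))
  invisible(x)
}

#' Serialise a fitted logistic model to a structured text file
#'
#' Tab-separated `coefficient<TAB>value` lines with full double precision,
#' preceded by `#`-prefixed header lines echoing the fit state (convergence,
#' iterations, log-likelihood).  [load_logistic_model()] restores a model
#' usable with [predict_prob()]; the covariance is not serialised.
#'
#' @param model a fitted [fit_weighted_logistic()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_logistic_model <- function(model, path) {
  stopifnot(inherits(model, "wlogit"))
  lines <- c(
    sprintf("# converged: %s", model$converged),
    sprintf("# separated: %s", isTRUE(model$separated)),
    sprintf("# iterations: %d", model$iterations),
    sprintf("# loglik: %.17g", model$loglik),
    sprintf("%s\t%.17g", names(model$coefficients), model$coefficients)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_logistic_model
#' @export
load_logistic_model <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  coefs <- setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(parts, `[`, character(1), 1))
  hdr <- function(key) sub(paste0("# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), lines, value = TRUE))
  structure(list(coefficients = coefs,
                 vcov = matrix(NA_real_, length(coefs), length(coefs)),
                 converged = identical(hdr("converged"), "TRUE"),
                 separated = identical(hdr("separated"), "TRUE"),
                 iterations = as.integer(hdr("iterations")),
                 loglik = as.numeric(hdr("loglik")), weights = NULL),
            class = "wlogit")
}

# default multi-column terms of the node-level model: the echelon main
# effect and the SUVmax-by-echelon interaction are tested jointly (2 df)
.default_term_groups <- function(cols) {
  groups <- list()
  if (all(c("ech2", "ech3") %in% cols)) {
    groups$echelon <- c("ech2", "ech3")
  }
  if (all(c("suv_x_ech2", "suv_x_ech3") %in% cols)) {
    groups$suv_x_echelon <- c("suv_x_ech2", "suv_x_ech3")
  }
  singles <- setdiff(cols, unlist(groups))
  for (s in singles) groups[[s]] <- s
  groups
}

#' Wald chi-square tests per model term
#'
#' Single-column terms are tested as `(beta / se)^2` on 1 df; multi-level
#' terms (the echelon dummies, the SUVmax-by-echelon interaction pair) are
#' tested jointly with `beta' V^{-1} beta` on as many df as component
#' columns.
#'
#' @param model a fitted [fit_weighted_logistic()] model.
#' @param terms named list mapping term names to coefficient-column names;
#'   default groups the echelon dummies and the interaction pair.
#' @return data frame with columns `term`, `chisq`, `df`, `p`.
#' @export
wald_tests <- function(model, terms = NULL) {
  stopifnot(inherits(model, "wlogit"))
  cols <- names(model$coefficients)
  if (is.null(terms)) terms <- .default_term_groups(cols)
  rows <- lapply(names(terms), function(nm) {
    idx <- match(terms[[nm]], cols)
    if (anyNA(idx)) stop("unknown coefficient in term '", nm, "'")
    b <- model$coefficients[idx]
    V <- model$vcov[idx, idx, drop = FALSE]
    chi <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) {
      stop("singular covariance for term '", nm, "'", call. = FALSE)
    })
    data.frame(term = nm, chisq = chi, df = length(idx),
               p = pchisq(chi, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
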