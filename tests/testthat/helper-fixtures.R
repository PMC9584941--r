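# Shared fixtures: tiny hand-written cohorts and stub trainers.

# three clean nodes over two patients
tiny_cohort <- function() {
  as_cohort(data.frame(
    patient_id = c("A", "A", "B"),
    echelon = c(1, 2, 3),
    suv_max = c(12.5, 4.2, 2.1),
    suv_max_primary = c(15.0, 15.0, 9.5),
    short_diameter_cm = c(2.1, 1.3, 0.8),
    conglomerate = c(0, 0, 0),
    station4R_left_primary = c(0, 0, 0),
    histology_adeno = c(1, 1, 0),
    primary_right_sided = c(1, 1, 0),
    largest_suv_echelon2 = c(4.2, 4.2, 1.9),
    ebus_positive = c(1, 1, 0),
    truth_positive = c(1, 1, 0),
    stringsAsFactors = FALSE
  ), provenance = "fixture")
}

# small default cohort shared across tests (generated once per run)
small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- generate_cohort(cohort_config(seed = 42))
    memo
  }
})

# weighted Bernoulli log-likelihood, for oracle maximisation in tests
wloglik <- function(beta, X, y, w) {
  eta <- drop(X %*% beta)
  sum(w * (y * eta - log1p(exp(eta))))
}

# independent brute-force maximiser of the weighted likelihood
oracle_logistic <- function(X, y, w = rep(1, length(y))) {
  p <- ncol(X)
  opt <- optim(rep(0, p), fn = function(b) -wloglik(b, X, y, w),
               gr = function(b) {
                 mu <- plogis(drop(X %*% b))
                 -drop(crossprod(X, w * (y - mu)))
               },
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# O(n^2) pairwise-count AUC oracle with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive-threshold oracle for the sensitivity cut-off
oracle_cutoff <- function(scores, labels, target) {
  pos <- scores[labels == 1]
  cand <- sort(unique(scores), decreasing = TRUE)
  ok <- vapply(cand, function(c0) mean(pos >= c0) >= target, logical(1))
  cand[which(ok)[1]]
}

# two-sided exact McNemar oracle by explicit binomial enumeration
oracle_mcnemar_p <- function(b, c) {
  m <- b + c
  if (m == 0) return(1)
  pmf <- choose(m, 0:m) / 2^m
  min(1, 2 * sum(pmf[seq_len(min(b, c) + 1L)]))
}

# two-sided Fisher oracle by hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
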