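# Synthetic node-level cohorts with the published marginal structure:
# per-echelon node counts and EBUS-positive fractions, log-normal SUVmax
# with positive-node dependence on the primary tumour, per-echelon/status
# diameter distributions, and a latent-truth layer observed through EBUS
# with configurable sensitivity.

#' Fit a log-normal distribution to a median and a quantile pair
#'
#' Given the median and a symmetric-in-probability quantile pair
#' (for example 25th/75th or 5th/95th percentiles) of a positive quantity,
#' returns the parameters of the log-normal distribution that matches the
#' median exactly and reproduces the quantile spread:
#' `mu = log(median)` and
#' `sigma = (log(q_high) - log(q_low)) / (z(p_high) - z(p_low))`
#' with `z` the standard-normal quantile function.
#'
#' @param median,q_low,q_high positive reals, `q_low <= median <= q_high`.
#' @param p_low,p_high probabilities of the lower/upper quantile,
#'   `p_low < p_high`.
#' @return list with elements `mu` and `sigma` (log-scale).
#' @examples
#' lognormal_from_quantiles(2.43, 0.90, 5.30, 0.05, 0.95)
#' @export
lognormal_from_quantiles <- function(median, q_low, q_high,
                                     p_low = 0.25, p_high = 0.75) {
  stopifnot(median > 0, q_low > 0, q_high > 0, p_low < p_high,
            p_low > 0, p_high < 1)
  if (q_low == q_high && q_low != median) {
    stop("infeasible quantile spec: q_low = q_high != median", call. = FALSE)
  }
  if (q_low > median || q_high < median) {
    stop("quantile spec must satisfy q_low <= median <= q_high",
         call. = FALSE)
  }
  sigma <- (log(q_high) - log(q_low)) / (qnorm(p_high) - qnorm(p_low))
  list(mu = log(median), sigma = sigma)
}

#' Intercept calibration for the positive-node SUVmax model
#'
#' Positive-node log SUVmax follows
#' `log(suv) = beta0 + slope * log(primary suv) + echelon offset + noise`.
#' This chooses `beta0` so that at the median primary SUVmax the median
#' echelon-1 positive-node SUVmax equals `target_median_e1`:
#' `beta0 = log(target) - slope * mu_primary`.
#'
#' @param target_median_e1 target median SUVmax of echelon-1 positive nodes.
#' @param slope slope on log primary SUVmax.
#' @param mu_primary log-scale mean (= log median) of the primary SUVmax
#'   distribution.
#' @return the intercept `beta0`.
#' @export
calibrate_positive_intercept <- function(target_median_e1, slope, mu_primary) {
  if (!is.numeric(target_median_e1) || target_median_e1 <= 0) {
    stop("target median must be positive", call. = FALSE)
  }
  log(target_median_e1) - slope * mu_primary
}

# Table-1 diameter quartiles (cm), median (q25, q75), per echelon x status
.diameter_specs <- list(
  pos = list(
    list(median = 2.04, q_low = 1.29, q_high = 6.00),
    list(median = 1.63, q_low = 1.29, q_high = 2.15),
    list(median = 1.66, q_low = 1.28, q_high = 1.90)
  ),
  neg = list(
    list(median = 0.92, q_low = 0.62, q_high = 1.24),
    list(median = 1.02, q_low = 0.78, q_high = 1.34),
    list(median = 0.79, q_low = 0.60, q_high = 1.06)
  )
)

#' Generative configuration for synthetic cohorts
#'
#' Bundles every parameter of the cohort generator.  The defaults encode the
#' published cohort structure: 180 patients with on average 675 nodes split
#' 169/297/209 over echelons 1-3; per-echelon EBUS-positive fractions
#' 0.86/0.42/0.096; primary-tumour SUVmax log-normal with median 14.65
#' (5th-95th percentiles 4.85-30.35); positive-node log SUVmax regressed on
#' log primary SUVmax with slope 0.55 and echelon offsets -0.328 (echelon 2)
#' and -0.422 (echelon 3) relative to echelon 1; negative-node SUVmax
#' log-normal with median 2.43 (5th-95th: 0.90-5.30); per-echelon/status
#' diameter log-normals fitted to the published quartiles.
#'
#' The residual log-SUV noise `sigma_res` of positive nodes defaults to a
#' variance decomposition: the marginal log-SUV spread of echelon-1
#' positives (sd 0.668 from the published quartile ratio) minus the variance
#' explained by the primary, `sqrt(0.668^2 - slope^2 * sigma_primary^2)`,
#' about 0.59.  The intercept `beta0` defaults to
#' [calibrate_positive_intercept()] with target median 10.6 (echelon-1
#' positives).
#'
#' @param n_patients number of patients.
#' @param mean_nodes_per_echelon expected sampled nodes per patient at
#'   echelons 1-3 (Poisson means).
#' @param prevalence_by_echelon probability that a sampled node is truly
#'   involved, per echelon.
#' @param ebus_sensitivity probability that EBUS detects a truly involved
#'   node (specificity is taken as 1).  Default 1; use 0.85 for the
#'   combined-test experiments.
#' @param primary_suv_lognormal list `(mu, sigma)` of log primary SUVmax.
#' @param slope,delta2,delta3 positive-node regression slope on log primary
#'   SUVmax and echelon-2/3 offsets (echelon 1 is the reference, offset 0).
#' @param beta0 positive-node regression intercept; `NULL` = calibrated to
#'   an echelon-1 median of `target_median_e1`.
#' @param target_median_e1 see `beta0`.
#' @param sigma_res residual sd of positive-node log SUVmax; `NULL` =
#'   variance-decomposition default.
#' @param negative_node_lognormal list `(mu, sigma)` of log SUVmax of
#'   uninvolved nodes.
#' @param diameter_lognormal nested list `pos`/`neg` of per-echelon
#'   `(mu, sigma)` lists for the CT short-axis diameter.
#' @param p_conglomerate probability that a node is part of a
#'   conglomerate/diffuse-infiltration mass; its diameter is then drawn from
#'   the echelon-1 involved-node distribution truncated at 6 cm (the
#'   largest-size-group convention).
#' @param p_adeno probability of adenocarcinoma histology (per patient).
#' @param p_right_primary probability of a right-sided primary.
#' @param p_station4R_given_left probability that a node of a left-sided
#'   primary carries the station-4R flag (default tuned so about 55/675
#'   nodes carry it).
#' @param min_diameter_cm smallest sampled node diameter (EBUS samples nodes
#'   of 0.5 cm or more).
#' @param seed integer root seed; fixes the cohort bit-for-bit.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 180L,
    mean_nodes_per_echelon = c(169, 297, 209) / 180,
    prevalence_by_echelon = c(0.86, 0.42, 0.096),
    ebus_sensitivity = 1.0,
    primary_suv_lognormal = lognormal_from_quantiles(14.65, 4.85, 30.35,
                                                     0.05, 0.95),
    slope = 0.55,
    delta2 = -0.328,
    delta3 = -0.422,
    beta0 = NULL,
    target_median_e1 = 10.6,
    sigma_res = NULL,
    negative_node_lognormal = lognormal_from_quantiles(2.43, 0.90, 5.30,
                                                       0.05, 0.95),
    diameter_lognormal = NULL,
    p_conglomerate = 0.03,
    p_adeno = 304 / 675,
    p_right_primary = 337 / 675,
    p_station4R_given_left = 55 / 338,
    min_diameter_cm = 0.5,
    seed = 1L) {
  if (is.null(diameter_lognormal)) {
    diameter_lognormal <- lapply(.diameter_specs, function(side) {
      lapply(side, function(s) {
        lognormal_from_quantiles(s$median, s$q_low, s$q_high, 0.25, 0.75)
      })
    })
  }
  if (is.null(beta0)) {
    beta0 <- calibrate_positive_intercept(target_median_e1, slope,
                                          primary_suv_lognormal$mu)
  }
  if (is.null(sigma_res)) {
    # marginal sd of log SUVmax of echelon-1 positives from Table-1
    # quartiles 6.5-16.0, minus the part explained by the primary
    sd_total <- (log(16.0) - log(6.5)) / (2 * qnorm(0.75))
    sigma_res <- sqrt(max(sd_total^2 -
                            slope^2 * primary_suv_lognormal$sigma^2, 0))
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    mean_nodes_per_echelon = mean_nodes_per_echelon,
    prevalence_by_echelon = prevalence_by_echelon,
    ebus_sensitivity = ebus_sensitivity,
    primary_suv_lognormal = primary_suv_lognormal,
    slope = slope, delta2 = delta2, delta3 = delta3,
    beta0 = beta0, sigma_res = sigma_res,
    negative_node_lognormal = negative_node_lognormal,
    diameter_lognormal = diameter_lognormal,
    p_conglomerate = p_conglomerate,
    p_adeno = p_adeno,
    p_right_primary = p_right_primary,
    p_station4R_given_left = p_station4R_given_left,
    min_diameter_cm = min_diameter_cm,
    seed = as.integer(seed)
  )
  probs <- c(cfg$prevalence_by_echelon, cfg$ebus_sensitivity,
             cfg$p_conglomerate, cfg$p_adeno, cfg$p_right_primary,
             cfg$p_station4R_given_left)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(cfg$mean_nodes_per_echelon > 0),
            cfg$sigma_res >= 0,
            cfg$primary_suv_lognormal$sigma >= 0,
            cfg$negative_node_lognormal$sigma >= 0,
            cfg$n_patients >= 1L)
  class(cfg) <- "cohort_config"
  cfg
}

# truncated log-normal draw via inverse CDF (exact, no rejection loop)
.rlnorm_trunc <- function(n, mu, sigma, lower) {
  p_lo <- plnorm(lower, mu, sigma)
  p_lo <- pmin(p_lo, 1 - 1e-12)
  qlnorm(runif(n, p_lo, 1), mu, sigma)
}

#' Generate a synthetic node-level cohort
#'
#' Draws, per patient: primary SUVmax, laterality and histology; Poisson
#' node counts per echelon (a patient drawing zero nodes in total is redrawn
#' once, then accepted); then per node in echelon-ascending order: latent
#' truth, SUVmax (regression model for involved nodes, negative-node
#' log-normal otherwise), CT short-axis diameter from the echelon-by-status
#' log-normal truncated below at the minimum sampled diameter, a
#' conglomerate flag (the diameter is then instead drawn from the widest
#' involved-node distribution truncated at 6 cm), the station-4R flag for
#' left-sided primaries, and the EBUS result
#' as truth times a Bernoulli with the configured sensitivity.  Finally
#' `largest_suv_echelon2` is the maximum SUVmax over the patient's
#' echelon-2 nodes, or one auxiliary draw from the negative-node
#' distribution when the patient has none (an unsampled background node, so
#' the feature is defined everywhere without leaking truth).
#'
#' The root seed fixes the whole cohort bit-for-bit; draws occur in the
#' documented order (patients in sequence, nodes echelon-ascending).
#'
#' @param config a [cohort_config()].
#' @return an `ln_cohort` with `truth_positive` set on every record.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  pieces <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    primary_suv <- exp(rnorm(1, config$primary_suv_lognormal$mu,
                             config$primary_suv_lognormal$sigma))
    right <- rbinom(1, 1, config$p_right_primary)
    adeno <- rbinom(1, 1, config$p_adeno)
    counts <- rpois(3, config$mean_nodes_per_echelon)
    if (sum(counts) == 0L) counts <- rpois(3, config$mean_nodes_per_echelon)
    n_i <- sum(counts)
    if (n_i == 0L) {
      # still consume the auxiliary echelon-2 draw for stream stability
      rnorm(1)
      next
    }
    ech <- rep(1:3, counts)
    truth <- rbinom(n_i, 1, config$prevalence_by_echelon[ech])
    offs <- c(0, config$delta2, config$delta3)[ech]
    mu_pos <- config$beta0 + config$slope * log(primary_suv) + offs
    log_suv <- ifelse(truth == 1,
                      rnorm(n_i, mu_pos, config$sigma_res),
                      rnorm(n_i, config$negative_node_lognormal$mu,
                            config$negative_node_lognormal$sigma))
    conglomerate <- rbinom(n_i, 1, config$p_conglomerate)
    # diameter parameters per node: echelon-by-status log-normal, except
    # conglomerate/diffuse masses, which sit in the largest size group
    # (>= 6 cm) whatever their echelon and draw from the widest diameter
    # distribution (echelon-1 involved nodes) truncated at 6 cm
    dmu <- vapply(seq_len(n_i), function(j) {
      config$diameter_lognormal[[if (truth[j] == 1) "pos" else "neg"]][[ech[j]]]$mu
    }, numeric(1))
    dsig <- vapply(seq_len(n_i), function(j) {
      config$diameter_lognormal[[if (truth[j] == 1) "pos" else "neg"]][[ech[j]]]$sigma
    }, numeric(1))
    big <- conglomerate == 1
    dmu[big] <- config$diameter_lognormal$pos[[1L]]$mu
    dsig[big] <- config$diameter_lognormal$pos[[1L]]$sigma
    lower <- ifelse(big, 6, config$min_diameter_cm)
    dia <- .rlnorm_trunc(n_i, dmu, dsig, lower)
    st4R <- if (right == 1) rep(0L, n_i) else
      rbinom(n_i, 1, config$p_station4R_given_left)
    ebus <- truth * rbinom(n_i, 1, config$ebus_sensitivity)
    lse2 <- if (any(ech == 2)) max(exp(log_suv[ech == 2])) else
      exp(rnorm(1, config$negative_node_lognormal$mu,
                config$negative_node_lognormal$sigma))
    pieces[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i),
      echelon = ech,
      suv_max = exp(log_suv),
      suv_max_primary = primary_suv,
      short_diameter_cm = dia,
      conglomerate = conglomerate,
      station4R_left_primary = st4R,
      histology_adeno = adeno,
      primary_right_sided = right,
      largest_suv_echelon2 = lse2,
      ebus_positive = ebus,
      truth_positive = truth,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  cohort <- as_cohort(df, provenance = sprintf(
    "generate_cohort(seed=%d, n_patients=%d, ebus_sensitivity=%g)",
    config$seed, config$n_patients, config$ebus_sensitivity))
  attr(cohort, "config") <- config
  cohort
}
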