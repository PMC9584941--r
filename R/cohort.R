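# Node-level cohort container and CSV interchange.
#
# One row = one EBUS-sampled lymph node; patient-level fields are
# denormalised onto node rows because the node is the unit of analysis.

# canonical column order; truth_positive is optional (absent on real-world
# files, present on synthetic cohorts)
.cohort_columns <- c(
  "patient_id", "echelon", "suv_max", "suv_max_primary", "short_diameter_cm",
  "conglomerate", "station4R_left_primary", "histology_adeno",
  "primary_right_sided", "largest_suv_echelon2", "ebus_positive"
)
.cohort_optional <- "truth_positive"

#' Construct a lymph-node cohort
#'
#' A cohort is a data frame with one row per sampled lymph node and the
#' canonical column set (see Details), carrying class `ln_cohort`.  Binary
#' fields are coded 0/1.  `truth_positive` (latent involvement, synthetic
#' cohorts only) is optional; when it is present and 0 the EBUS result must
#' be 0, reflecting the near-perfect specificity of EBUS-TBNA.
#'
#' @details Canonical columns: `patient_id` (identifier), `echelon`
#'   (1, 2 or 3 along the lymphatic drainage), `suv_max` (node SUVmax, > 0),
#'   `suv_max_primary` (primary-tumour SUVmax, > 0), `short_diameter_cm`
#'   (CT short-axis diameter, cm, > 0), `conglomerate` (conglomerate node or
#'   diffuse mediastinal infiltration, implies diameter >= 6 cm),
#'   `station4R_left_primary` (node in station 4R while the primary is
#'   left-sided), `histology_adeno`, `primary_right_sided`,
#'   `largest_suv_echelon2` (largest echelon-2 node SUVmax of the same
#'   patient, constant within patient), `ebus_positive` and optionally
#'   `truth_positive`.
#'
#' @param df data frame holding the canonical columns.
#' @param provenance free-text origin (file path or generator description).
#' @return the data frame with class `ln_cohort` and a `provenance`
#'   attribute.  Construction does not enforce the row-level invariants;
#'   use [validate_cohort()] to list violations.
#' @seealso [load_cohort()], [save_cohort()], [validate_cohort()]
#' @export
as_cohort <- function(df, provenance = "in-memory") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- c(.cohort_columns,
            intersect(.cohort_optional, names(df)))
  df <- df[, keep, drop = FALSE]
  num_cols <- setdiff(keep, "patient_id")
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      stop("cohort parse error: column '", cl, "' is not numeric",
           call. = FALSE)
    }
  }
  df$patient_id <- as.character(df$patient_id)
  rownames(df) <- NULL
  structure(df, class = c("ln_cohort", "data.frame"),
            provenance = provenance)
}

#' Read a node-level cohort from CSV
#'
#' Expects a header row with the canonical column names (see [as_cohort()]);
#' `truth_positive` may be absent.  Row order is preserved.  Structural
#' problems (missing column, non-numeric SUV or diameter, echelon outside
#' 1..3) raise errors naming the offending column or row; softer rule
#' violations are reported by [validate_cohort()] and raise a warning here.
#'
#' @param path path to a CSV file (UTF-8, decimal point).
#' @return an `ln_cohort`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in setdiff(c(.cohort_columns, intersect(.cohort_optional, names(raw))),
                     "patient_id")) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad) > 0L) {
        stop("cohort parse error: non-numeric value in column '", cl,
             "', row ", bad[1L], call. = FALSE)
      }
      raw[[cl]] <- conv
    }
  }
  bad_ech <- which(!(raw$echelon %in% c(1, 2, 3)))
  if (length(bad_ech) > 0L) {
    stop("cohort validation error: echelon outside {1,2,3} in row ",
         bad_ech[1L], call. = FALSE)
  }
  cohort <- as_cohort(raw, provenance = path)
  viol <- validate_cohort(cohort)
  if (nrow(viol) > 0L) {
    warning(nrow(viol), " invariant violation(s) in ", path,
            "; see validate_cohort()", call. = FALSE)
  }
  cohort
}

# shortest decimal string that round-trips the double exactly
.fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  long <- as.numeric(s) != x & !is.na(x)
  s[long] <- sprintf("%.17g", x[long])
  s
}

#' Write a cohort to CSV
#'
#' Numeric fields are written with enough digits to round-trip exactly, so
#' `load_cohort(save_cohort(x))` reproduces every field bit-for-bit and a
#' file produced by `save_cohort` round-trips byte-identically.
#'
#' @param cohort an `ln_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ln_cohort"))
  out <- as.data.frame(cohort)
  for (cl in setdiff(names(out), "patient_id")) out[[cl]] <- .fmt_num(out[[cl]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' List invariant violations of a cohort
#'
#' Pure check: reports, never raises.  Rules checked per record: echelon in
#' 1..3; positive SUVmax and diameter; binary flags in 0/1; conglomerate
#' nodes have short-axis diameter >= 6 cm; when latent truth is present and
#' 0, the EBUS result is 0 (EBUS specificity treated as 1); the largest
#' echelon-2 SUVmax is constant within each patient.
#'
#' @param cohort an `ln_cohort` (or data frame with the canonical columns).
#' @return data frame with columns `row` (record index, `NA` for
#'   patient-level rules), `rule` (short identifier) and `message`; zero rows
#'   iff all invariants hold.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  add <- function(rows, rule, msg) {
    if (length(rows) > 0L) {
      v[[length(v) + 1L]] <<- data.frame(
        row = rows, rule = rule, message = msg, stringsAsFactors = FALSE)
    }
  }
  add(which(!(cohort$echelon %in% c(1, 2, 3))), "echelon_domain",
      "echelon must be 1, 2 or 3")
  add(which(!(cohort$suv_max > 0)), "suv_positive", "suv_max must be > 0")
  add(which(!(cohort$short_diameter_cm > 0)), "diameter_positive",
      "short_diameter_cm must be > 0")
  for (cl in c("conglomerate", "station4R_left_primary", "histology_adeno",
               "primary_right_sided", "ebus_positive")) {
    add(which(!(cohort[[cl]] %in% c(0, 1))), paste0(cl, "_binary"),
        paste0(cl, " must be 0 or 1"))
  }
  add(which(cohort$conglomerate == 1 & cohort$short_diameter_cm < 6),
      "conglomerate_diameter",
      "conglomerate/diffuse-infiltration nodes must have diameter >= 6 cm")
  if ("truth_positive" %in% names(cohort)) {
    add(which(!is.na(cohort$truth_positive) & cohort$truth_positive == 0 &
                cohort$ebus_positive == 1),
        "ebus_specificity",
        "EBUS cannot be positive on a truth-negative node (specificity 1)")
  }
  per_pat <- tapply(cohort$largest_suv_echelon2, cohort$patient_id,
                    function(x) length(unique(x)) > 1L)
  bad_pat <- names(per_pat)[per_pat]
  if (length(bad_pat) > 0L) {
    add(which(cohort$patient_id %in% bad_pat)[1L], "largest_suv_e2_constant",
        "largest_suv_echelon2 must be identical within patient")
  }
  if (length(v) == 0L) {
    return(data.frame(row = integer(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' @export
print.ln_cohort <- function(x, ...) {
  cat("Lymph-node cohort: ", nrow(x), " nodes, ",
      length(unique(x$patient_id)), " patients\n", sep = "")
  cat("  provenance: ", attr(x, "provenance") %||% "unknown", "\n", sep = "")
  tab <- table(factor(x$echelon, levels = 1:3))
  pos <- tapply(x$ebus_positive, factor(x$echelon, levels = 1:3), mean)
  cat(sprintf("  echelon %d: %d nodes, %.1f%% EBUS-positive\n",
              1:3, as.integer(tab), 100 * ifelse(is.na(pos), 0, pos)))
  invisible(x)
}
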