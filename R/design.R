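# Design-matrix construction for the node-level classifiers.

.design_columns <- c(
  "intercept", "suv_max", "ct_sd", "suv_max_primary",
  "ech2", "ech3", "suv_x_ech2", "suv_x_ech3",
  "station4R_left", "largest_suv_e2", "conglomerate",
  "histology_adeno", "primary_right"
)

#' Build the node-level design matrix
#'
#' Encodes each lymph-node record into the covariate row of the published
#' multivariable model: raw node SUVmax, CT short-axis diameter, primary
#' SUVmax, echelon dummies with echelon 1 as the reference level,
#' SUVmax-by-echelon interaction products, the station-4R/left-primary flag,
#' the patient's largest echelon-2 SUVmax, the conglomerate flag, histology
#' and primary laterality.  Covariates enter untransformed (SUV units, cm).
#'
#' @param cohort an `ln_cohort` (or data frame with the canonical columns).
#' @return numeric matrix with one row per node and columns `intercept`,
#'   `suv_max`, `ct_sd`, `suv_max_primary`, `ech2`, `ech3`, `suv_x_ech2`,
#'   `suv_x_ech3`, `station4R_left`, `largest_suv_e2`, `conglomerate`,
#'   `histology_adeno`, `primary_right`.
#' @export
build_design <- function(cohort) {
  ech2 <- as.numeric(cohort$echelon == 2)
  ech3 <- as.numeric(cohort$echelon == 3)
  X <- cbind(
    intercept = 1,
    suv_max = cohort$suv_max,
    ct_sd = cohort$short_diameter_cm,
    suv_max_primary = cohort$suv_max_primary,
    ech2 = ech2,
    ech3 = ech3,
    suv_x_ech2 = cohort$suv_max * ech2,
    suv_x_ech3 = cohort$suv_max * ech3,
    station4R_left = cohort$station4R_left_primary,
    largest_suv_e2 = cohort$largest_suv_echelon2,
    conglomerate = cohort$conglomerate,
    histology_adeno = cohort$histology_adeno,
    primary_right = cohort$primary_right_sided
  )
  X
}
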