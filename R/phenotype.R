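#' Correct observed blood pressure for antihypertensive treatment
#'
#' For individuals on antihypertensive drugs, adds 15 mm Hg to systolic and
#' 10 mm Hg to diastolic pressure; untreated records are unchanged. The
#' corrected values are written to new `sbp_adj` / `dbp_adj` columns so the
#' correction is applied exactly once per record (it is not idempotent on its
#' own output). The correction applies only to the continuous blood-pressure
#' outcomes; hypertension classification uses the observed values.
#'
#' @param data A data frame with systolic/diastolic pressure and a
#'   treatment flag.
#' @param sbp,dbp,on_meds Column names (strings).
#' @param offsets Numeric length-2 vector of (systolic, diastolic) mm Hg
#'   added for treated individuals.
#' @return `data` as a tibble with `sbp_adj` and `dbp_adj` columns added.
#' @examples
#' adjust_bp_for_treatment(
#'   tibble::tibble(sbp = 130, dbp = 80, on_meds = TRUE)
#' )
#' @export
adjust_bp_for_treatment <- function(data, sbp = "sbp", dbp = "dbp",
                                    on_meds = "on_meds",
                                    offsets = c(15, 10)) {
  data <- tibble::as_tibble(data)
  for (col in c(sbp, dbp, on_meds)) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
  }
  meds <- data[[on_meds]]
  if (any(is.na(meds))) {
    abort("Treatment flag contains missing values; no silent default is applied.")
  }
  if (!all(is.finite(data[[sbp]])) || !all(is.finite(data[[dbp]]))) {
    abort("Blood-pressure values must be finite.")
  }
  meds <- as.logical(meds)
  dplyr::mutate(
    data,
    sbp_adj = .data[[sbp]] + offsets[1] * meds,
    dbp_adj = .data[[dbp]] + offsets[2] * meds
  )
}

#' Classify hypertension
#'
#' Hypertension is defined as observed (pre-correction) systolic pressure of
#' 140 mm Hg or higher, diastolic pressure of 90 mm Hg or higher, or current
#' use of antihypertensive drugs; both thresholds are inclusive.
#'
#' @inheritParams adjust_bp_for_treatment
#' @param sbp_threshold,dbp_threshold Inclusive thresholds in mm Hg.
#' @return `data` as a tibble with a logical `hypertension` column added.
#' @examples
#' classify_hypertension(
#'   tibble::tibble(sbp = c(140, 120), dbp = c(85, 70), on_meds = c(FALSE, TRUE))
#' )
#' @export
classify_hypertension <- function(data, sbp = "sbp", dbp = "dbp",
                                  on_meds = "on_meds",
                                  sbp_threshold = 140, dbp_threshold = 90) {
  data <- tibble::as_tibble(data)
  for (col in c(sbp, dbp, on_meds)) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
  }
  if (any(is.na(data[[on_meds]]))) {
    abort("Treatment flag contains missing values; no silent default is applied.")
  }
  dplyr::mutate(
    data,
    hypertension = .data[[sbp]] >= sbp_threshold |
      .data[[dbp]] >= dbp_threshold |
      as.logical(.data[[on_meds]])
  )
}

#' Natural-log transform of 25(OH)D concentration
#'
#' 25(OH)D concentrations (nmol/L) are analysed on the natural-log scale to
#' approximate normality and linearise associations with the outcomes.
#' Non-positive concentrations are rejected with the offending record named.
#'
#' @param x Numeric vector of concentrations in nmol/L, all > 0.
#' @return `log(x)`.
#' @examples
#' ln_25ohd(c(1, exp(2), 50))
#' @export
ln_25ohd <- function(x) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad) > 0) {
    abort(paste0("Non-positive 25(OH)D concentration at record(s) ",
                 toString(head(bad, 5)),
                 if (length(bad) > 5) " ..." else "",
                 "; the natural-log transform requires values > 0."))
  }
  log(x)
}

#' Convert a log-scale per-allele effect to percent difference
#'
#' A coefficient `b` from a regression of ln 25(OH)D corresponds to a
#' `100 * (exp(b) - 1)` percent difference in concentration per allele; this
#' is the reporting convention used throughout the pipeline.
#' [ln_per_allele()] is the exact inverse.
#'
#' @param beta_ln Effect on ln 25(OH)D (log-units per allele).
#' @return Percent difference per allele.
#' @examples
#' percent_per_allele(0.0279) # ~2.83%
#' @export
percent_per_allele <- function(beta_ln) {
  stopifnot(all(is.finite(beta_ln)))
  100 * expm1(beta_ln)
}

#' @rdname percent_per_allele
#' @param percent Percent difference per allele.
#' @export
ln_per_allele <- function(percent) {
  stopifnot(all(is.finite(percent)))
  log1p(percent / 100)
}

#' Apply all phenotype definitions to a cohort table
#'
#' One-stop preparation: computes `ln25ohd` from `vitd_nmol` when absent,
#' classifies hypertension from observed blood pressure and the treatment
#' flag, and adds treatment-corrected `sbp_adj` / `dbp_adj`. Already-prepared
#' tables pass through unchanged, so the correction is never applied twice.
#' Records with diastolic >= systolic pressure trigger a validation warning
#' (not an error).
#'
#' @param data A cohort table (see [simulate_cohort()] for the layout).
#' @return A prepared tibble.
#' @export
prepare_phenotypes <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"ln25ohd" %in% names(data) && "vitd_nmol" %in% names(data)) {
    data <- dplyr::mutate(data, ln25ohd = ln_25ohd(.data$vitd_nmol))
  }
  n_bad <- sum(data$dbp >= data$sbp, na.rm = TRUE)
  if (n_bad > 0) {
    warn(paste0(n_bad, " record(s) have diastolic >= systolic pressure; ",
                "check units and column mapping."))
  }
  if (!"hypertension" %in% names(data)) data <- classify_hypertension(data)
  if (!all(c("sbp_adj", "dbp_adj") %in% names(data))) {
    data <- adjust_bp_for_treatment(data)
  }
  data
}
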