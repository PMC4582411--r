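#' Read and write pipeline tables
#'
#' All pipeline artefacts are tab-separated text with a header row:
#' per-individual cohort tables, per-SNP summary statistics
#' (`snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`,
#' `outcome`), and association-result tables (`study_id`, `exposure`,
#' `outcome`, `beta`, `se`, `n`, `scale`, `covariates`). The readers check
#' for their required columns and return tibbles.
#'
#' @param data Table to write.
#' @param path File path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name vitdmr_io
NULL

#' @rdname vitdmr_io
#' @export
write_cohort_tsv <- function(data, path) {
  readr::write_tsv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname vitdmr_io
#' @export
read_cohort_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("study_id", "sbp", "dbp", "on_meds")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort table ", path, " is missing columns: ",
                 toString(missing_cols)))
  }
  d
}

#' @rdname vitdmr_io
#' @export
write_summary_stats <- function(data, path) {
  req <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
           "n", "outcome")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Summary statistics are missing columns: ",
                 toString(missing_cols)))
  }
  readr::write_tsv(tibble::as_tibble(data)[req], path)
  invisible(path)
}

#' @rdname vitdmr_io
#' @export
read_summary_stats <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("Summary statistics ", path, " are missing columns: ",
                 toString(missing_cols)))
  }
  d
}

#' @rdname vitdmr_io
#' @export
write_assoc_tsv <- function(data, path) {
  readr::write_tsv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname vitdmr_io
#' @export
read_assoc_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("exposure", "outcome", "beta", "se")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("Association table ", path, " is missing columns: ",
                 toString(missing_cols)))
  }
  d
}
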