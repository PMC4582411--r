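#' Unweighted allele scores from SNP dosages
#'
#' Adds the synthesis and metabolism allele scores to a cohort table. Each
#' score is the unweighted sum of the two component dosages (counted on the
#' 25(OH)D-increasing allele), so it ranges from 0 to 4 and accepts
#' fractional (imputed) dosages. No per-SNP weighting is applied: external
#' weights are generally unavailable and internal weights can bias
#' instrumental-variable results.
#'
#' Individuals missing either component dosage get a missing score and are
#' dropped from score analyses downstream (complete-case); the count of such
#' individuals is reported via a message.
#'
#' @param data Cohort table with one dosage column per panel SNP.
#' @param panel SNP panel (see [default_snp_panel()]).
#' @return `data` with `score_synthesis` and `score_metabolism` columns.
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 100, seed = 1))
#' add_allele_scores(cohort)
#' @export
add_allele_scores <- function(data, panel = default_snp_panel()) {
  data <- tibble::as_tibble(data)
  panel <- validate_snp_panel(panel)
  for (score in c("synthesis", "metabolism")) {
    snps <- score_snps(panel, score)$snp_id
    data[[paste0("score_", score)]] <- allele_score(data, snps)
  }
  data
}

#' Compute one allele score
#'
#' Low-level scorer: sums the dosage columns named in `snps`. Errors if a
#' component SNP column is absent (no single-SNP fallback) or any dosage
#' falls outside `[0, 2]`.
#'
#' @param data Cohort table.
#' @param snps Character vector of component SNP (dosage column) names.
#' @return Numeric vector of scores in `[0, 2 * length(snps)]`; missing if
#'   any component dosage is missing.
#' @export
allele_score <- function(data, snps) {
  missing_snps <- setdiff(snps, names(data))
  if (length(missing_snps) > 0) {
    abort(paste0("Missing component SNP column(s): ", toString(missing_snps),
                 "; scores require all components (no single-SNP fallback)."))
  }
  mat <- as.matrix(data[snps])
  out_of_range <- which(!is.na(mat) & (mat < 0 | mat > 2))
  if (length(out_of_range) > 0) {
    abort("Dosages must lie within [0, 2].")
  }
  score <- rowSums(mat)
  n_na <- sum(is.na(score))
  if (n_na > 0) {
    inform(paste0(n_na, " individual(s) missing a component dosage for score over ",
                  toString(snps), "; they are excluded from score analyses."))
  }
  score
}

#' Harmonise external per-SNP summary statistics to the panel orientation
#'
#' Aligns each summary row to the panel's effect allele (the
#' 25(OH)D-increasing allele). Rows already matching are kept; rows with
#' swapped alleles have their beta sign flipped and EAF replaced by 1 - EAF;
#' strand-complement matches are resolved the same way. Palindromic SNPs
#' (A/T or C/G) have no resolvable strand, so by default they are excluded
#' with a warning rather than silently flipped; set `keep_palindromic = TRUE`
#' only for tables whose strand is known to match the panel (e.g. summary
#' statistics emitted by this pipeline).
#'
#' @param sumstats Tibble with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se` (extra columns pass through).
#' @param panel Target SNP panel.
#' @param keep_palindromic Treat palindromic rows as being on the panel's
#'   strand instead of excluding them.
#' @return Harmonised tibble with an added `harmonisation` column
#'   (`"kept"`, `"flipped"`); palindromic rows are dropped unless kept.
#' @export
harmonise_summary_stats <- function(sumstats, panel = default_snp_panel(),
                                    keep_palindromic = FALSE) {
  sumstats <- tibble::as_tibble(sumstats)
  req <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  missing_cols <- setdiff(req, names(sumstats))
  if (length(missing_cols) > 0) {
    abort(paste0("Summary statistics are missing columns: ",
                 toString(missing_cols)))
  }
  panel <- validate_snp_panel(panel)
  unknown <- setdiff(sumstats$snp_id, panel$snp_id)
  if (length(unknown) > 0) {
    warn(paste0("Dropping summary rows for SNPs not in the panel: ",
                toString(unknown)))
    sumstats <- dplyr::filter(sumstats, .data$snp_id %in% panel$snp_id)
  }
  if (!all(c(sumstats$effect_allele, sumstats$other_allele) %in%
             c("A", "C", "G", "T"))) {
    abort("Summary-statistic alleles must be single characters in {A, C, G, T}.")
  }

  rows <- purrr::map(seq_len(nrow(sumstats)), function(i) {
    row <- sumstats[i, ]
    target <- panel[panel$snp_id == row$snp_id, ]
    ea <- row$effect_allele; oa <- row$other_allele
    t_ea <- target$effect_allele; t_oa <- target$other_allele

    if (is_palindromic(ea, oa)) {
      if (!keep_palindromic) {
        warn(paste0("Excluding palindromic SNP ", row$snp_id, " (", ea, "/", oa,
                    "): strand orientation is ambiguous."))
        return(NULL)
      }
      # forward-strand assumption: fall through to direct matching
    }
    cea <- allele_complement(ea); coa <- allele_complement(oa)
    if (ea == t_ea && oa == t_oa) {
      action <- "kept"
    } else if (ea == t_oa && oa == t_ea) {
      action <- "flipped"
    } else if (!is_palindromic(ea, oa) && cea == t_ea && coa == t_oa) {
      action <- "kept"
    } else if (!is_palindromic(ea, oa) && cea == t_oa && coa == t_ea) {
      action <- "flipped"
    } else {
      abort(paste0("Alleles for ", row$snp_id, " (", ea, "/", oa,
                   ") match neither the panel orientation (", t_ea, "/", t_oa,
                   ") nor its strand complement."))
    }
    if (action == "flipped") {
      row$beta <- -row$beta
      row$eaf <- 1 - row$eaf
    }
    row$effect_allele <- t_ea
    row$other_allele <- t_oa
    row$harmonisation <- action
    row
  })
  purrr::list_rbind(purrr::compact(rows))
}
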