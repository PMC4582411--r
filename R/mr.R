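#' Delta-method standard error of a Wald ratio
#'
#' First-order Taylor-expansion variance of the ratio `beta_zy / beta_zx`
#' with the numerator-denominator covariance set to zero:
#' `var(r) = se_zy^2 / beta_zx^2 + beta_zy^2 * se_zx^2 / beta_zx^4`.
#' The zero-covariance assumption matches the standard two-stage ratio; it
#' is recorded in the estimate's metadata.
#'
#' @param beta_zy,se_zy Instrument-outcome association and its SE.
#' @param beta_zx,se_zx Instrument-exposure association and its SE
#'   (`beta_zx` must be non-zero).
#' @return The standard error of `beta_zy / beta_zx` (unscaled).
#' @examples
#' taylor_se(-0.08, 0.0332, 2.83, 0.1786)
#' @export
taylor_se <- function(beta_zy, se_zy, beta_zx, se_zx) {
  if (beta_zx == 0) abort("beta_zx must be non-zero for the Taylor-expansion SE.")
  stopifnot(se_zy >= 0, se_zx >= 0)
  sqrt(se_zy^2 / beta_zx^2 + beta_zy^2 * se_zx^2 / beta_zx^4)
}

#' Instrumental-variable (Wald) ratio estimate
#'
#' Divides the pooled instrument-outcome association (per allele) by the
#' instrument-exposure association expressed as percent difference in
#' 25(OH)D per allele, and rescales to the conventional per-10%-increase
#' reporting unit: `ratio = (beta_zy / beta_zx_percent) * 10`. The standard
#' error comes from [taylor_se()] on the same scale; 95% confidence limits
#' and the Wald p-value use the normal reference. For binary outcomes
#' `beta_zy` must be a log-odds coefficient; the interval is built on the
#' log-odds scale and exponentiated into an odds ratio per 10% increase.
#'
#' @param beta_zy Per-allele score-outcome association (mm Hg, or log-odds
#'   for binary outcomes).
#' @param se_zy Its standard error.
#' @param beta_zx_percent Per-allele score-exposure association in percent
#'   difference of 25(OH)D; must be positive (25(OH)D-increasing
#'   orientation).
#' @param se_zx_percent Its standard error (percent).
#' @param binary Is the outcome binary (log-odds numerator)?
#' @param outcome Optional outcome label carried in the result.
#' @return An object of class `vitdmr_iv`: the per-10% causal-effect ratio,
#'   delta-method SE, 95% CI, Wald p-value, and (for binary outcomes) the
#'   odds-ratio scale.
#' @examples
#' iv_ratio(-0.08, 0.0332, 2.83, 0.1786)
#' @export
iv_ratio <- function(beta_zy, se_zy, beta_zx_percent, se_zx_percent,
                     binary = FALSE, outcome = NA_character_) {
  if (!is.finite(beta_zx_percent) || beta_zx_percent <= 0) {
    abort(paste0("beta_zx_percent must be > 0 (instrument oriented to the ",
                 "25(OH)D-increasing allele); got ", beta_zx_percent, "."))
  }
  stopifnot(is.finite(beta_zy), se_zy > 0, se_zx_percent >= 0)
  ratio <- beta_zy / beta_zx_percent * 10
  se <- 10 * taylor_se(beta_zy, se_zy, beta_zx_percent, se_zx_percent)
  ci_low <- ratio - qnorm(0.975) * se
  ci_high <- ratio + qnorm(0.975) * se
  p <- 2 * pnorm(-abs(ratio / se))
  out <- list(
    ratio = ratio, se = se, ci_low = ci_low, ci_high = ci_high, p = p,
    binary = binary, outcome = outcome,
    or = if (binary) exp(ratio) else NA_real_,
    or_ci_low = if (binary) exp(ci_low) else NA_real_,
    or_ci_high = if (binary) exp(ci_high) else NA_real_,
    covariance_assumption = "numerator-denominator covariance set to 0"
  )
  structure(out, class = "vitdmr_iv")
}

#' Instrument-strength diagnostics
#'
#' From the proportion of exposure variance explained by the allele score,
#' computes the instrument F-statistic `F = R^2 * (n - 2) / (1 - R^2)` and
#' the relative bias `1/F` of the instrumental-variable ratio compared with
#' ordinary least-squares regression.
#'
#' @param r2 Proportion of ln 25(OH)D variance explained by the score
#'   (`0 <= r2 < 1`).
#' @param n Sample size behind `r2` (`n > 2`).
#' @return An object of class `vitdmr_instrument` with fields `r2`, `n`,
#'   `f_stat`, `relative_bias`.
#' @examples
#' f_statistic(0.005, 49363)
#' @export
f_statistic <- function(r2, n) {
  if (!is.finite(r2) || r2 < 0 || r2 >= 1) {
    abort("r2 must lie in [0, 1).")
  }
  if (n <= 2) abort("n must exceed 2.")
  f <- r2 * (n - 2) / (1 - r2)
  structure(
    list(r2 = r2, n = as.integer(n), f_stat = f, relative_bias = 1 / f),
    class = "vitdmr_instrument"
  )
}

#' @export
print.vitdmr_instrument <- function(x, ...) {
  cat(sprintf("<instrument diagnostics> R2 = %.4g, n = %d, F = %.4g, relative bias = %.3g%%\n",
              x$r2, x$n, x$f_stat, 100 * x$relative_bias))
  invisible(x)
}

#' @export
print.vitdmr_iv <- function(x, ...) {
  cat("<instrumental-variable ratio, per 10% increase in 25(OH)D>\n")
  cat(sprintf("  estimate %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$ratio, x$se, x$ci_low, x$ci_high, x$p))
  if (isTRUE(x$binary)) {
    cat(sprintf("  odds ratio %.4g, 95%% CI [%.4g, %.4g]\n",
                x$or, x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' Triangulation table of phenotypic, genetic and IV estimates
#'
#' Builds the summary table that juxtaposes, for each blood-pressure
#' outcome, (i) the phenotypic association per 10% increase in 25(OH)D,
#' (ii) the per-allele association of the synthesis score with the outcome,
#' and (iii) the instrumental-variable causal estimate per 10% increase,
#' with its delta-method CI and p-value. Binary outcomes are reported as
#' odds ratios.
#'
#' @param assoc A table of association rows (columns `exposure`, `outcome`,
#'   `beta`, `se`, `scale`) containing, per outcome, a `ln25ohd` phenotypic
#'   row and a `score_synthesis` row, plus one `score_synthesis` row with
#'   `outcome == "ln25ohd"` whose `scale` is either `"percent_per_allele"`
#'   (beta already in percent) or a log-scale per-allele beta.
#' @param outcomes Outcome labels to triangulate, in display order.
#' @return A tibble with one row per outcome: phenotypic estimate and CI,
#'   genetic per-allele estimate and CI, IV estimate, CI and p-value
#'   (odds-ratio scale for binary outcomes).
#' @export
triangulate <- function(assoc,
                        outcomes = c("sbp", "dbp", "hypertension")) {
  assoc <- tibble::as_tibble(assoc)
  get_row <- function(exposure, outcome) {
    r <- dplyr::filter(assoc, .data$exposure == !!exposure,
                       .data$outcome == !!outcome)
    if (nrow(r) != 1) {
      abort(paste0("Expected exactly one row for ", exposure, " -> ",
                   outcome, ", found ", nrow(r), "."))
    }
    r
  }
  zx <- get_row("score_synthesis", "ln25ohd")
  if (identical(zx$scale, "percent_per_allele")) {
    zx_pct <- zx$beta
    zx_pct_se <- zx$se
  } else {
    # convert a log-scale per-allele beta to the percent reporting scale
    zx_pct <- percent_per_allele(zx$beta)
    zx_pct_se <- 100 * exp(zx$beta) * zx$se  # delta method for 100*(e^b - 1)
  }
  rows <- purrr::map(outcomes, function(oc) {
    binary <- grepl("hyper", oc)
    outcome_key <- map_outcome_key(assoc, oc)
    pheno <- get_row("ln25ohd", outcome_key)
    gen <- get_row("score_synthesis", outcome_key)
    iv <- iv_ratio(gen$beta, gen$se, zx_pct, zx_pct_se, binary = binary,
                   outcome = oc)
    tr <- function(x) if (binary) exp(x) else x
    tibble::tibble(
      outcome = oc,
      binary = binary,
      phenotypic = tr(pheno$beta),
      phenotypic_ci_low = tr(pheno$beta - 1.96 * pheno$se),
      phenotypic_ci_high = tr(pheno$beta + 1.96 * pheno$se),
      genetic_per_allele = tr(gen$beta),
      genetic_ci_low = tr(gen$beta - 1.96 * gen$se),
      genetic_ci_high = tr(gen$beta + 1.96 * gen$se),
      iv_estimate = if (binary) iv$or else iv$ratio,
      iv_ci_low = if (binary) iv$or_ci_low else iv$ci_low,
      iv_ci_high = if (binary) iv$or_ci_high else iv$ci_high,
      iv_p = iv$p
    )
  })
  purrr::list_rbind(rows)
}

map_outcome_key <- function(assoc, outcome) {
  keys <- unique(assoc$outcome)
  cand <- c(outcome, paste0(outcome, "_adj"))
  hit <- intersect(cand, keys)
  if (length(hit) == 0) {
    abort(paste0("No association rows found for outcome '", outcome, "'."))
  }
  hit[1]
}
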