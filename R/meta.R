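#' @name meta
#' @title Fixed- and random-effects meta-analysis
#'
#' @description
#' Inverse-variance pooling of per-study association estimates with the
#' heterogeneity statistics used to choose between models:
#'
#' * `meta_fixed()` - fixed-effect pooling with weights `w = 1/se^2`,
#'   Cochran's `Q = sum(w * (beta - pooled)^2)` on `k - 1` degrees of
#'   freedom, and `I^2 = max(0, (Q - df)/Q) * 100`.
#' * `meta_random()` - DerSimonian-Laird random effects:
#'   `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` from the
#'   fixed-effect weights, then re-pooling with `w* = 1/(se^2 + tau^2)`.
#' * `select_model()` - random effects are used in the presence of
#'   heterogeneity, i.e. when the fixed-effect heterogeneity p-value falls
#'   strictly below `alpha_q` (default 0.05); otherwise fixed effects.
#' * `run_meta()` - fits the fixed model, applies the rule, and returns the
#'   selected result with the decision recorded.
#'
#' @param estimates A data frame with columns `beta` and `se` (`study_id`
#'   optional; extra columns ignored).
#' @return An object of class `vitdmr_meta`; see [tidy.vitdmr_meta()] and
#'   [glance.vitdmr_meta()].
#' @examples
#' ests <- tibble::tibble(beta = c(1, 1.2, 0.8), se = c(0.2, 0.3, 0.25))
#' meta_fixed(ests)
#' run_meta(ests)
NULL

meta_inputs <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  if (!all(c("beta", "se") %in% names(estimates))) {
    abort("Estimates must have 'beta' and 'se' columns.")
  }
  if (nrow(estimates) < 1) abort("At least one study estimate is required.")
  if (!all(is.finite(estimates$beta)) || !all(estimates$se > 0)) {
    abort("All betas must be finite and all SEs > 0.")
  }
  if (!"study_id" %in% names(estimates)) {
    estimates$study_id <- paste0("study_", seq_len(nrow(estimates)))
  }
  estimates[c("study_id", "beta", "se")]
}

new_meta <- function(beta, se, model, q, df, p_q, i2, tau2, inputs,
                     selection = NULL) {
  structure(
    list(beta = beta, se = se, model = model,
         q = q, df = df, p_q = p_q, i2 = i2, tau2 = tau2,
         k = nrow(inputs), inputs = inputs, selection = selection),
    class = "vitdmr_meta"
  )
}

#' @rdname meta
#' @export
meta_fixed <- function(estimates) {
  d <- meta_inputs(estimates)
  w <- 1 / d$se^2
  beta <- sum(w * d$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (d$beta - beta)^2)
  df <- nrow(d) - 1L
  p_q <- if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  new_meta(beta, se, "fixed", q, df, p_q, i2, tau2 = 0, inputs = d)
}

#' @rdname meta
#' @export
meta_random <- function(estimates) {
  d <- meta_inputs(estimates)
  if (nrow(d) < 2) abort("Random-effects pooling needs at least 2 studies.")
  fx <- meta_fixed(d)
  w <- 1 / d$se^2
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (fx$q - fx$df) / c_dl)
  w_star <- 1 / (d$se^2 + tau2)
  beta <- sum(w_star * d$beta) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  new_meta(beta, se, "random", fx$q, fx$df, fx$p_q, fx$i2, tau2, inputs = d)
}

#' @rdname meta
#' @param fixed_result A `vitdmr_meta` from [meta_fixed()].
#' @param alpha_q Heterogeneity-test threshold for switching to random
#'   effects (strict inequality; ties stay fixed).
#' @export
select_model <- function(fixed_result, alpha_q = 0.05) {
  stopifnot(inherits(fixed_result, "vitdmr_meta"))
  if (!is.na(fixed_result$p_q) && fixed_result$p_q < alpha_q) "random" else "fixed"
}

#' @rdname meta
#' @export
run_meta <- function(estimates, alpha_q = 0.05) {
  fx <- meta_fixed(estimates)
  model <- select_model(fx, alpha_q)
  res <- if (model == "random") meta_random(estimates) else fx
  res$selection <- tibble::tibble(
    k = fx$k, q = fx$q, df = fx$df, p_q = fx$p_q, alpha_q = alpha_q,
    model = model
  )
  res
}

#' Univariate meta-regression
#'
#' Regresses per-study effect sizes on one study-level covariate by weighted
#' least squares, with a residual (method-of-moments) between-study variance
#' estimated from the meta-regression residual Q and folded into the
#' weights: `w = 1/(se^2 + tau2_mr)`. Used to probe sources of heterogeneity
#' (e.g. mean study BMI, age, measurement method).
#'
#' @param estimates Data frame with `beta`, `se` columns.
#' @param covariate Numeric study-level covariate (one value per study), or
#'   a factor/character with two levels (coded 0/1 internally).
#' @return A one-row tibble: `slope`, `se`, `p`, `tau2`, `q_resid`, `k`.
#' @export
meta_regression <- function(estimates, covariate) {
  d <- meta_inputs(estimates)
  k <- nrow(d)
  if (k < 3) abort("Meta-regression needs at least 3 studies.")
  if (length(covariate) != k) {
    abort("Covariate must have one value per study.")
  }
  if (is.character(covariate) || is.factor(covariate)) {
    lev <- unique(as.character(covariate))
    if (length(lev) != 2) abort("Categorical covariates must have two levels.")
    covariate <- as.numeric(as.character(covariate) == lev[2])
  }
  if (length(unique(covariate)) < 2) {
    abort("Meta-regression covariate is constant.")
  }
  X <- cbind(1, covariate)
  wls <- function(w) {
    W <- diag(w)
    xtwx_inv <- solve(t(X) %*% W %*% X)
    b <- xtwx_inv %*% t(X) %*% (w * d$beta)
    list(b = b, cov = xtwx_inv, resid = d$beta - X %*% b)
  }
  w0 <- 1 / d$se^2
  fit0 <- wls(w0)
  q_resid <- sum(w0 * fit0$resid^2)
  # method-of-moments tau2 from the residual Q of the fixed-weight fit
  W0 <- diag(w0)
  P <- W0 - W0 %*% X %*% solve(t(X) %*% W0 %*% X) %*% t(X) %*% W0
  tau2 <- max(0, (q_resid - (k - 2)) / sum(diag(P)))
  w1 <- 1 / (d$se^2 + tau2)
  fit1 <- wls(w1)
  slope <- unname(fit1$b[2, 1])
  se <- unname(sqrt(fit1$cov[2, 2]))
  tibble::tibble(
    slope = slope, se = se,
    p = 2 * pnorm(-abs(slope / se)),
    tau2 = tau2, q_resid = q_resid, k = k
  )
}

#' Approximate an allele-score effect from per-SNP summary statistics
#'
#' Combines harmonised per-SNP consortium rows into the per-allele effect of
#' an unweighted allele score, without individual-level data. Each SNP is
#' weighted by its dosage variance under Hardy-Weinberg,
#' `v_j = 2 * eaf_j * (1 - eaf_j)`: the score effect is
#' `sum(v_j * beta_j) / sum(v_j)` with standard error
#' `sqrt(sum(v_j^2 * se_j^2)) / sum(v_j)` under SNP independence. With
#' `weighting = "unweighted"` a plain mean of the per-SNP betas is used
#' instead (a cruder alternative retained for sensitivity checks). Both
#' variants are validated against individual-level score regression in the
#' test-suite.
#'
#' @param per_snp Harmonised summary rows for exactly the score's component
#'   SNPs (columns `snp_id`, `eaf`, `beta`, `se`, optionally `n`).
#' @param panel SNP panel defining the score memberships.
#' @param score `"synthesis"` or `"metabolism"`.
#' @param weighting `"dosage_variance"` (default) or `"unweighted"`.
#' @return A one-row association-result tibble with
#'   `exposure = "score_<score>"`.
#' @export
approximate_score_effect <- function(per_snp, panel = default_snp_panel(),
                                     score = c("synthesis", "metabolism"),
                                     weighting = c("dosage_variance",
                                                   "unweighted")) {
  score <- match.arg(score)
  weighting <- match.arg(weighting)
  per_snp <- tibble::as_tibble(per_snp)
  comp <- score_snps(panel, score)$snp_id
  missing_snps <- setdiff(comp, per_snp$snp_id)
  if (length(missing_snps) > 0) {
    abort(paste0("Missing summary rows for score component SNP(s): ",
                 toString(missing_snps)))
  }
  rows <- per_snp[match(comp, per_snp$snp_id), ]
  if (any(is.na(rows$eaf))) abort("EAF is required for every component SNP.")
  if (any(rows$eaf <= 0 | rows$eaf >= 1)) {
    abort("EAFs must lie strictly between 0 and 1.")
  }
  v <- if (weighting == "dosage_variance") 2 * rows$eaf * (1 - rows$eaf)
       else rep(1, nrow(rows))
  beta <- sum(v * rows$beta) / sum(v)
  se <- sqrt(sum(v^2 * rows$se^2)) / sum(v)
  n <- if ("n" %in% names(rows)) max(rows$n) else NA_integer_
  assoc_result(
    study_id = "summary_approximation",
    exposure = paste0("score_", score),
    outcome = if ("outcome" %in% names(rows)) rows$outcome[1] else NA_character_,
    beta = beta, se = se, n = if (is.na(n)) 0L else n,
    scale = "per_allele", covariates = paste0("approx_", weighting)
  )
}

#' Combine a cohort meta-analysis with an external consortium estimate
#'
#' Inverse-variance combination of a pooled multi-cohort result with one
#' consortium summary estimate on the same exposure/outcome/scale, reporting
#' the between-stratum heterogeneity of the two inputs. Overlapping studies
#' must already have been excluded upstream (a configuration concern, not
#' inferred here).
#'
#' @param cohort_result A `vitdmr_meta` or one-row association result.
#' @param consortium A one-row association result (columns `beta`, `se`,
#'   and `scale` when available).
#' @param scale Optional expected scale; if both inputs carry scale metadata
#'   they must agree.
#' @return A `vitdmr_meta` over the two strata.
#' @export
combine_with_consortium <- function(cohort_result, consortium, scale = NULL) {
  as_est <- function(x, label) {
    if (inherits(x, "vitdmr_meta")) {
      tibble::tibble(study_id = label, beta = x$beta, se = x$se,
                     scale = scale %||% NA_character_)
    } else {
      x <- tibble::as_tibble(x)
      stopifnot(nrow(x) == 1)
      tibble::tibble(study_id = label, beta = x$beta, se = x$se,
                     scale = if ("scale" %in% names(x)) x$scale else
                       scale %||% NA_character_)
    }
  }
  a <- as_est(cohort_result, "cohorts")
  b <- as_est(consortium, "consortium")
  if (!is.na(a$scale) && !is.na(b$scale) && a$scale != b$scale) {
    abort(paste0("Scale mismatch: cohorts '", a$scale, "' vs consortium '",
                 b$scale, "'."))
  }
  if (is.infinite(b$se)) return_res <- meta_fixed(a[c("study_id", "beta", "se")])
  else return_res <- meta_fixed(dplyr::bind_rows(a, b)[c("study_id", "beta", "se")])
  return_res
}

#' Forest-plot-ready table of a meta-analysis
#'
#' @param x A `vitdmr_meta`.
#' @return A tibble with per-study rows (`study`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `weight_pct`) followed by the pooled row.
#' @export
forest_table <- function(x) {
  stopifnot(inherits(x, "vitdmr_meta"))
  w <- 1 / (x$inputs$se^2 + x$tau2)
  per_study <- tibble::tibble(
    study = x$inputs$study_id,
    beta = x$inputs$beta, se = x$inputs$se,
    ci_low = x$inputs$beta - 1.96 * x$inputs$se,
    ci_high = x$inputs$beta + 1.96 * x$inputs$se,
    weight_pct = 100 * w / sum(w),
    pooled = FALSE
  )
  pooled <- tibble::tibble(
    study = paste0("pooled (", x$model, ")"),
    beta = x$beta, se = x$se,
    ci_low = x$beta - 1.96 * x$se,
    ci_high = x$beta + 1.96 * x$se,
    weight_pct = 100, pooled = TRUE
  )
  dplyr::bind_rows(per_study, pooled)
}

#' @export
print.vitdmr_meta <- function(x, ...) {
  cat(sprintf("<%s-effects meta-analysis of %d studies>\n", x$model, x$k))
  cat(sprintf("  pooled beta %.4g (se %.4g), 95%% CI [%.4g, %.4g]\n",
              x$beta, x$se, x$beta - 1.96 * x$se, x$beta + 1.96 * x$se))
  cat(sprintf("  Q = %.3g on %d df (p = %.3g), I2 = %.1f%%, tau2 = %.4g\n",
              x$q, x$df, x$p_q, x$i2, x$tau2))
  invisible(x)
}
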