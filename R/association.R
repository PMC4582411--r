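#' @name association
#' @title Per-study adjusted regressions
#'
#' @description
#' The regression engine behind every per-study association the
#' meta-analyses consume. Both fitters take a data frame, an outcome column,
#' an exposure column and a character vector of covariate columns, perform
#' complete-case filtering over exactly the columns used, and return a
#' one-row tibble (an association result) with the exposure's coefficient:
#'
#' * `fit_assoc_linear()` - ordinary least squares; covariates are
#'   partialled in the same fit. When `"age"` is among the covariates an
#'   age-squared term is constructed internally.
#' * `fit_assoc_logistic()` - maximum-likelihood logistic regression
#'   (iteratively reweighted least squares, convergence tolerance 1e-8,
#'   at most 50 iterations), returning a log-odds coefficient. Perfect
#'   separation raises an error rather than a huge finite estimate.
#'
#' Character or factor covariates (e.g. batch, region) enter as factors.
#' Results are invariant to row order and covariate order.
#'
#' @param data A data frame.
#' @param outcome Outcome column name. For the logistic fitter this must be
#'   logical or 0/1 with both classes present.
#' @param exposure Exposure column name (numeric).
#' @param covariates Character vector of covariate column names.
#' @param study_id Study label stored in the result (defaults to the table's
#'   `study_id` when unique).
#' @param scale Scale metadata string stored in the result.
#' @return A one-row tibble: `study_id`, `exposure`, `outcome`, `beta`,
#'   `se`, `n`, `scale`, `covariates`.
NULL

assoc_result <- function(study_id, exposure, outcome, beta, se, n, scale,
                         covariates) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  tibble::tibble(
    study_id = study_id %||% NA_character_,
    exposure = exposure, outcome = outcome,
    beta = beta, se = se, n = as.integer(n), scale = scale,
    covariates = paste(covariates, collapse = "+")
  )
}

default_study_id <- function(data) {
  if ("study_id" %in% names(data)) {
    ids <- unique(data$study_id)
    if (length(ids) == 1) return(as.character(ids))
  }
  NA_character_
}

build_design <- function(data, outcome, exposure, covariates) {
  cols <- unique(c(outcome, exposure, covariates))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found: ", toString(missing_cols)))
  }
  df <- as.data.frame(data[cols])
  df <- df[complete.cases(df), , drop = FALSE]
  terms <- covariates
  if ("age" %in% covariates) {
    df$.age_sq <- df$age^2
    terms <- c(terms, ".age_sq")
  }
  for (v in terms) {
    if (v != ".age_sq" && (is.character(df[[v]]) || is.logical(df[[v]]))) {
      df[[v]] <- factor(df[[v]])
    }
  }
  fml <- stats::reformulate(c(sprintf("`%s`", exposure),
                              sprintf("`%s`", terms)),
                            response = sprintf("`%s`", outcome))
  list(df = df, formula = fml)
}

check_rank <- function(fit) {
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased) > 0) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 toString(aliased)))
  }
}

extract_term <- function(fit, exposure) {
  nm <- sprintf("`%s`", exposure)
  cf <- coef(summary(fit))
  idx <- match(nm, rownames(cf))
  if (is.na(idx)) idx <- match(exposure, rownames(cf))
  if (is.na(idx)) abort(paste0("Exposure term '", exposure, "' not in fit."))
  c(beta = cf[idx, 1], se = cf[idx, 2])
}

#' @rdname association
#' @export
fit_assoc_linear <- function(data, outcome, exposure, covariates = character(),
                             study_id = default_study_id(data),
                             scale = "per_unit") {
  d <- build_design(data, outcome, exposure, covariates)
  p <- length(attr(stats::terms(d$formula), "term.labels")) + 1
  if (nrow(d$df) <= p) {
    abort(paste0("Too few complete cases (", nrow(d$df),
                 ") for ", p, " parameters."))
  }
  fit <- lm(d$formula, data = d$df)
  check_rank(fit)
  est <- extract_term(fit, exposure)
  assoc_result(study_id, exposure, outcome, est[["beta"]], est[["se"]],
               nrow(d$df), scale, covariates)
}

#' @rdname association
#' @export
fit_assoc_logistic <- function(data, outcome, exposure,
                               covariates = character(),
                               study_id = default_study_id(data),
                               scale = "log_odds") {
  d <- build_design(data, outcome, exposure, covariates)
  y <- d$df[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) {
    abort("Logistic outcome must be logical or 0/1.")
  }
  if (length(unique(y)) < 2) {
    abort("Both outcome classes must be present for logistic regression.")
  }
  d$df[[outcome]] <- y
  p <- length(attr(stats::terms(d$formula), "term.labels")) + 1
  if (nrow(d$df) <= p) {
    abort(paste0("Too few complete cases (", nrow(d$df),
                 ") for ", p, " parameters."))
  }
  fit <- withCallingHandlers(
    glm(d$formula, data = d$df, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  check_rank(fit)
  eta <- stats::predict(fit, type = "link")
  if (!fit$converged || max(abs(eta)) > 30) {
    abort(paste0("Logistic fit for '", exposure, "' vs '", outcome,
                 "' shows (quasi-)complete separation; no finite ",
                 "maximum-likelihood estimate exists."))
  }
  est <- extract_term(fit, exposure)
  assoc_result(study_id, exposure, outcome, est[["beta"]], est[["se"]],
               nrow(d$df), scale, covariates)
}

#' Standard per-study association battery
#'
#' Runs the standard analysis plan on one study: each single SNP and each
#' allele score against ln 25(OH)D (additionally adjusted for month of blood
#' draw and laboratory batch), against treatment-corrected systolic and
#' diastolic pressure, and against hypertension (logistic); plus the
#' phenotypic ln 25(OH)D association with each blood-pressure outcome.
#' Phenotype preparation and scores are applied automatically if absent.
#'
#' @param cohort One study's cohort table.
#' @param panel SNP panel.
#' @param covariates Shared adjustment set (default age + age-squared
#'   internally, sex, BMI).
#' @param lipid_adjust Additionally adjust for serum triglycerides (`tg`)
#'   and total cholesterol (`chol`) columns, when present, as a pleiotropy
#'   sensitivity analysis.
#' @return A tibble of association results, one row per model:
#'   `(4 SNPs + 2 scores) x 4 outcomes + 3 phenotypic` rows.
#' @export
study_association_battery <- function(cohort, panel = default_snp_panel(),
                                      covariates = c("age", "sex", "bmi"),
                                      lipid_adjust = FALSE) {
  cohort <- prepare_phenotypes(cohort)
  if (!all(c("score_synthesis", "score_metabolism") %in% names(cohort))) {
    cohort <- add_allele_scores(cohort, panel)
  }
  sid <- default_study_id(cohort)
  if (lipid_adjust) {
    lipids <- intersect(c("tg", "chol"), names(cohort))
    if (length(lipids) == 0) {
      abort("lipid_adjust = TRUE but no 'tg'/'chol' columns are present.")
    }
    covariates <- unique(c(covariates, lipids))
  }
  run <- function(fun, outcome, exposure, covs, scale) {
    tryCatch(
      fun(cohort, outcome, exposure, covariates = covs, scale = scale),
      error = function(e) {
        abort(paste0("Association battery failed for study '", sid,
                     "', model ", exposure, " -> ", outcome, ": ",
                     conditionMessage(e)))
      }
    )
  }
  exposures <- c(panel$snp_id, "score_synthesis", "score_metabolism")
  ln_covs <- unique(c(covariates, "month", "batch"))
  genetic <- purrr::map(exposures, function(ex) {
    dplyr::bind_rows(
      run(fit_assoc_linear, "ln25ohd", ex, ln_covs, "per_allele_ln"),
      run(fit_assoc_linear, "sbp_adj", ex, covariates, "per_allele"),
      run(fit_assoc_linear, "dbp_adj", ex, covariates, "per_allele"),
      run(fit_assoc_logistic, "hypertension", ex, covariates,
          "log_odds_per_allele")
    )
  })
  phenotypic <- purrr::map(
    c("sbp_adj", "dbp_adj"),
    ~ run(fit_assoc_linear, .x, "ln25ohd", covariates, "per_ln_unit")
  )
  phenotypic <- c(phenotypic, list(
    run(fit_assoc_logistic, "hypertension", "ln25ohd", covariates,
        "log_odds_per_ln_unit")
  ))
  purrr::list_rbind(c(genetic, phenotypic))
}
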