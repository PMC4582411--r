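#' Simulation configuration for one cohort
#'
#' Parameterises the generative model behind a simulated study cohort.
#' Genotypes are drawn under Hardy-Weinberg equilibrium with no linkage
#' disequilibrium between the four panel SNPs. ln 25(OH)D is additive in the
#' per-allele SNP effects, a seasonal cosine in month of blood draw, centred
#' age/BMI and sex confounder terms, and a laboratory batch offset. Latent
#' blood pressure depends on the same confounders and, optionally, causally
#' on ln 25(OH)D; antihypertensive treatment is assigned by a logistic model
#' on latent systolic pressure, and observed pressure in treated individuals
#' is lowered by a fixed per-arm amount (default 15/10 mm Hg), so the
#' conventional +15/+10 correction is exact in expectation.
#'
#' @param n Number of individuals.
#' @param snps SNP panel tibble (see [default_snp_panel()]); its
#'   `beta_ln25ohd` column carries the per-allele effects on ln 25(OH)D.
#' @param study_id Study label.
#' @param mu_ln25ohd Baseline mean of ln 25(OH)D (log nmol/L). The default
#'   4.0 corresponds to about 55 nmol/L.
#' @param seasonal_amplitude Amplitude of the seasonal cosine on the log
#'   scale (log-units); `peak_month` places its maximum.
#' @param peak_month Calendar month (1-12) at which 25(OH)D peaks.
#' @param confounder_effects Named vector: effects of centred `age` (per
#'   year), centred `bmi` (per kg/m2) and `sex` (indicator) on ln 25(OH)D.
#' @param causal_effect_sbp,causal_effect_dbp True causal effect of
#'   ln 25(OH)D on blood pressure, in mm Hg per log-unit (0 = no effect).
#' @param confounder_bp_effects List with `sbp` and `dbp` named vectors:
#'   effects of centred age/BMI and sex on latent blood pressure (mm Hg).
#' @param sbp_intercept,dbp_intercept Latent blood-pressure intercepts
#'   (mm Hg) at covariate means (and at ln 25(OH)D = 0 when a causal effect
#'   is present).
#' @param sd_ln25ohd,sd_sbp,sd_dbp Residual standard deviations.
#' @param bp_residual_cor Correlation between the systolic and diastolic
#'   residuals (in [0, 1]); keeps simulated diastolic below systolic
#'   pressure at physiologic rates.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate distributions.
#' @param treatment_model Named vector `c(intercept=, slope=)` of the
#'   logistic model for antihypertensive use on (latent SBP - 140).
#' @param treatment_effect_sbp,treatment_effect_dbp Observed blood-pressure
#'   lowering (mm Hg, non-negative) in treated individuals.
#' @param batch_effects Numeric vector of additive batch offsets on
#'   ln 25(OH)D; its length sets the number of laboratory batches.
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return An object of class `vitdmr_sim_config`.
#' @examples
#' cfg <- sim_config(n = 500, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n = 2000,
                       snps = default_snp_panel(),
                       study_id = "study_1",
                       mu_ln25ohd = 4.0,
                       seasonal_amplitude = 0.15,
                       peak_month = 8,
                       confounder_effects = c(age = 0, bmi = -0.012, sex = 0.05),
                       causal_effect_sbp = 0,
                       causal_effect_dbp = 0,
                       confounder_bp_effects = list(
                         sbp = c(age = 0.5, bmi = 0.5, sex = 4),
                         dbp = c(age = 0.15, bmi = 0.4, sex = 2)
                       ),
                       sbp_intercept = 130,
                       dbp_intercept = 78,
                       sd_ln25ohd = 0.35,
                       sd_sbp = 15,
                       sd_dbp = 10,
                       bp_residual_cor = 0.6,
                       age_mean = 55, age_sd = 10,
                       bmi_mean = 27, bmi_sd = 4.5,
                       treatment_model = c(intercept = -2.5, slope = 0.06),
                       treatment_effect_sbp = 15,
                       treatment_effect_dbp = 10,
                       batch_effects = c(0, 0.03, -0.03),
                       seed = 1L) {
  cfg <- list(
    n = n, snps = validate_snp_panel(snps), study_id = study_id,
    mu_ln25ohd = mu_ln25ohd,
    seasonal_amplitude = seasonal_amplitude, peak_month = peak_month,
    confounder_effects = confounder_effects,
    causal_effect_sbp = causal_effect_sbp,
    causal_effect_dbp = causal_effect_dbp,
    confounder_bp_effects = confounder_bp_effects,
    sbp_intercept = sbp_intercept, dbp_intercept = dbp_intercept,
    sd_ln25ohd = sd_ln25ohd, sd_sbp = sd_sbp, sd_dbp = sd_dbp,
    bp_residual_cor = bp_residual_cor,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    treatment_model = treatment_model,
    treatment_effect_sbp = treatment_effect_sbp,
    treatment_effect_dbp = treatment_effect_dbp,
    batch_effects = batch_effects,
    seed = as.integer(seed)
  )
  class(cfg) <- "vitdmr_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num <- c(cfg$n, cfg$mu_ln25ohd, cfg$seasonal_amplitude, cfg$peak_month,
           cfg$confounder_effects, cfg$causal_effect_sbp, cfg$causal_effect_dbp,
           unlist(cfg$confounder_bp_effects), cfg$sbp_intercept, cfg$dbp_intercept,
           cfg$sd_ln25ohd, cfg$sd_sbp, cfg$sd_dbp, cfg$bp_residual_cor,
           cfg$age_mean, cfg$age_sd, cfg$bmi_mean, cfg$bmi_sd,
           cfg$treatment_model, cfg$treatment_effect_sbp, cfg$treatment_effect_dbp,
           cfg$batch_effects)
  if (!all(is.finite(num))) {
    abort("Simulation configuration error: all parameters must be finite numbers.")
  }
  if (cfg$n < 1) abort("Simulation configuration error: n must be >= 1.")
  if (any(c(cfg$sd_ln25ohd, cfg$sd_sbp, cfg$sd_dbp) < 0)) {
    abort("Simulation configuration error: residual SDs must be >= 0.")
  }
  if (cfg$bp_residual_cor < 0 || cfg$bp_residual_cor > 1) {
    abort("Simulation configuration error: bp_residual_cor must lie in [0, 1].")
  }
  if (cfg$treatment_effect_sbp < 0 || cfg$treatment_effect_dbp < 0) {
    abort("Simulation configuration error: treatment effects must be >= 0.")
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    abort("Simulation configuration error: a single integer seed is required.")
  }
  cfg
}

#' Simulate one study cohort
#'
#' Draws a per-individual cohort table under the generative model described
#' in [sim_config()]. Deterministic given the config's seed: the same config
#' reproduces a byte-identical table.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per individual: `id`, `study_id`, one dosage
#'   column per SNP (named by rsID, counted on the 25(OH)D-increasing
#'   allele), `ln25ohd` (log nmol/L), `vitd_nmol`, observed `sbp`/`dbp`
#'   (mm Hg, post-treatment where treated), `on_meds`, `age`, `sex`, `bmi`,
#'   `month`, `batch`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "vitdmr_sim_config"))
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n
  panel <- cfg$snps
  dosages <- purrr::map(panel$eaf, ~ rbinom(n, size = 2L, prob = .x))
  names(dosages) <- panel$snp_id

  age <- rnorm(n, cfg$age_mean, cfg$age_sd)
  bmi <- pmax(rnorm(n, cfg$bmi_mean, cfg$bmi_sd), 14)
  sex <- rbinom(n, 1L, 0.5)
  month <- sample.int(12L, n, replace = TRUE)
  n_batch <- length(cfg$batch_effects)
  batch_idx <- sample.int(n_batch, n, replace = TRUE)
  batch <- paste0("batch_", batch_idx)

  ce <- cfg$confounder_effects
  genetic <- Reduce(`+`, purrr::map2(dosages, panel$beta_ln25ohd, ~ .x * .y))
  season <- cfg$seasonal_amplitude * cos(2 * pi * (month - cfg$peak_month) / 12)
  ln25ohd <- cfg$mu_ln25ohd + genetic + season +
    ce[["age"]] * (age - cfg$age_mean) +
    ce[["bmi"]] * (bmi - cfg$bmi_mean) +
    ce[["sex"]] * sex +
    cfg$batch_effects[batch_idx] +
    rnorm(n, 0, cfg$sd_ln25ohd)

  # correlated BP residuals: shared + arm-specific standard-normal components
  rho <- cfg$bp_residual_cor
  z_common <- rnorm(n)
  z_sbp <- sqrt(rho) * z_common + sqrt(1 - rho) * rnorm(n)
  z_dbp <- sqrt(rho) * z_common + sqrt(1 - rho) * rnorm(n)
  bp_lat <- function(intercept, causal, eff, sd_res, z) {
    intercept + causal * ln25ohd +
      eff[["age"]] * (age - cfg$age_mean) +
      eff[["bmi"]] * (bmi - cfg$bmi_mean) +
      eff[["sex"]] * sex +
      sd_res * z
  }
  sbp_lat <- bp_lat(cfg$sbp_intercept, cfg$causal_effect_sbp,
                    cfg$confounder_bp_effects$sbp, cfg$sd_sbp, z_sbp)
  dbp_lat <- bp_lat(cfg$dbp_intercept, cfg$causal_effect_dbp,
                    cfg$confounder_bp_effects$dbp, cfg$sd_dbp, z_dbp)

  tm <- cfg$treatment_model
  p_meds <- plogis(tm[["intercept"]] + tm[["slope"]] * (sbp_lat - 140))
  on_meds <- rbinom(n, 1L, p_meds) == 1L

  tibble::tibble(
    id = paste0(cfg$study_id, "_", seq_len(n)),
    study_id = cfg$study_id,
    !!!dosages,
    ln25ohd = ln25ohd,
    vitd_nmol = exp(ln25ohd),
    sbp = sbp_lat - cfg$treatment_effect_sbp * on_meds,
    dbp = dbp_lat - cfg$treatment_effect_dbp * on_meds,
    on_meds = on_meds,
    age = age, sex = sex, bmi = bmi,
    month = month, batch = batch
  )
}

substream_seed <- function(master, index) {
  if (index == 1) return(as.integer(master))
  as.integer((as.numeric(master) %% 2147483647 * 48271 + index * 100003) %% 2147483647)
}

#' Simulate a multi-study collaboration
#'
#' Generates several independent cohorts from a list of per-study configs and
#' stacks them into one table. Each study draws from its own random substream
#' derived from the study's seed and its position in the list, so studies
#' sharing a seed value are still statistically independent.
#'
#' @param configs A list of [sim_config()] objects with distinct `study_id`s.
#' @return A tibble in the [simulate_cohort()] layout, with `study_id`
#'   identifying each cohort.
#' @examples
#' cfgs <- replicate_config(sim_config(n = 200, seed = 3), n_studies = 2)
#' studies <- simulate_studies(cfgs)
#' @export
simulate_studies <- function(configs) {
  if (length(configs) < 1) abort("At least one simulation config is required.")
  ids <- purrr::map_chr(configs, "study_id")
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate study_id in multi-study simulation: ",
                 toString(unique(ids[duplicated(ids)]))))
  }
  purrr::imap(configs, function(cfg, i) {
    cfg$seed <- substream_seed(cfg$seed, i)
    simulate_cohort(validate_sim_config(cfg))
  }) |>
    purrr::list_rbind()
}

#' Replicate one config across studies
#'
#' Convenience helper that clones a base config `n_studies` times with
#' distinct study labels (the master seed is kept; [simulate_studies()]
#' derives independent substreams per position).
#'
#' @param config Base [sim_config()].
#' @param n_studies Number of studies.
#' @param study_prefix Prefix for generated study labels.
#' @param mutate_fn Optional function `(config, index) -> config` applied to
#'   each clone, e.g. to inject between-study heterogeneity.
#' @return A list of configs suitable for [simulate_studies()].
#' @export
replicate_config <- function(config, n_studies, study_prefix = "study",
                             mutate_fn = NULL) {
  stopifnot(inherits(config, "vitdmr_sim_config"), n_studies >= 1)
  purrr::map(seq_len(n_studies), function(i) {
    cfg <- config
    cfg$study_id <- paste0(study_prefix, "_", i)
    if (!is.null(mutate_fn)) cfg <- mutate_fn(cfg, i)
    cfg
  })
}

#' Per-SNP summary statistics from a cohort
#'
#' Emits the per-SNP summary rows a consortium would publish for one outcome:
#' effect-allele-oriented beta and SE from single-SNP adjusted regressions,
#' observed effect-allele frequency, and sample size. Betas come from the
#' same regression engine as the per-study association battery, so they match
#' direct [fit_assoc_linear()] / [fit_assoc_logistic()] output exactly.
#'
#' @param cohort A prepared cohort table (see [prepare_phenotypes()]); must
#'   contain the panel dosage columns.
#' @param outcome One of `"ln25ohd"`, `"sbp"`, `"dbp"`, `"hypertension"`.
#' @param panel SNP panel; defaults to [default_snp_panel()].
#' @param covariates Adjustment covariates passed to the regression engine.
#'   Models with ln 25(OH)D as the outcome are additionally adjusted for
#'   month of blood draw and laboratory batch.
#' @return A tibble with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `n`, `outcome`.
#' @export
emit_summary_stats <- function(cohort, outcome,
                               panel = default_snp_panel(),
                               covariates = c("age", "sex", "bmi")) {
  outcome <- as.character(outcome)
  if (!outcome %in% c("ln25ohd", "sbp", "dbp", "hypertension")) {
    abort(paste0("Unknown outcome label: '", outcome, "'."))
  }
  cohort <- prepare_phenotypes(cohort)
  ycol <- switch(outcome,
    ln25ohd = "ln25ohd", sbp = "sbp_adj", dbp = "dbp_adj",
    hypertension = "hypertension")
  covs <- covariates
  if (outcome == "ln25ohd") covs <- unique(c(covs, "month", "batch"))
  rows <- purrr::pmap(panel, function(snp_id, effect_allele, other_allele,
                                      eaf, role, ...) {
    fit <- if (outcome == "hypertension") {
      fit_assoc_logistic(cohort, ycol, snp_id, covariates = covs)
    } else {
      fit_assoc_linear(cohort, ycol, snp_id, covariates = covs)
    }
    tibble::tibble(
      snp_id = snp_id,
      effect_allele = effect_allele,
      other_allele = other_allele,
      eaf = mean(cohort[[snp_id]]) / 2,
      beta = fit$beta, se = fit$se, n = fit$n,
      outcome = outcome
    )
  })
  purrr::list_rbind(rows)
}
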