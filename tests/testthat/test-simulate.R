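test_that("noise-free degenerate config collapses to the baseline mean", {
  cfg <- sim_config(
    n = 50, seed = 11, snps = null_panel(),
    seasonal_amplitude = 0,
    confounder_effects = c(age = 0, bmi = 0, sex = 0),
    batch_effects = c(0, 0, 0),
    sd_ln25ohd = 0, mu_ln25ohd = 4.0
  )
  cohort <- simulate_cohort(cfg)
  expect_equal(cohort$ln25ohd, rep(4.0, 50))

  cfg$seasonal_amplitude <- 0.2
  cohort2 <- simulate_cohort(validate_sim_config(cfg))
  season <- 0.2 * cos(2 * pi * (cohort2$month - cfg$peak_month) / 12)
  expect_equal(cohort2$ln25ohd, 4.0 + season)
})

test_that("genotypes follow binomial moments and Hardy-Weinberg proportions", {
  panel <- default_snp_panel()
  panel$eaf <- 0.5
  cohort <- simulate_cohort(sim_config(n = 50000, seed = 5, snps = panel))
  mc_se <- sqrt(2 * 0.5 * 0.5 / 50000)
  for (snp in panel$snp_id) {
    expect_lt(abs(mean(cohort[[snp]]) - 1.0), 3 * mc_se)
  }

  # HWE at the default frequencies, n = 10^4
  cohort <- simulate_cohort(sim_config(n = 10000, seed = 6))
  for (i in seq_len(4)) {
    p <- default_snp_panel()$eaf[i]
    g <- cohort[[default_snp_panel()$snp_id[i]]]
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    observed <- tabulate(g + 1, 3) / 10000
    for (k in 1:3) {
      se_k <- sqrt(expected[k] * (1 - expected[k]) / 10000)
      expect_lt(abs(observed[k] - expected[k]), 4 * se_k)
    }
  }
})

test_that("a single-SNP effect on ln 25(OH)D is recovered by regression", {
  panel <- null_panel()
  panel$beta_ln25ohd[1] <- 0.03
  cohort <- simulate_cohort(sim_config(n = 20000, seed = 7, snps = panel))
  fit <- fit_assoc_linear(cohort, "ln25ohd", panel$snp_id[1])
  expect_lt(abs(fit$beta - 0.03), 3 * fit$se)
})

test_that("fixed seeds reproduce byte-identical cohorts", {
  cfg <- tiny_config(seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sd_sbp = -1), "SDs")
  expect_error(sim_config(mu_ln25ohd = Inf), "finite")
  expect_error(sim_config(treatment_effect_sbp = -5), "treatment")
  expect_error(sim_config(bp_residual_cor = 1.5), "bp_residual_cor")
})

test_that("multi-study generation keeps studies independent and ids distinct", {
  base <- tiny_config(n = 2000, seed = 42)
  cfgs <- replicate_config(base, 2)
  studies <- simulate_studies(cfgs)
  expect_setequal(unique(studies$study_id), c("study_1", "study_2"))

  # same master seed, different study slots -> decorrelated streams
  s1 <- studies$ln25ohd[studies$study_id == "study_1"]
  s2 <- studies$ln25ohd[studies$study_id == "study_2"]
  expect_false(isTRUE(all.equal(s1, s2)))
  expect_lt(abs(cor(s1, s2)), 3 / sqrt(2000))

  # one config reproduces the single-cohort generator exactly
  single <- simulate_studies(list(base))
  expect_identical(single, simulate_cohort(base))

  cfg_dup <- replicate_config(base, 2)
  cfg_dup[[2]]$study_id <- "study_1"
  expect_error(simulate_studies(cfg_dup), "Duplicate study_id")
})

test_that("homogeneous studies show near-zero between-study heterogeneity", {
  cfgs <- replicate_config(tiny_config(n = 1500, seed = 8), 12)
  studies <- simulate_studies(cfgs)
  prepared <- suppressWarnings(add_allele_scores(prepare_phenotypes(studies)))
  per_study <- prepared |>
    dplyr::group_split(study_id) |>
    purrr::map(~ fit_assoc_linear(.x, "ln25ohd", "score_synthesis",
                                  covariates = c("age", "sex", "bmi"))) |>
    purrr::list_rbind()
  m <- meta_fixed(per_study)
  expect_lt(m$i2, 40)          # equal true effects: I^2 should be near 0
  expect_gt(m$p_q, 0.01)
})

test_that("summary-statistic emission matches the regression engine", {
  cohort <- suppressWarnings(prepare_phenotypes(
    simulate_cohort(tiny_config(n = 1200, seed = 21))
  ))
  ss <- emit_summary_stats(cohort, "ln25ohd")
  direct <- fit_assoc_linear(cohort, "ln25ohd", "rs12785878",
                             covariates = c("age", "sex", "bmi", "month", "batch"))
  row <- ss[ss$snp_id == "rs12785878", ]
  expect_identical(row$beta, direct$beta)
  expect_identical(row$se, direct$se)
  expect_equal(row$eaf, mean(cohort$rs12785878) / 2)
  expect_error(emit_summary_stats(cohort, "height"), "Unknown outcome")
})

test_that("per-SNP betas are centred on zero under the null", {
  betas <- purrr::map_dbl(1:30, function(i) {
    cohort <- simulate_cohort(sim_config(n = 400, seed = 1000 + i,
                                         snps = null_panel()))
    fit_assoc_linear(cohort, "ln25ohd", "rs2282679")$beta
  })
  se_mean <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas)), 3 * se_mean)
})
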