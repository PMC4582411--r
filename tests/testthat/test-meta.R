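test_that("fixed-effect pooling matches hand-computed closed forms", {
  one <- meta_fixed(tibble::tibble(beta = 1.2, se = 0.4))
  expect_equal(one$beta, 1.2)
  expect_equal(one$se, 0.4)
  expect_equal(one$q, 0)

  two <- meta_fixed(tibble::tibble(beta = c(1, 1), se = c(0.5, 0.5)))
  expect_equal(two$beta, 1.0, tolerance = 1e-12)
  expect_equal(two$se, 0.5 / sqrt(2), tolerance = 1e-12)

  split <- meta_fixed(tibble::tibble(beta = c(0, 1), se = c(0.1, 0.1)))
  expect_equal(split$beta, 0.5, tolerance = 1e-10)
  expect_equal(split$q, 50, tolerance = 1e-10)
  expect_equal(split$i2, 98, tolerance = 1e-10)
})

test_that("DerSimonian-Laird pooling matches the hand calculation", {
  d <- tibble::tibble(beta = c(0, 1), se = c(0.1, 0.1))
  r <- meta_random(d)
  # sum(w) = 200, sum(w^2)/sum(w) = 100 -> tau2 = (50 - 1)/100 = 0.49
  expect_equal(r$tau2, 0.49, tolerance = 1e-10)
  expect_equal(r$beta, 0.5, tolerance = 1e-10)
  expect_equal(r$se, 0.5, tolerance = 1e-10)

  # homogeneous inputs: tau2 = 0 and results collapse to fixed effects
  h <- tibble::tibble(beta = c(1, 1, 1), se = c(0.2, 0.3, 0.25))
  fx <- meta_fixed(h); rd <- meta_random(h)
  expect_equal(rd$tau2, 0)
  expect_equal(rd$beta, fx$beta)
  expect_equal(rd$se, fx$se)
})

test_that("pooling satisfies its structural invariants", {
  withr::with_seed(4, {
    d <- tibble::tibble(beta = rnorm(8), se = runif(8, 0.1, 0.5))
  })
  fx <- meta_fixed(d); rd <- meta_random(d)
  expect_lte(fx$se, min(d$se))
  expect_gte(rd$se, fx$se)   # se(random) >= se(fixed) when tau2 > 0
  # I^2 invariant to common rescaling
  scaled <- meta_fixed(dplyr::mutate(d, beta = beta * 7, se = se * 7))
  expect_equal(scaled$i2, fx$i2, tolerance = 1e-10)
  expect_error(meta_fixed(d[0, ]), "At least one")
  expect_error(meta_random(d[1, ]), "at least 2")
})

test_that("pooled estimates agree with an independent meta-analysis library", {
  skip_if_not_installed("metafor")
  withr::with_seed(12, {
    d <- tibble::tibble(beta = rnorm(10, 0.3, 0.3), se = runif(10, 0.1, 0.4))
  })
  fx <- meta_fixed(d)
  ref_fx <- metafor::rma(yi = d$beta, sei = d$se, method = "FE")
  expect_equal(fx$beta, as.numeric(ref_fx$beta), tolerance = 1e-8)
  expect_equal(fx$se, ref_fx$se, tolerance = 1e-8)
  expect_equal(fx$q, as.numeric(ref_fx$QE), tolerance = 1e-8)

  rd <- meta_random(d)
  ref_rd <- metafor::rma(yi = d$beta, sei = d$se, method = "DL")
  expect_equal(rd$beta, as.numeric(ref_rd$beta), tolerance = 1e-8)
  expect_equal(rd$se, ref_rd$se, tolerance = 1e-8)
  expect_equal(rd$tau2, ref_rd$tau2, tolerance = 1e-8)
})

test_that("the model-selection rule switches on heterogeneity strictly below alpha", {
  fx <- meta_fixed(tibble::tibble(beta = c(0.1, 0.12), se = c(0.1, 0.1)))
  fx$p_q <- 0.48
  expect_equal(select_model(fx), "fixed")
  fx$p_q <- 0.003
  expect_equal(select_model(fx), "random")
  fx$p_q <- 0.05
  expect_equal(select_model(fx), "fixed")   # boundary: strict inequality

  het <- tibble::tibble(beta = c(0, 1), se = c(0.1, 0.1))
  chosen <- run_meta(het)
  expect_equal(chosen$model, "random")
  expect_equal(chosen$selection$model, "random")
})

test_that("DL tau2 is recovered across simulated meta-analyses", {
  true_tau2 <- 0.04
  tau2_hat <- purrr::map_dbl(1:200, function(i) {
    withr::with_seed(5000 + i, {
      se <- runif(20, 0.1, 0.2)
      beta <- rnorm(20, 0, sqrt(se^2 + true_tau2))
    })
    meta_random(tibble::tibble(beta = beta, se = se))$tau2
  })
  mc_se <- sd(tau2_hat) / sqrt(length(tau2_hat))
  expect_lt(abs(mean(tau2_hat) - true_tau2), 4 * mc_se)
})

test_that("meta-regression handles exact, categorical and degenerate cases", {
  # betas exactly linear in the covariate with equal SEs
  x <- 1:5
  d <- tibble::tibble(beta = 0.2 + 0.5 * x, se = rep(0.1, 5))
  mr <- meta_regression(d, x)
  expect_equal(mr$slope, 0.5, tolerance = 1e-10)
  expect_equal(mr$q_resid, 0, tolerance = 1e-10)
  expect_equal(mr$tau2, 0)

  # two-level covariate, equal SEs: slope is the subgroup mean difference
  g <- c("a", "a", "a", "b", "b", "b")
  d2 <- tibble::tibble(beta = c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8),
                       se = rep(0.15, 6))
  mr2 <- meta_regression(d2, g)
  expect_equal(mr2$slope, mean(d2$beta[4:6]) - mean(d2$beta[1:3]),
               tolerance = 1e-10)

  expect_error(meta_regression(d, rep(1, 5)), "constant")
  expect_error(meta_regression(d[1:2, ], x[1:2]), "at least 3")
})

test_that("meta-regression slope is centred on zero for an unrelated covariate", {
  slopes <- purrr::map_dbl(1:100, function(i) {
    withr::with_seed(7000 + i, {
      se <- runif(10, 0.1, 0.3)
      beta <- rnorm(10, 0.2, se)
      x <- rnorm(10)
    })
    meta_regression(tibble::tibble(beta = beta, se = se), x)$slope
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("meta-regression agrees with an independent method-of-moments fit", {
  skip_if_not_installed("metafor")
  withr::with_seed(77, {
    se <- runif(12, 0.1, 0.3)
    x <- rnorm(12)
    beta <- 0.1 + 0.3 * x + rnorm(12, 0, sqrt(se^2 + 0.02))
  })
  mr <- meta_regression(tibble::tibble(beta = beta, se = se), x)
  ref <- metafor::rma(yi = beta, sei = se, mods = ~x, method = "DL")
  expect_equal(mr$slope, as.numeric(ref$beta[2]), tolerance = 1e-8)
  expect_equal(mr$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(mr$se, ref$se[2], tolerance = 1e-8)
})

test_that("summary-statistic score approximation matches its closed-form cases", {
  panel <- default_snp_panel()
  rows <- tibble::tibble(
    snp_id = c("rs12785878", "rs12794714"),
    eaf = c(0.5, 0.5),
    beta = c(0.1, 0.3),
    se = c(0.02, 0.02)
  )
  approx <- approximate_score_effect(rows, panel, "synthesis")
  expect_equal(approx$beta, 0.2, tolerance = 1e-12)

  # vanishing dosage variance: the other SNP dominates
  rows$eaf <- c(1e-9, 0.5)
  approx2 <- approximate_score_effect(rows, panel, "synthesis")
  expect_equal(approx2$beta, 0.3, tolerance = 1e-6)

  expect_error(approximate_score_effect(rows[1, ], panel, "synthesis"),
               "Missing summary rows")
  rows$eaf[1] <- NA
  expect_error(approximate_score_effect(rows, panel, "synthesis"), "EAF")
})

test_that("consortium combination pools strata and respects limits", {
  cohort_est <- meta_fixed(tibble::tibble(beta = c(0.9, 1.1), se = c(0.2, 0.2)))
  consortium <- tibble::tibble(beta = 1.0, se = 0.1)

  # zero-weight limit: infinite consortium SE returns the cohort result
  unchanged <- combine_with_consortium(
    cohort_est, tibble::tibble(beta = 5, se = Inf))
  expect_equal(unchanged$beta, cohort_est$beta)
  expect_equal(unchanged$se, cohort_est$se)

  # equal betas pool to the same value with a smaller SE
  same <- combine_with_consortium(
    meta_fixed(tibble::tibble(beta = 1, se = 0.2)),
    tibble::tibble(beta = 1, se = 0.1))
  expect_equal(same$beta, 1.0, tolerance = 1e-12)
  expect_lt(same$se, 0.1)

  expect_error(
    combine_with_consortium(
      tibble::tibble(beta = 1, se = 0.1, scale = "per_allele"),
      tibble::tibble(beta = 1, se = 0.1, scale = "per_10pct")),
    "Scale mismatch"
  )
})

test_that("two strata from one truth beat either stratum alone", {
  errs <- purrr::map(1:60, function(i) {
    withr::with_seed(9000 + i, {
      a <- rnorm(1, 0.5, 0.15)
      b <- rnorm(1, 0.5, 0.12)
    })
    pooled <- combine_with_consortium(
      tibble::tibble(beta = a, se = 0.15),
      tibble::tibble(beta = b, se = 0.12))
    tibble::tibble(a = (a - 0.5)^2, b = (b - 0.5)^2,
                   pooled = (pooled$beta - 0.5)^2)
  }) |> purrr::list_rbind()
  expect_lt(mean(errs$pooled), mean(errs$a))
  expect_lt(mean(errs$pooled), mean(errs$b))
})

test_that("tidiers and the forest table expose the pooled result", {
  d <- tibble::tibble(study_id = c("s1", "s2", "s3"),
                      beta = c(0.2, 0.3, 0.25), se = c(0.1, 0.1, 0.1))
  m <- run_meta(d)
  td <- tidy(m)
  expect_equal(td$estimate, m$beta)
  expect_equal(td$conf.high - td$conf.low, 2 * qnorm(0.975) * m$se)
  gl <- glance(m)
  expect_equal(gl$k, 3)
  ft <- forest_table(m)
  expect_equal(nrow(ft), 4)
  expect_equal(sum(ft$weight_pct[!ft$pooled]), 100, tolerance = 1e-10)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})
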