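test_that("linear fit matches exact and closed-form cases", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = 2 * c(1, 2, 3, 4))
  fit <- suppressWarnings(fit_assoc_linear(d, "y", "x"))  # exact fit
  expect_equal(fit$beta, 2.0, tolerance = 1e-12)
  expect_lt(fit$se, 1e-10)

  # orthogonal exposure
  d2 <- tibble::tibble(x = c(-1, 1, -1, 1), y = c(1, 1, -1, -1))
  expect_lt(abs(fit_assoc_linear(d2, "y", "x")$beta), 1e-12)

  # independent closed-form oracle on irregular data
  withr::with_seed(1, {
    x <- rnorm(40); y <- 1.3 + 0.7 * x + rnorm(40)
  })
  fit3 <- fit_assoc_linear(tibble::tibble(x = x, y = y), "y", "x")
  oracle <- ols_oracle(y, x)
  expect_equal(fit3$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(fit3$se, oracle$se, tolerance = 1e-10)
})

test_that("covariates are partialled in the same fit with internal age-squared", {
  cohort <- simulate_cohort(tiny_config(n = 5000, seed = 31))
  fit <- fit_assoc_linear(cohort, "ln25ohd", "rs2282679",
                          covariates = c("age", "sex", "bmi"))
  expect_match(fit$covariates, "age")
  expect_lt(abs(fit$beta - 0.067), 3 * fit$se)

  # a duplicated covariate column is flagged as collinear by name
  dup <- dplyr::mutate(cohort, bmi2 = bmi)
  expect_error(
    fit_assoc_linear(dup, "ln25ohd", "rs2282679",
                     covariates = c("bmi", "bmi2")),
    "collinear.*bmi2"
  )
})

test_that("logistic fit equals the analytic 2x2 log odds ratio", {
  counts <- c(a = 10, b = 20, c = 20, d = 10)
  d <- tibble::tibble(
    x = rep(c(1, 1, 0, 0), counts),
    y = rep(c(1, 0, 1, 0), counts)
  )
  fit <- fit_assoc_logistic(d, "y", "x")
  oracle <- log_or_oracle(10, 20, 20, 10)
  expect_equal(fit$beta, oracle$log_or, tolerance = 1e-6)
  expect_equal(fit$beta, log(0.25), tolerance = 1e-6)
  expect_equal(fit$se, oracle$se, tolerance = 1e-4)
})

test_that("logistic fit recovers a known effect and rejects separation", {
  withr::with_seed(5, {
    x <- rnorm(3000)
    y <- rbinom(3000, 1, plogis(-0.5 + 0.8 * x))
  })
  fit <- fit_assoc_logistic(tibble::tibble(x = x, y = y), "y", "x")
  expect_lt(abs(fit$beta - 0.8), 3 * fit$se)

  sep <- tibble::tibble(x = c(-(5:1), 1:5), y = rep(c(0, 1), each = 5))
  expect_error(fit_assoc_logistic(sep, "y", "x"), "separation")
  expect_error(
    fit_assoc_logistic(tibble::tibble(x = 1:5, y = rep(1, 5)), "y", "x"),
    "Both outcome classes"
  )
})

test_that("fits are invariant to row order and covariate order", {
  cohort <- simulate_cohort(tiny_config(n = 800, seed = 17))
  f1 <- fit_assoc_linear(cohort, "ln25ohd", "rs12785878",
                         covariates = c("age", "sex", "bmi"))
  shuffled <- cohort[withr::with_seed(1, sample(nrow(cohort))), ]
  f2 <- fit_assoc_linear(shuffled, "ln25ohd", "rs12785878",
                         covariates = c("bmi", "age", "sex"))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
  expect_equal(f2$se, f1$se, tolerance = 1e-10)
})

test_that("the battery emits the full per-study model grid", {
  cohort <- simulate_cohort(tiny_config(n = 1000, seed = 23))
  res <- quiet_battery(cohort)
  # (4 SNPs + 2 scores) x 4 outcomes + 3 phenotypic models
  expect_equal(nrow(res), 6 * 4 + 3)
  expect_setequal(
    unique(res$outcome),
    c("ln25ohd", "sbp_adj", "dbp_adj", "hypertension")
  )
  expect_true(all(res$se > 0))
  expect_true(all(res$study_id == "study_1"))
  # hypertension rows are on the log-odds scale
  expect_true(all(grepl("log_odds", res$scale[res$outcome == "hypertension"])))
})

test_that("score beta equals the variance-weighted per-SNP combination in an orthogonal design", {
  # balanced factorial over both dosages: sample covariance is exactly zero
  grid <- tidyr::expand_grid(g1 = 0:2, g2 = 0:2, rep = 1:4)
  withr::with_seed(9, {
    y <- 0.4 * grid$g1 + 0.1 * grid$g2 + rnorm(nrow(grid))
  })
  d <- tibble::tibble(g1 = grid$g1, g2 = grid$g2, score = grid$g1 + grid$g2,
                      y = y)
  b1 <- fit_assoc_linear(d, "y", "g1")$beta
  b2 <- fit_assoc_linear(d, "y", "g2")$beta
  bs <- fit_assoc_linear(d, "y", "score")$beta
  v1 <- var(d$g1); v2 <- var(d$g2)
  expect_equal(bs, (v1 * b1 + v2 * b2) / (v1 + v2), tolerance = 1e-10)
})

test_that("null simulations give nominal type-I error for the exposure test", {
  pvals <- purrr::map_dbl(1:200, function(i) {
    withr::with_seed(3000 + i, {
      x <- rnorm(150)
      y <- rnorm(150)
    })
    fit <- fit_assoc_linear(tibble::tibble(x = x, y = y), "y", "x")
    2 * pnorm(-abs(fit$beta / fit$se))
  })
  rejections <- sum(pvals < 0.05)
  # binomial(200, 0.05): central 99.9% range
  expect_gte(rejections, 1)
  expect_lte(rejections, 22)
})
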