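# Shared fixtures and independent oracles used across test files.

# A quiet, quick cohort config.
tiny_config <- function(n = 500, seed = 1, ...) {
  sim_config(n = n, seed = seed, ...)
}

# Panel with zeroed genetic effects (pure-noise biomarker).
null_panel <- function() {
  p <- default_snp_panel()
  p$beta_ln25ohd <- 0
  p
}

# Closed-form simple / two-variable weighted least squares, written
# independently of the lm-based engine.
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  b <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% b
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  list(beta = unname(b[2, 1]), se = unname(sqrt(s2 * xtx_inv[2, 2])))
}

# Analytic 2x2 log odds ratio and its SE.
log_or_oracle <- function(a, b, c, d) {
  list(log_or = log((a / b) / (c / d)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# Parametric-bootstrap SE of the per-10% Wald ratio.
bootstrap_ratio_se <- function(beta_zy, se_zy, beta_zx, se_zx,
                               n_draws = 1e5, seed = 42) {
  withr::with_seed(seed, {
    num <- rnorm(n_draws, beta_zy, se_zy)
    den <- rnorm(n_draws, beta_zx, se_zx)
    sd(num / den * 10)
  })
}

# Suppress the expected preparation chatter in bulk simulations.
quiet_battery <- function(...) {
  suppressMessages(suppressWarnings(study_association_battery(...)))
}
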