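#' Tidy a meta-analysis result
#'
#' @param x A `vitdmr_meta` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
tidy.vitdmr_meta <- function(x, ...) {
  tibble::tibble(
    term = "pooled",
    estimate = x$beta,
    std.error = x$se,
    conf.low = x$beta - qnorm(0.975) * x$se,
    conf.high = x$beta + qnorm(0.975) * x$se,
    p.value = 2 * pnorm(-abs(x$beta / x$se))
  )
}

#' Model-level summary of a meta-analysis result
#'
#' @inheritParams tidy.vitdmr_meta
#' @return A one-row tibble with the model used, number of studies, and
#'   heterogeneity statistics (`q`, `df`, `p.q`, `i2`, `tau2`).
#' @export
glance.vitdmr_meta <- function(x, ...) {
  tibble::tibble(
    model = x$model, k = x$k,
    q = x$q, df = x$df, p.q = x$p_q, i2 = x$i2, tau2 = x$tau2
  )
}

#' Tidy an instrumental-variable estimate
#'
#' @param x A `vitdmr_iv` object.
#' @param ... Unused.
#' @return A one-row tibble on the per-10%-increase scale; binary outcomes
#'   additionally carry the odds-ratio columns.
#' @export
tidy.vitdmr_iv <- function(x, ...) {
  out <- tibble::tibble(
    term = "iv_ratio_per_10pct",
    outcome = x$outcome,
    estimate = x$ratio,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.value = x$p
  )
  if (isTRUE(x$binary)) {
    out$odds.ratio <- x$or
    out$or.conf.low <- x$or_ci_low
    out$or.conf.high <- x$or_ci_high
  }
  out
}

#' Model-level summary of an instrumental-variable estimate
#'
#' @inheritParams tidy.vitdmr_iv
#' @return A one-row tibble noting the outcome type and the covariance
#'   assumption behind the delta-method variance.
#' @export
glance.vitdmr_iv <- function(x, ...) {
  tibble::tibble(
    binary = x$binary,
    covariance_assumption = x$covariance_assumption
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
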