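#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a meta-analysis
#'
#' Per-study estimates with 95% intervals, point size proportional to
#' meta-analytic weight, and the pooled estimate below.
#'
#' @param object A `vitdmr_meta`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vitdmr_meta <- function(object, ...) {
  d <- forest_table(object)
  d$study <- factor(d$study, levels = rev(d$study))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$study)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$beta, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_pct,
                                     shape = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = "effect estimate (95% CI)", y = NULL,
      subtitle = sprintf("%s effects; Q = %.2f (p = %.3g), I² = %.0f%%",
                         object$model, object$q, object$p_q, object$i2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a triangulation table
#'
#' Displays, per outcome, the phenotypic, genetic (per-allele) and
#' instrumental-variable estimates with 95% intervals. Binary outcomes are
#' drawn on the odds-ratio scale with a null line at 1; continuous outcomes
#' in mm Hg with a null line at 0.
#'
#' @param triangulation Output of [triangulate()].
#' @return A ggplot object.
#' @export
plot_triangulation <- function(triangulation) {
  long <- tidyr::pivot_longer(
    triangulation,
    cols = c("phenotypic", "genetic_per_allele", "iv_estimate"),
    names_to = "analysis", values_to = "estimate"
  )
  ci <- tibble::tibble(
    analysis = rep(c("phenotypic", "genetic_per_allele", "iv_estimate"),
                   each = nrow(triangulation)),
    outcome = rep(triangulation$outcome, 3),
    low = c(triangulation$phenotypic_ci_low, triangulation$genetic_ci_low,
            triangulation$iv_ci_low),
    high = c(triangulation$phenotypic_ci_high, triangulation$genetic_ci_high,
             triangulation$iv_ci_high)
  )
  long <- dplyr::left_join(long, ci, by = c("analysis", "outcome"))
  null_df <- dplyr::distinct(
    dplyr::mutate(long, null = ifelse(.data$binary, 1, 0)),
    .data$outcome, .data$null
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$analysis)) +
    ggplot2::geom_vline(data = null_df,
                        ggplot2::aes(xintercept = .data$null),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$low, xmax = .data$high),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
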