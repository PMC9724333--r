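#' Love plot of covariate balance
#'
#' Dot plot of the standardized mean difference per covariate with the
#' conventional 10% minor-difference threshold marked.
#'
#' @param object An `hb_balance` from [balance_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hb_balance <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !.data$incomputable)
  d$variable <- factor(d$variable, levels = rev(d$variable))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$smd_percent,
                                  y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 10, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Standardized mean difference (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Propensity-score overlap box plot
#'
#' @param object An `hb_overlap` from [overlap_summary()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hb_overlap <- function(object, ...) {
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$group, y = .data$ps)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Propensity score") +
    ggplot2::theme_minimal()
  if (object$has_overlap) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = object$overlap_low,
                               ymax = object$overlap_high,
                               alpha = 0.12, fill = "steelblue")
  }
  p
}

#' Forest plot of effect estimates across analysis datasets
#'
#' Odds ratios with 95% confidence intervals on a log scale, one row per
#' analysis dataset; non-estimable datasets are omitted.
#'
#' @param object An `hb_report` from [generate_report()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hb_report <- function(object, ...) {
  d <- dplyr::filter(object$effects, .data$estimable)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
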