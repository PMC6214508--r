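#' Kaplan-Meier plot of a stratification
#'
#' Step curves of metastasis-free probability for the low- and high-risk
#' arms, annotated with the log-rank p-value and hazard ratio.
#'
#' @param x a `stratification_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.stratification_result <- function(x, ...) {
  if (!is.null(x$error)) stop("stratification failed: ", x$error)
  lab <- sprintf("log-rank p = %.3g\nHR (low vs high) = %.2f",
                 x$logrank_p, x$hazard_ratio_low_vs_high)
  ggplot2::ggplot(x$km,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::annotate("text", x = max(x$km$time), y = 1, hjust = 1,
                      vjust = 1, label = lab, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Metastasis-free probability",
                  colour = "Risk group") +
    ggplot2::theme_minimal()
}

#' Univariable screen plot
#'
#' Dot plot of the oriented concordance of each screened feature, filled by
#' FDR significance, in the style of a univariable radiomics panel.
#'
#' @param screen a [univariable_screen()] tibble (optionally with a
#'   `region` column).
#' @return A ggplot.
#' @export
plot_univariable <- function(screen) {
  screen <- dplyr::mutate(screen,
                          feature = stats::reorder(.data$feature,
                                                   .data$ci_oriented))
  p <- ggplot2::ggplot(screen,
                       ggplot2::aes(x = .data$ci_oriented, y = .data$feature,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "Concordance index (oriented)", y = NULL,
                  colour = "FDR < alpha") +
    ggplot2::theme_minimal()
  if ("region" %in% names(screen)) {
    p <- p + ggplot2::facet_wrap(~region, scales = "free_y")
  }
  p
}

#' Validation concordance plot for a study
#'
#' Point-and-error-bar display of every model's validation concordance.
#'
#' @param x a `periomics_study`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.periomics_study <- function(x, ...) {
  v <- dplyr::mutate(x$validation,
                     model = stats::reorder(.data$model, .data$ci))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$model, y = .data$ci)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci - .data$se,
                                        ymax = .data$ci + .data$se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Validation concordance index") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
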