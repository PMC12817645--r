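# Optional figure rendering on top of the deterministic plot-data tables.
# All plots are thin ggplot2 layers over plot_exports(); ggplot2 is a
# suggested dependency.

utils::globalVariables(".data")

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for rendering; use plot_exports() for the data")
}

#' Scatter plot of outcome vs exposure effects with method fit lines
#' @param exports Output of [plot_exports()].
#' @return A ggplot object.
#' @export
mr_scatter_plot <- function(exports) {
  need_ggplot2()
  p <- exports$scatter_points; l <- exports$scatter_lines
  ggplot2::ggplot(p, ggplot2::aes(x = .data$beta_exposure,
                                  y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - 1.96 * .data$se_outcome,
      ymax = .data$beta_outcome + 1.96 * .data$se_outcome),
      width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - 1.96 * .data$se_exposure,
      xmax = .data$beta_exposure + 1.96 * .data$se_exposure),
      height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = l, ggplot2::aes(
      slope = .data$slope, intercept = .data$intercept,
      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "MR method") +
    ggplot2::theme_minimal()
}

#' Funnel plot of Wald ratios against precision
#' @param exports Output of [plot_exports()].
#' @return A ggplot object.
#' @export
mr_funnel_plot <- function(exports) {
  need_ggplot2()
  ggplot2::ggplot(exports$funnel_points,
                  ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(data = exports$funnel_lines,
                        ggplot2::aes(xintercept = .data$beta,
                                     colour = .data$method)) +
    ggplot2::labs(x = "Wald ratio", y = "1 / SE", colour = "MR method") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-SNP ratios and combined estimates
#' @param exports Output of [plot_exports()].
#' @return A ggplot object.
#' @export
mr_forest_plot <- function(exports) {
  need_ggplot2()
  f <- exports$forest
  f$label <- factor(f$label, levels = rev(f$label))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$beta, y = .data$label,
                                  colour = .data$type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal estimate", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Leave-one-out plot
#' @param exports Output of [plot_exports()].
#' @return A ggplot object.
#' @export
mr_loo_plot <- function(exports) {
  need_ggplot2()
  l <- exports$loo
  if (is.null(l)) stop("no leave-one-out table in exports")
  l$excluded_rsid <- factor(l$excluded_rsid, levels = rev(l$excluded_rsid))
  ggplot2::ggplot(l, ggplot2::aes(x = .data$beta, y = .data$excluded_rsid)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                                         xmax = .data$beta + 1.96 * .data$se),
                            height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate excluding the SNP", y = NULL) +
    ggplot2::theme_minimal()
}
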