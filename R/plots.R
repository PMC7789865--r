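#' Neutrality plot (GC12 vs GC3)
#'
#' Scatter of per-gene GC12 against GC3 with the fitted regression line and
#' the identity line for reference.
#'
#' @param metrics Tibble with `gc3` and `gc12` columns.
#' @return A ggplot object.
#' @export
plot_neutrality <- function(metrics) {
  fit <- neutrality_regression(metrics)
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "GC3", y = "GC12",
      title = sprintf("Neutrality plot: slope %.3f, r = %.3f",
                      fit$slope, fit$r)
    ) +
    ggplot2::theme_minimal()
}

#' ENc vs GC3s plot with the expected curve
#'
#' @param metrics Tibble with `gc3s` and `enc` columns.
#' @return A ggplot object.
#' @export
plot_enc_gc3s <- function(metrics) {
  curve <- tibble::tibble(gc3s = seq(0, 1, by = 0.005))
  curve$enc <- expected_enc(curve$gc3s)
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$gc3s, y = .data$enc)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(20, 62)) +
    ggplot2::labs(x = "GC3s", y = "ENc",
                  title = "ENc vs GC3s with compositional expectation") +
    ggplot2::theme_minimal()
}

#' PR2 bias plot
#'
#' @param pr2 A `pr2_analysis` object, or a composition tibble to analyse.
#' @return A ggplot object.
#' @export
plot_pr2 <- function(pr2) {
  if (!inherits(pr2, "pr2_analysis")) pr2 <- pr2_analysis(pr2)
  ggplot2::ggplot(tidy(pr2), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3 / (G3 + C3)", y = "A3 / (A3 + U3)",
                  title = "Parity-rule-2 bias plot") +
    ggplot2::theme_minimal()
}

#' CAI vs ENc plot
#'
#' @param metrics Tibble with `enc` and `cai` columns.
#' @return A ggplot object.
#' @export
plot_cai_enc <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$enc, y = .data$cai)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "ENc", y = "CAI", title = "CAI vs ENc") +
    ggplot2::theme_minimal()
}

#' GC-content distribution
#'
#' @param composition Tibble from [codon_composition()] or [gene_metrics()].
#' @param width Bin width in percent.
#' @return A ggplot object.
#' @export
plot_gc_distribution <- function(composition, width = 2.5) {
  h <- gc_histogram(composition, width = width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$n)) +
    ggplot2::geom_col(width = width * 0.9, fill = "steelblue") +
    ggplot2::labs(x = "GC content (%)", y = "Number of genes",
                  title = "Distribution of per-gene GC content") +
    ggplot2::theme_minimal()
}

#' Correspondence-analysis gene map
#'
#' Plots genes on the first two CA axes, optionally coloured by GC class.
#'
#' @param object A `coa_result`.
#' @param gc_all Optional per-gene overall GC fractions (same order as the
#'   CA input rows) for the conventional three-class colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coa_result <- function(object, gc_all = NULL, ...) {
  d <- object$gene_coords
  if (object$n_axes < 2) stop("need at least 2 retained axes", call. = FALSE)
  lab <- sprintf("Axis %d (%.1f%%)", 1:2, 100 * object$inertia$fraction[1:2])
  p <- if (is.null(gc_all)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
      ggplot2::geom_point(alpha = 0.6, size = 0.9)
  } else {
    d$gc_class <- gc_class(gc_all)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                    colour = .data$gc_class)) +
      ggplot2::geom_point(alpha = 0.7, size = 0.9) +
      ggplot2::labs(colour = "GC content")
  }
  p + ggplot2::labs(x = lab[1], y = lab[2],
                    title = "Correspondence analysis of RSCU") +
    ggplot2::theme_minimal()
}
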