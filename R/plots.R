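# ggplot2 displays for the main result types.

#' Plot PCA sample scores
#'
#' Scatter of the first two components (or any pair), coloured by
#' population when the design was supplied to [genotype_pca()], with
#' variance-explained percentages on the axes.
#'
#' @param object An `altipop_pca`.
#' @param components Length-2 integer vector (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot altipop_pca
#' @export
autoplot.altipop_pca <- function(object, components = c(1, 2), ...) {
  xc <- paste0("PC", components[1]); yc <- paste0("PC", components[2])
  ve <- round(100 * object$var_explained[components], 2)
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data[[xc]], y = .data[[yc]]))
  p <- if ("population" %in% names(object$scores)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$population), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::labs(x = sprintf("%s (%.2f%%)", xc, ve[1]),
                  y = sprintf("%s (%.2f%%)", yc, ve[2])) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a pairwise DEG table
#'
#' @param de_tbl Output of [call_degs()] (or [de_test()]).
#' @param alpha,fc_min Cutoff guides drawn on the plot.
#' @return A ggplot of log2 fold change against -log10 adjusted p.
#' @export
plot_volcano <- function(de_tbl, alpha = 0.05, fc_min = 1) {
  v <- volcano_table(de_tbl)
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$log2fc,
                                       y = .data$neg_log10_p_adj))
  p <- if ("call" %in% names(v)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$call), alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(up = "red", down = "blue", ns = "grey60"))
  } else {
    p + ggplot2::geom_point(alpha = 0.6)
  }
  p +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-fc_min, fc_min), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Plot ABC posterior marginals
#'
#' Histograms of the accepted parameter draws, one facet per parameter.
#'
#' @param object An `altipop_abc`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot altipop_abc
#' @export
autoplot.altipop_abc <- function(object, bins = 40, ...) {
  long <- tidyr::pivot_longer(object$accepted,
                              cols = -dplyr::any_of("distance"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "accepted value", y = "count") +
    ggplot2::theme_minimal()
}

#' Forest plot of a random-effects meta-analysis
#'
#' Per-study effects with 95% intervals and the pooled estimate.
#'
#' @param object An `altipop_meta`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot altipop_meta
#' @export
autoplot.altipop_meta <- function(object, ...) {
  w <- object$weights
  w$lo <- w$g - 1.959964 * sqrt(w$var_g)
  w$hi <- w$g + 1.959964 * sqrt(w$var_g)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$g, y = .data$study)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = object$pooled, colour = "red") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(x = "Hedges' g", y = NULL) +
    ggplot2::theme_minimal()
}
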