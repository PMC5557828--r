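#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_segment geom_point labs scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Histogram of normalized ratios coloured by band
#'
#' The expected tri-modal structure under XX/XY: Y-candidate fragments pile
#' up near 0, autosomal fragments near 1, X-linked fragments near 2. Dashed
#' lines mark the Y threshold.
#'
#' @param object An `fr_ratios` table from [compute_ratios()].
#' @param binwidth Histogram bin width on `r_norm` (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fr_ratios
#' @export
autoplot.fr_ratios <- function(object, binwidth = 0.05, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$r_norm), ]
  y_max <- attr(object, "y_max") %||% 0.3
  ggplot(df, aes(x = .data$r_norm, fill = .data$band)) +
    geom_histogram(binwidth = binwidth, boundary = 0) +
    geom_vline(xintercept = y_max, linetype = "dashed") +
    labs(x = "normalized female:male ratio (r_norm)", y = "fragments",
         fill = "band") +
    theme_minimal()
}

#' Per-scaffold enrichment plot
#'
#' Lollipop plot of -log10 P per scaffold, with the significance level as a
#' dashed line.
#'
#' @param object An `fr_enrichment` from [enrich_scaffolds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fr_enrichment
#' @export
autoplot.fr_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  df$scaffold_id <- stats::reorder(df$scaffold_id, -df$log10_p)
  alpha <- attr(object, "alpha") %||% 1e-5
  ggplot(df, aes(x = .data$scaffold_id, y = -.data$log10_p,
                 colour = .data$enriched)) +
    geom_segment(aes(xend = .data$scaffold_id, yend = 0)) +
    geom_point() +
    geom_vline(xintercept = 0, linetype = "blank") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(x = NULL, y = "-log10 P (upper-tail hypergeometric)",
         colour = paste0("p < ", format(alpha))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname autoplot.fr_ratios
#' @param ratios An `fr_ratios` table.
#' @export
plot_ratio_hist <- function(ratios, binwidth = 0.05) {
  autoplot.fr_ratios(ratios, binwidth = binwidth)
}
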