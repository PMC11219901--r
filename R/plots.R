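# ggplot2 displays for the result objects: volcano plot for differential
# abundance, bar chart for term enrichment, region bars for Venn counts.

#' Volcano plot of a differential-abundance result
#'
#' Log2 fold change against `-log10(p)`, with the conventional dashed line
#' at raw `p = 0.05` (`y = 1.3`) and points coloured by significance class.
#'
#' @param object A `diff_abund` or `volcano_table`.
#' @param fc_threshold,alpha,p_column Passed to [volcano_table()] when
#'   `object` is a raw `diff_abund` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diff_abund <- function(object, fc_threshold = 0, alpha = 0.05,
                                p_column = "p_adj", ...) {
  vt <- volcano_table(object, fc_threshold = fc_threshold, alpha = alpha,
                      p_column = p_column)
  autoplot(vt, ...)
}

#' @rdname autoplot.diff_abund
#' @export
autoplot.volcano_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neg_log10_raw_p <- neg_log10(df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = .data$neg_log10_raw_p,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::geom_hline(yintercept = neg_log10_threshold(0.05),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2c6fbb", ns = "grey60"),
      drop = FALSE) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ italic(p)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of enriched terms
#'
#' `-log10` of the BH-adjusted p-value per term, with the significance
#' threshold at 1.3 marked.
#'
#' @param object An `enrichment_result`.
#' @param top Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$term_name <- factor(df$term_name,
                         levels = rev(unique(df$term_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neg_log10_p_adj,
                                   y = .data$term_name,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = neg_log10_threshold(
      attr(object, "alpha") %||% 0.05), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c6fbb",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted" ~ italic(p)),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn region counts
#'
#' @param counts Output of [venn_counts()].
#' @return A ggplot object showing the exclusive regions.
#' @export
plot_venn_counts <- function(counts) {
  df <- counts[!grepl("^total_|^union$", counts$region), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "#2c6fbb") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "proteins") +
    ggplot2::theme_minimal()
}
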