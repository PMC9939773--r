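#' Plot pscnet results
#'
#' `autoplot()` methods give each result type its standard display: a volcano
#' plot for the DE screen, a ranked -log10(p) bar chart for enrichment, and a
#' degree lollipop of the top hub lncRNAs for the co-expression network.
#'
#' @param object A pscnet result object.
#' @param ... Passed on to the method (`k` for the network hub count,
#'   `n_terms` for enrichment).
#' @return A ggplot object.
#' @name pscnet_plots
NULL

#' @rdname pscnet_plots
#' @export
autoplot.de_result <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(neg_log10_p = -log10(pmax(.data$p_value, .Machine$double.xmin)))
  p <- attr(object, "params")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-log2(p$fc_min), log2(p$fc_min)),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pscnet_plots
#' @param n_terms Terms shown (default 20).
#' @export
autoplot.enrich_result <- function(object, n_terms = 20, ...) {
  d <- as_tibble(object) %>%
    arrange(.data$p_value, .data$term_id) %>%
    slice_head(n = n_terms) %>%
    mutate(term_id = factor(.data$term_id, levels = rev(.data$term_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$neg_log10_p, y = .data$term_id,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#27ae60", `FALSE` = "grey70")) +
    ggplot2::labs(x = "-log10 p", y = NULL, fill = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @rdname pscnet_plots
#' @param k Hubs shown (default 10).
#' @export
autoplot.coex_network <- function(object, k = 10, ...) {
  d <- top_hubs(object, k = k) %>%
    mutate(gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$gene_id)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$gene_id),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2.5, colour = "#2c3e50") +
    ggplot2::labs(x = "connectivity degree", y = NULL,
                  title = "Top hub lncRNAs") +
    ggplot2::theme_minimal()
}
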