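#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_point
#'   geom_segment scale_fill_manual labs theme_minimal coord_flip
NULL

#' @export
ggplot2::autoplot

direction_palette <- c(
  UP = "#c0392b", DOWN = "#2e6da4", UNCHANGED = "grey90"
)

#' Heatmap of per-contrast regulation calls
#'
#' One tile per protein and contrast, shaded by call direction (red up, blue
#' down), restricted to proteins differential in at least one contrast --
#' the summary view of the screening stage.
#'
#' @param object A `protein_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_screen <- function(object, ...) {
  calls <- object$calls
  keep <- unique(calls$gene_symbol[calls$differential])
  calls <- calls[calls$gene_symbol %in% keep, , drop = FALSE]
  ggplot(calls, aes(
    x = factor(.data$contrast, levels = ret_contrasts()),
    y = .data$gene_symbol, fill = .data$direction
  )) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = direction_palette) +
    labs(
      x = NULL, y = NULL, fill = "Call",
      title = "Differential regulation across contrasts"
    ) +
    theme_minimal()
}

#' Bar chart of top enriched terms
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  d <- utils::head(as.data.frame(object), top)
  d$term_id <- factor(d$term_id, levels = rev(d$term_id))
  ggplot(d, aes(x = .data$term_id, y = -log10(.data$q), fill = .data$significant)) +
    geom_col() +
    coord_flip() +
    scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70")) +
    labs(
      x = NULL, y = expression(-log[10] ~ FDR ~ q),
      title = "Over-represented gene sets"
    ) +
    theme_minimal()
}

#' Lollipop chart of hub betweenness
#'
#' @param object A `hub_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hub_ranking <- function(object, ...) {
  d <- as.data.frame(object)
  d$symbol <- factor(d$symbol, levels = rev(d$symbol))
  ggplot(d, aes(x = .data$symbol, y = .data$betweenness)) +
    geom_segment(aes(xend = .data$symbol, yend = 0), colour = "grey60") +
    geom_point(aes(size = .data$is_top_hub, colour = .data$is_seed)) +
    coord_flip() +
    labs(
      x = NULL, y = "Betweenness centrality",
      title = "Hub proteins (top ranked largest)"
    ) +
    theme_minimal()
}

#' Category counts for concordance or reversal tables
#'
#' @param object A `concordance_table` or `reversal_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reversal_table <- function(object, ...) {
  plot_category_counts(object, "RET reversal of baseline age dysregulation")
}

#' @rdname autoplot.reversal_table
#' @export
autoplot.concordance_table <- function(object, ...) {
  plot_category_counts(object, "RET-response concordance between ages")
}

plot_category_counts <- function(object, title) {
  d <- category_counts(object)
  ggplot(d, aes(x = .data$category, y = .data$n)) +
    geom_col(fill = "#2e6da4") +
    coord_flip() +
    labs(x = NULL, y = "Proteins", title = title) +
    theme_minimal()
}
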