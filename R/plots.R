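# Figures: karyomorphology scatter, per-type box plots, NOR tree display.

#' Karyomorphology scatter of a karyotype summary
#'
#' Median centromeric index (x) against median relative length (y) per
#' chromosome type, coloured by subgenome, with dashed guides at the Levan
#' category boundaries (12.5, 25, 37.5).
#'
#' @param object A `karyo_summary` from [aggregate_karyotype()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.karyo_summary <- function(object, ...) {
  wide <- as_tibble(object) %>%
    filter(.data$metric %in% c("i", "l_pct")) %>%
    select("type", "metric", "Q2") %>%
    tidyr::pivot_wider(names_from = "metric", values_from = "Q2") %>%
    mutate(subgenome = subgenome_of(.data$type))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$i, y = .data$l_pct,
                                     colour = .data$subgenome,
                                     label = .data$type)) +
    ggplot2::geom_vline(xintercept = c(12.5, 25, 37.5), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::xlim(0, 50) +
    ggplot2::labs(x = "centromeric index (i)",
                  y = "chromosome length (% of metaphase)",
                  colour = "subgenome") +
    ggplot2::theme_minimal()
}

#' Per-type box plots of a chromosome metric
#'
#' Distribution of `l_pct` or `i` per assigned chromosome type across
#' metaphases, homeolog pairs adjacent, coloured by subgenome.
#'
#' @param metrics Metrics tibble with `assigned_type`.
#' @param metric `"l_pct"` or `"i"`.
#' @return A ggplot object.
#' @export
plot_metric_boxes <- function(metrics, metric = c("l_pct", "i")) {
  metric <- arg_match(metric)
  df <- metrics %>%
    mutate(type = .data$assigned_type,
           subgenome = subgenome_of(.data$type),
           value = .data[[metric]])
  ord <- unique(df$type)[ref_order(unique(df$type))]
  df$type <- factor(df$type, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$value,
                                   fill = .data$subgenome)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = metric, fill = "subgenome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a NOR parsimony result on its tree
#'
#' Draws the pruned species tree with leaf states and the most-parsimonious
#' state set at each internal node.
#'
#' @param result A `nor_parsimony` object.
#' @param ... Passed to [ape::plot.phylo()].
#' @return `result`, invisibly.
#' @export
plot_nor_tree <- function(result, ...) {
  stopifnot(inherits(result, "nor_parsimony"))
  tree <- result$tree
  ape::plot.phylo(tree, ...)
  n_tip <- ape::Ntip(tree)
  ape::tiplabels(result$reconstruction[seq_len(n_tip)], adj = -0.3,
                 frame = "none", col = "darkblue", cex = 0.7)
  sets <- vapply(result$node_sets[(n_tip + 1):(n_tip + tree$Nnode)],
                 paste, character(1), collapse = "|")
  ape::nodelabels(sets, frame = "rect", bg = "lightyellow", cex = 0.6)
  invisible(result)
}
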