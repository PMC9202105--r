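#' Plot per-node novel orthogroup counts
#'
#' Bar chart of the number of orthogroups assigned to each ladder node, in
#' ladder (root-to-tip) order, with the unassigned remainder shown last.
#'
#' @param object A `novelty_calls` tibble from [assign_origin()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.novelty_calls <- function(object, ...) {
  tal <- tally_origins(object)
  tal$origin_node <- factor(tal$origin_node, levels = tal$origin_node)
  ggplot2::ggplot(tal, ggplot2::aes(x = .data$origin_node, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "orthogroups",
                  title = "Orthogroup origin assignments") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot a label-enrichment comparison
#'
#' Percentage of labeled proteins among novel vs non-novel proteins, the
#' visual companion to the 2x2 Fisher test.
#'
#' @param object An `og_enrichment` object from [label_enrichment()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.og_enrichment <- function(object, ...) {
  tab <- object$table
  df <- tibble::tibble(
    group = factor(c("novel", "non-novel"), levels = c("novel", "non-novel")),
    pct = 100 * c(tab[1, 1] / sum(tab[1, ]), tab[2, 1] / sum(tab[2, ]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pct)) +
    ggplot2::geom_col(fill = c("firebrick", "grey60")) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% labeled",
                  subtitle = sprintf("two-sided Fisher p = %.3g", object$p_two_sided)) +
    ggplot2::theme_minimal()
}

#' Plot dual-origin categories per phylum
#'
#' Stacked bar chart of species counts per phylum, split by dual-origin
#' category (coexistence, replacement, eukaryotic-only, full loss).
#'
#' @param object A `dual_origin_summary` from [summarize_dual_origin()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dual_origin_summary <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phylum, y = .data$n,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "species", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot the component-size distribution of an interaction graph
#'
#' @param object A [ppi_graph()].
#' @param min_size Smallest component size to display (default 2).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ppi_graph <- function(object, min_size = 2, ...) {
  comps <- components_min_size(object, min_size = min_size)
  df <- tibble::tibble(
    component = factor(seq_along(comps)),
    size = lengths(comps)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$size)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "component (size rank)", y = "proteins",
                  title = sprintf("%d components with >= %d proteins",
                                  length(comps), min_size)) +
    ggplot2::theme_minimal()
}
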