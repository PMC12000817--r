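# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot relative synonymous codon usage
#'
#' Bar chart of RSCU per codon, grouped by amino-acid family, with the
#' no-bias line at RSCU = 1 — the usual codon-bias figure for a
#' mitogenome's pooled protein-coding genes.
#'
#' @param object An `rscu_table` from [rscu()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot rscu_table
#' @export
autoplot.rscu_table <- function(object, ...) {
  dat <- dplyr::filter(object, !.data$family_unused)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$codon, y = .data$rscu, fill = .data$amino_acid)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_grid(
      cols = ggplot2::vars(.data$amino_acid),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(
      x = NULL, y = "RSCU",
      title = "Relative synonymous codon usage"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a per-region SSR census
#'
#' Stacked bars of repeat counts per annotated region by motif-length
#' class.
#'
#' @param census A census tibble from [ssr_census()].
#' @return A ggplot object.
#' @export
plot_ssr_census <- function(census) {
  dat <- census |>
    filter(.data$region != "Total") |>
    tidyr::pivot_longer(
      cols = c("MRS", "DRS", "TriRS", "TetRS", "microsatellite"),
      names_to = "class", values_to = "n"
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = stats::reorder(.data$region, .data$n, sum),
      y = .data$n, fill = .data$class
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "perfect repeats", fill = "motif class",
      title = "Microsatellites per region"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise distance matrix
#'
#' Heatmap of the long-format distances for one gene (or the
#' concatenation).
#'
#' @param object A `mito_dist` tibble from [distance_matrix()].
#' @param gene Which gene's rows to draw; default the first present.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot mito_dist
#' @export
autoplot.mito_dist <- function(object, gene = NULL, ...) {
  gene <- gene %||% object$gene[[1L]]
  d <- object[object$gene == gene, ]
  both <- bind_rows(
    d,
    d |> rename(taxon_a = "taxon_b", taxon_b = "taxon_a")
  )
  ggplot2::ggplot(
    both,
    ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b, fill = .data$distance)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$distance)), size = 2.6
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "distance (%)",
      title = paste0("Pairwise p-distance: ", gene)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
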