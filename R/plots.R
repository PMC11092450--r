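#' Volcano-style plot of differential transcript usage results
#'
#' Gene-level effect size (for switching genes) or maximum usage difference
#' against the negative log10 adjusted p-value, with the significance
#' cutoff drawn.
#'
#' @param object A `dtu_results` object.
#' @param alpha Adjusted-p significance cutoff to draw (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dtu_results <- function(object, alpha = 0.01, ...) {
  genes <- object$genes |> dplyr::filter(!.data$excluded)
  usage_diff <- object$transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(max_diff = max(abs(.data$pi_A - .data$pi_B)))
  df <- dplyr::left_join(genes, usage_diff, by = "gene_id") |>
    dplyr::mutate(
      effect = dplyr::coalesce(.data$effect_size, .data$max_diff),
      neglog_p = -log10(pmax(.data$padj_gene, 1e-300)),
      significant = .data$padj_gene <= alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$neglog_p,
                                   colour = .data$significant,
                                   shape = .data$switching)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "effect size (usage difference)",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = paste("padj ≤", alpha),
                  shape = "isoform switching") +
    ggplot2::theme_minimal()
}

#' Bar plot of average transcript usage for one gene
#'
#' Estimated average usage (pi-bar) per isoform and population, with
#' bootstrap standard-deviation error bars when available.
#'
#' @param results A `dtu_results` object.
#' @param gene Gene id to plot.
#' @return A ggplot object.
#' @export
plot_transcript_usage <- function(results, gene) {
  df <- results$transcripts |> dplyr::filter(.data$gene_id == gene)
  if (nrow(df) == 0L) abort(paste("gene not in results:", gene))
  long <- dplyr::bind_rows(
    tibble::tibble(isoform = df$isoform, population = results$populations[1],
                   pi = df$pi_A, sd = df$sd_A),
    tibble::tibble(isoform = df$isoform, population = results$populations[2],
                   pi = df$pi_B, sd = df$sd_B))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$isoform, y = .data$pi,
                                     fill = .data$population)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$pi - .data$sd, 0),
                   ymax = pmin(.data$pi + .data$sd, 1)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      na.rm = TRUE) +
    ggplot2::labs(title = gene, x = NULL, y = "average transcript usage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sub-exon structure plot of a gene model
#'
#' Draws each transcript's member sub-exons as boxes on a shared genomic
#' axis — the compatibility-matrix view of the gene.
#'
#' @param object A `subexon_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subexon_partition <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$member == 1L)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = as.integer(factor(.data$transcript_id)) - 0.35,
                                    ymax = as.integer(factor(.data$transcript_id)) + 0.35),
                       fill = "steelblue", colour = "grey30") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(df$transcript_id)),
      labels = sort(unique(df$transcript_id))) +
    ggplot2::labs(title = object$gene_id,
                  x = sprintf("%s (%s)", object$chrom, object$strand),
                  y = NULL) +
    ggplot2::theme_minimal()
}
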