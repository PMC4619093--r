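#' Forest plot of neighborhood enrichment results
#'
#' Draws the difference of proportions with its Bonferroni-level confidence
#' interval for the top-ranked domains, enriched domains highlighted — the
#' graphical form of the enrichment report table.
#'
#' @param object A `gmrsd_enrichment` result.
#' @param top_n Number of top-ranked domains to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gmrsd_enrichment
#' @export
autoplot.gmrsd_enrichment <- function(object, top_n = 20, ...) {
  df <- utils::head(dplyr::arrange(tidy(object), .data$rank), top_n)
  df$domain_id <- factor(df$domain_id, levels = rev(df$domain_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff, y = .data$domain_id,
                                   colour = .data$enriched)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(
      x = "difference of proportions (neighborhood - background)",
      y = NULL,
      colour = "enriched",
      title = sprintf("Neighborhood enrichment (CI level %.5g)",
                      attr(object, "conf_level"))
    ) +
    ggplot2::theme_minimal()
}

#' Conservation profile plot
#'
#' Per-column modal-residue frequency along the alignment, with the
#' strictly-above-threshold (`+`-marked) columns highlighted.
#'
#' @param object A `gmrsd_conservation` profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gmrsd_conservation
#' @export
autoplot.gmrsd_conservation <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column,
                                       y = .data$frequency)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = object[object$plus_mark, , drop = FALSE],
                        colour = "#c0392b", size = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2,
                        colour = "#c0392b") +
    ggplot2::labs(x = "alignment column", y = "modal residue frequency",
                  title = sprintf("Conservation profile (mark > %.2f)", thr)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Stacked per-genome architecture inventory plot
#'
#' The genome-inventory view of the family: how many genomes carry each
#' combination of double-domain and single-domain members.
#'
#' @param inventory Output of [build_inventory()].
#' @return A ggplot object.
#' @export
plot_inventory <- function(inventory) {
  assert_columns(inventory, c("genome_id", "n_double", "n_s_only",
                              "n_d_only", "n_other"), "inventory")
  long <- tidyr::pivot_longer(inventory, -"genome_id",
                              names_to = "class", values_to = "count")
  long$class <- factor(long$class,
                       levels = c("n_double", "n_s_only", "n_d_only",
                                  "n_other"),
                       labels = c("double-domain", "GmrS-only", "GmrD-only",
                                  "other"))
  counts <- long |>
    dplyr::filter(.data$count > 0) |>
    dplyr::count(.data$class, .data$count)
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$count), y = .data$n,
                                       fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "members per genome", y = "genomes",
                  fill = "architecture",
                  title = "GmrSD family inventory across genomes") +
    ggplot2::theme_minimal()
}
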