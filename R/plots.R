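#' Pan-target scatter of tumor versus normal score
#'
#' Each point is a target at its average tumor binned score (y) against its
#' average normal binned score (x); high-priority targets sit top-left (high
#' tumor, low normal expression).  Color encodes tier, shape the AS versus
#' gene-level class.
#'
#' @param targets Target tibble with `tumor_score`, `normal_score`, `tier`,
#'   `target_class` (e.g. `tidy()` of a `cse_run`).
#' @return A ggplot object.
#' @export
plot_target_scatter <- function(targets) {
  ggplot2::ggplot(targets,
                  ggplot2::aes(x = .data$normal_score, y = .data$tumor_score,
                               color = factor(.data$tier),
                               shape = .data$target_class)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::scale_color_manual(values = c(`1` = "#D55E00", `2` = "#0072B2"),
                                name = "Tier") +
    ggplot2::scale_shape_manual(values = c(AS = 17, gene_level = 16),
                                name = "Class") +
    ggplot2::coord_cartesian(xlim = c(0, 3), ylim = c(0, 3)) +
    ggplot2::labs(x = "Average binned score, normal tissues",
                  y = "Average binned score, tumor types") +
    ggplot2::theme_minimal()
}

#' @rdname plot_target_scatter
#' @param object A `cse_run` object.
#' @param ... Unused.
#' @method autoplot cse_run
#' @export
autoplot.cse_run <- function(object, ...) {
  plot_target_scatter(object$targets)
}

#' Exon-level expression profile of one gene
#'
#' Mean percentile rank per exon (transcription order) and group, the
#' heatmap-view representation that distinguishes an AS target (one exon
#' high in tumors only) from a gene-level target (all exons high).
#'
#' @param run A `cse_run` object.
#' @param gene Gene id.
#' @param compartment Compartment rank space to show (default first).
#' @return A ggplot object.
#' @export
plot_exon_profile <- function(run, gene, compartment = NULL) {
  models <- attr(run, "models")
  if (is.null(models)) abort("Run object carries no gene models.")
  compartment <- compartment %||% names(run$diffexp)[1]
  d <- run$diffexp[[compartment]]
  ex <- models$exons |>
    dplyr::filter(.data$gene_id == gene) |>
    dplyr::arrange(.data$index_in_gene)
  grp <- split(d$samples$sample_id, d$samples$group)
  mr <- vapply(grp, function(ids) {
    rowMeans(d$ranks[ex$exon_id, ids, drop = FALSE])
  }, numeric(nrow(ex)))
  df <- tibble::as_tibble(mr, rownames = "exon_id") |>
    tidyr::pivot_longer(-"exon_id", names_to = "group",
                        values_to = "mean_rank") |>
    dplyr::left_join(ex[, c("exon_id", "index_in_gene")], by = "exon_id") |>
    dplyr::left_join(dplyr::distinct(d$samples, .data$group, .data$cohort),
                     by = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index_in_gene,
                                   y = .data$group,
                                   fill = .data$mean_rank)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cohort),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Mean rank") +
    ggplot2::labs(x = "Exon index (5' to 3')", y = NULL, title = gene) +
    ggplot2::theme_minimal()
}
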