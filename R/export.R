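#' Export portal-ready tables
#'
#' Writes the four portal views plus a manifest:
#'
#' * `scatter.tsv` — per target: tumor score, normal score, tier, class,
#'   localization (the pan-target scatter);
#' * `table_view.tsv` — per target exon and type: mean percentile rank,
#'   mean binned score, prevalence and quartile-bin distribution;
#' * `heatmap.tsv` — exon x type mean percentile rank in `[0, 1]` for every
#'   exon of every target gene, with CSE flags;
#' * `gene_view.json` — exon coordinates, CSE/AS flags and localization per
#'   target gene;
#' * `manifest.json` — pipeline version, threshold hash and entity counts.
#'
#' All outputs are deterministic (sorted rows, no timestamps), so identical
#' runs produce byte-identical bundles.
#'
#' @param run A `cse_run` object.
#' @param dir Output directory (created if missing).
#' @param models Gene models; defaults to the models used in scoring when
#'   attached, otherwise required for the heatmap/gene view.
#' @return `dir`, invisibly.
#' @export
export_portal <- function(run, dir, models = NULL) {
  if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE) &&
      !dir.exists(dir)) {
    abort(sprintf("Cannot create output directory '%s'.", dir))
  }
  p <- function(f) file.path(dir, f)
  targets <- run$targets
  if (!"tumor_score" %in% names(targets)) targets$tumor_score <- NA_real_
  if (!"normal_score" %in% names(targets)) targets$normal_score <- NA_real_

  scatter <- targets |>
    dplyr::transmute(
      gene_id = .data$gene_id, exon_id = .data$representative_exon,
      tumor_score = .data$tumor_score,
      normal_score = .data$normal_score,
      tier = .data$tier, target_class = .data$target_class,
      localization = .data$localization) |>
    dplyr::arrange(.data$gene_id)
  readr::write_tsv(scatter, p("scatter.tsv"), progress = FALSE)

  if (!is.null(run$scores)) {
    bins <- run$scores$bins
    bin_dist <- run$scores$type_means |>
      dplyr::left_join(run$scores$prevalence,
                       by = c("exon_id", "group", "cohort"))
    # rank means per type from the compartment rank matrices
    rank_means <- purrr::imap(run$diffexp, function(d, comp) {
      grp <- split(d$samples$sample_id, d$samples$group)
      mr <- vapply(grp, function(ids) {
        rowMeans(d$ranks[, ids, drop = FALSE])
      }, numeric(nrow(d$ranks)))
      tibble::as_tibble(mr, rownames = "exon_id") |>
        tidyr::pivot_longer(-"exon_id", names_to = "group",
                            values_to = "mean_rank") |>
        dplyr::mutate(compartment = comp)
    }) |> dplyr::bind_rows()
    table_view <- bin_dist |>
      dplyr::filter(.data$exon_id %in% targets$representative_exon) |>
      dplyr::left_join(rank_means, by = c("exon_id", "group"),
                       relationship = "many-to-many") |>
      dplyr::arrange(.data$exon_id, .data$group)
    readr::write_tsv(table_view, p("table_view.tsv"), progress = FALSE)
  }

  mods <- models %||% attr(run, "models")
  if (!is.null(mods)) {
    gene_exons <- mods$exons |>
      dplyr::filter(.data$gene_id %in% targets$gene_id)
    cse_flags <- run$tiers |>
      dplyr::select("gene_id", "cse_exon_ids") |>
      tidyr::unnest("cse_exon_ids") |>
      dplyr::rename(exon_id = "cse_exon_ids") |>
      dplyr::mutate(is_cse = TRUE)
    heat <- purrr::imap(run$diffexp, function(d, comp) {
      grp <- split(d$samples$sample_id, d$samples$group)
      keep <- intersect(gene_exons$exon_id, rownames(d$ranks))
      mr <- vapply(grp, function(ids) {
        rowMeans(d$ranks[keep, ids, drop = FALSE])
      }, numeric(length(keep)))
      if (length(keep) == 1L) {
        mr <- matrix(mr, nrow = 1, dimnames = list(keep, names(grp)))
      }
      tibble::as_tibble(mr, rownames = "exon_id") |>
        dplyr::mutate(compartment = comp)
    }) |> dplyr::bind_rows()
    heat <- heat |>
      dplyr::left_join(gene_exons[, c("exon_id", "gene_id")], by = "exon_id") |>
      dplyr::left_join(cse_flags, by = c("exon_id", "gene_id")) |>
      dplyr::mutate(is_cse = dplyr::coalesce(.data$is_cse, FALSE)) |>
      dplyr::arrange(.data$gene_id, .data$exon_id, .data$compartment)
    readr::write_tsv(heat, p("heatmap.tsv"), progress = FALSE)

    gene_view <- targets |>
      dplyr::arrange(.data$gene_id) |>
      purrr::pmap(function(gene_id, target_class, chosen_exon, localization,
                           cse_exon_ids, tier, ...) {
        ex <- mods$exons[mods$exons$gene_id == gene_id, ]
        list(gene_id = gene_id, target_class = target_class, tier = tier,
             localization = localization,
             chosen_as_exon = if (is.na(chosen_exon)) NULL else chosen_exon,
             exons = purrr::pmap(
               ex[, c("exon_id", "chrom", "start", "end", "strand",
                      "index_in_gene")],
               function(exon_id, chrom, start, end, strand, index_in_gene) {
                 list(exon_id = exon_id, chrom = chrom, start = start,
                      end = end, strand = strand, index = index_in_gene,
                      is_cse = exon_id %in% cse_exon_ids)
               }))
      })
    jsonlite::write_json(gene_view, p("gene_view.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  manifest <- list(
    pipeline = "csefinder",
    version = as.character(utils::packageVersion("csefinder")),
    threshold_hash = digest::digest(run$thresholds),
    n_targets = nrow(targets),
    n_tier1 = sum(targets$tier == 1L),
    n_as = sum(targets$target_class == "AS"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
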