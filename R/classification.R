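#' Per-transcript CSE coverage
#'
#' Fraction of a transcript's exonic length contributed by the gene's CSE
#' exons: `coverage(t) = sum(length of CSE exons in t) / total exonic length
#' of t`.  Length-weighted (base pairs, not exon counts), so it is robust to
#' unequal exon sizes.
#'
#' @param gene Gene id.
#' @param cse_exons Character vector of the gene's CSE exon ids.
#' @param models A `cse_models` object.
#' @return Tibble `transcript_id`, `coverage`.
#' @export
transcript_cse_coverage <- function(gene, cse_exons, models) {
  ex <- models$exons[models$exons$gene_id == gene, ]
  bad <- setdiff(cse_exons, ex$exon_id)
  if (length(bad)) {
    abort(paste0("CSE exon(s) not in gene ", gene, ": ",
                 paste(bad, collapse = ", ")))
  }
  lens <- stats::setNames(ex$end - ex$start + 1L, ex$exon_id)
  tx <- models$transcripts[models$transcripts$gene_id == gene, ]
  tx |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      coverage = sum(lens[.data$exon_id[.data$exon_id %in% cse_exons]]) /
        sum(lens[.data$exon_id]),
      .groups = "drop")
}

# exons present in >= 1 and absent from >= 1 transcript of their gene
differentially_included <- function(gene, models) {
  tx <- models$transcripts[models$transcripts$gene_id == gene, ]
  n_tx <- length(unique(tx$transcript_id))
  if (n_tx < 2) return(character(0))
  counts <- table(tx$exon_id)
  names(counts)[counts < n_tx]
}

#' Classify targets as AS-exon or gene-level
#'
#' A gene is an alternatively spliced (AS) target when some transcript has
#' CSE coverage strictly below `coverage_threshold` (40%) and at least one
#' CSE exon is differentially included (present in some but not all
#' annotated transcripts, i.e. cassette behavior); otherwise it is a
#' gene-level target.  Single-transcript genes are always gene-level.  For
#' AS targets the most differential AS exon is chosen via [pick_top_as()].
#'
#' @param candidates Candidate exon tibble with `exon_id`, `gene_id`,
#'   `composite_z`.
#' @param models A `cse_models` object.
#' @param coverage_threshold Strict upper bound on coverage (default 0.40).
#' @return Tibble per gene: `gene_id`, `target_class`, `chosen_exon` (NA for
#'   gene-level), `coverage_min`, `cse_exon_ids` (list-column).
#' @export
classify_targets <- function(candidates, models, coverage_threshold = 0.40) {
  best_z <- candidates |>
    dplyr::group_by(.data$exon_id) |>
    dplyr::summarise(composite_z = max(.data$composite_z), .groups = "drop")
  per_gene <- candidates |>
    dplyr::distinct(.data$gene_id, .data$exon_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(cse_exon_ids = list(sort(unique(.data$exon_id))),
                     .groups = "drop")
  purrr::pmap(per_gene, function(gene_id, cse_exon_ids) {
    cov <- transcript_cse_coverage(gene_id, cse_exon_ids, models)
    di <- differentially_included(gene_id, models)
    as_exons <- intersect(cse_exon_ids, di)
    is_as <- any(cov$coverage < coverage_threshold) && length(as_exons) > 0
    chosen <- if (is_as) {
      pick_top_as(as_exons, best_z, models)
    } else {
      NA_character_
    }
    tibble::tibble(gene_id = gene_id,
                   target_class = if (is_as) "AS" else "gene_level",
                   chosen_exon = chosen,
                   coverage_min = min(cov$coverage),
                   cse_exon_ids = list(cse_exon_ids))
  }) |> dplyr::bind_rows()
}

#' Pick the most differential AS exon
#'
#' Returns the AS exon with the maximal composite Z-score (maximum over
#' compartments); ties are broken deterministically by genomic position
#' (lower start coordinate first).
#'
#' @param as_exons Candidate AS exon ids.
#' @param composites Tibble `exon_id`, `composite_z` (already reduced to the
#'   per-exon maximum).
#' @param models A `cse_models` object (for tie-break coordinates).
#' @return A single exon id.
#' @export
pick_top_as <- function(as_exons, composites, models) {
  df <- tibble::tibble(exon_id = as_exons) |>
    dplyr::left_join(composites, by = "exon_id") |>
    dplyr::left_join(models$exons[, c("exon_id", "start")], by = "exon_id") |>
    dplyr::arrange(dplyr::desc(.data$composite_z), .data$start)
  df$exon_id[1]
}

#' Find splice-site-proximal variant carriers
#'
#' A variant qualifies when it lies within `window` bp (inclusive) of either
#' boundary of the AS exon, on the same chromosome; positions are 1-based
#' genomic coordinates.
#'
#' @param variants Tibble `sample_id`, `chrom`, `pos`.
#' @param exon One-row tibble/list with `chrom`, `start`, `end`.
#' @param window Window size in bp (default 10).
#' @return Character vector of carrier sample ids (unique).
#' @export
near_splice_variants <- function(variants, exon, window = 10L) {
  if (!nrow(variants)) return(character(0))
  hit <- variants$chrom == exon$chrom &
    (abs(variants$pos - exon$start) <= window |
       abs(variants$pos - exon$end) <= window)
  unique(variants$sample_id[hit])
}

#' One-sided association test between splice variants and AS exon expression
#'
#' Welch two-sample t-test (carriers greater) of the AS exon's expression in
#' carrier versus non-carrier tumors, restricted to tumors with
#' median-or-higher expression of the exon.  With fewer than `min_group`
#' carriers or non-carriers among the eligible tumors, the result is
#' "insufficient" and no p-value is returned.
#'
#' @param expr_row Named numeric vector: the AS exon's expression per sample.
#' @param carriers Character vector of carrier sample ids.
#' @param samples Sample table (tumor samples are eligible).
#' @param min_group Minimum per-group size (default 2).
#' @return Tibble `status`, `p_value`, `mean_carrier`, `mean_noncarrier`,
#'   `n_carrier`, `n_noncarrier`.
#' @export
splice_variant_test <- function(expr_row, carriers, samples, min_group = 2L) {
  tumor <- intersect(samples$sample_id[samples$cohort == "tumor"],
                     names(expr_row))
  vals <- expr_row[tumor]
  eligible <- tumor[vals >= median(vals)]
  car <- intersect(eligible, carriers)
  non <- setdiff(eligible, carriers)
  if (length(car) < min_group || length(non) < min_group) {
    return(tibble::tibble(status = "insufficient", p_value = NA_real_,
                          mean_carrier = NA_real_, mean_noncarrier = NA_real_,
                          n_carrier = length(car), n_noncarrier = length(non)))
  }
  tt <- stats::t.test(expr_row[car], expr_row[non],
                      alternative = "greater", var.equal = FALSE)
  tibble::tibble(status = "ok", p_value = tt$p.value,
                 mean_carrier = mean(expr_row[car]),
                 mean_noncarrier = mean(expr_row[non]),
                 n_carrier = length(car), n_noncarrier = length(non))
}
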