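#' Above-median expression flags per group
#'
#' A group is flagged for an exon when the median percentile rank of the
#' group's samples exceeds 0.5 (strictly) in the shared compartment rank
#' space.
#'
#' @param ranks Percentile-rank matrix (exon x sample).
#' @param samples Sample table covering the rank columns.
#' @param groups Optional subset of group labels; unknown labels error.
#' @return Tibble with columns `exon_id`, `group`, `median_rank`,
#'   `above_median`.
#' @export
above_median_flags <- function(ranks, samples, groups = NULL) {
  samples <- samples[samples$sample_id %in% colnames(ranks), ]
  groups <- groups %||% unique(samples$group)
  unknown <- setdiff(groups, samples$group)
  if (length(unknown)) {
    abort(paste0("Unknown group label(s): ", paste(unknown, collapse = ", ")))
  }
  ids <- split(samples$sample_id, samples$group)[groups]
  out <- purrr::imap(ids, function(cols, g) {
    m <- row_medians(ranks[, cols, drop = FALSE])
    tibble::tibble(exon_id = rownames(ranks), group = g,
                   median_rank = m, above_median = m > 0.5)
  })
  dplyr::bind_rows(out)
}

#' Select candidate cancer-specific exons
#'
#' An exon is a CSE candidate in a compartment when its composite Z-score
#' exceeds `z_star` (strictly), at least one tumor type of the compartment
#' is above-median, and at most `max_normals` normal tissues are
#' above-median.
#'
#' @param diff A `cse_diffexp` object from [run_differential()].
#' @param z_star Composite Z threshold (default 1).
#' @param max_normals Maximum number of above-median normal tissues
#'   (default 5).
#' @return Tibble of candidates: `exon_id`, `gene_id`, `compartment`,
#'   `composite_z`, `supporting_groups` (list-column of above-median tumor
#'   types), `n_normals_above`.
#' @export
select_cse <- function(diff, z_star = 1, max_normals = 5) {
  gm <- diff$group_median_ranks
  t_above <- gm[, diff$tumor_groups, drop = FALSE] > 0.5
  n_above <- gm[, diff$normal_groups, drop = FALSE] > 0.5
  supporting <- apply(t_above, 1L, function(r) diff$tumor_groups[r],
                      simplify = FALSE)
  comp <- diff$composite
  out <- comp |>
    dplyr::mutate(
      supporting_groups = supporting[.data$exon_id],
      n_tumors_above = rowSums(t_above)[.data$exon_id],
      n_normals_above = rowSums(n_above)[.data$exon_id]) |>
    dplyr::filter(.data$composite_z > z_star,
                  .data$n_tumors_above >= 1,
                  .data$n_normals_above <= max_normals) |>
    dplyr::select("exon_id", "gene_id", "compartment", "composite_z",
                  "supporting_groups", "n_normals_above")
  out
}

#' Filter candidates to surfaceome/matrisome and apply the blacklist
#'
#' Keeps candidate exons whose gene belongs to the surfaceome or matrisome
#' and drops (at gene level, all exons) genes in any blacklist category, such
#' as tumor suppressors, transcription factors and chromatin regulators.
#' Genes absent from every annotation set are dropped as unannotated.
#'
#' @param candidates Candidate tibble from [select_cse()] (one or several
#'   compartments bound together).
#' @param annotations A `cse_annotations` object (or compatible list).
#' @param allowlist Optional genes exempted from the blacklist.
#' @return The kept candidates with a `localization` column
#'   (surfaceome/matrisome/both) and an `oncofetal` flag; dropped genes are
#'   recorded in the `"dropped"` attribute (tibble `gene_id`, `reason`).
#' @export
filter_localization <- function(candidates, annotations, allowlist = character(0)) {
  bl <- setdiff(unique(unlist(annotations$blacklist)), allowlist)
  surf <- annotations$surfaceome
  matr <- annotations$matrisome
  ann <- candidates |>
    dplyr::mutate(
      in_surf = .data$gene_id %in% surf,
      in_matr = .data$gene_id %in% matr,
      blacklisted = .data$gene_id %in% bl,
      localization = dplyr::case_when(
        in_surf & in_matr ~ "both",
        in_surf ~ "surfaceome",
        in_matr ~ "matrisome",
        TRUE ~ NA_character_),
      oncofetal = .data$gene_id %in% annotations$oncofetal)
  dropped <- ann |>
    dplyr::filter(.data$blacklisted | is.na(.data$localization)) |>
    dplyr::distinct(.data$gene_id,
                    reason = ifelse(.data$blacklisted, "blacklist",
                                    "unannotated"))
  kept <- ann |>
    dplyr::filter(!.data$blacklisted, !is.na(.data$localization)) |>
    dplyr::select(-"in_surf", -"in_matr", -"blacklisted")
  attr(kept, "dropped") <- dropped
  kept
}
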