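#' Cross-resource expression validation
#'
#' For every supporting tumor type of a candidate exon that was profiled by
#' two or more data sources, the exon must be above-median (median percentile
#' rank > 0.5) within each source's samples of that type separately; this
#' guards against coverage artifacts of a single RNA-seq protocol.  Types
#' profiled by a single source pass vacuously.
#'
#' @param candidates Candidate tibble with `exon_id` and `supporting_groups`.
#' @param ranks Compartment percentile-rank matrix.
#' @param samples Sample table with `group` and `data_source`.
#' @return Tibble `exon_id`, `cross_resource` ("pass", "fail" or
#'   "not_applicable"), `cross_resource_detail`.
#' @export
cross_resource_check <- function(candidates, ranks, samples) {
  multi <- samples |>
    dplyr::filter(.data$cohort == "tumor") |>
    dplyr::distinct(.data$group, .data$data_source) |>
    dplyr::count(.data$group) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull("group")
  src_ids <- samples |>
    dplyr::filter(.data$group %in% multi) |>
    dplyr::group_by(.data$group, .data$data_source) |>
    dplyr::summarise(ids = list(.data$sample_id), .groups = "drop")

  check_one <- function(exon_id, supporting) {
    applicable <- intersect(supporting, multi)
    if (!length(applicable)) {
      return(tibble::tibble(exon_id = exon_id,
                            cross_resource = "not_applicable",
                            cross_resource_detail = NA_character_))
    }
    rows <- src_ids[src_ids$group %in% applicable, ]
    ok <- purrr::map_lgl(rows$ids, function(ids) {
      median(ranks[exon_id, ids]) > 0.5
    })
    fail <- rows[!ok, ]
    tibble::tibble(
      exon_id = exon_id,
      cross_resource = if (all(ok)) "pass" else "fail",
      cross_resource_detail = if (all(ok)) NA_character_ else {
        paste(paste0(fail$group, "/", fail$data_source), collapse = ";")
      })
  }
  purrr::map2(candidates$exon_id, candidates$supporting_groups, check_one) |>
    dplyr::bind_rows()
}

#' Verify target expression in tumor proteomics
#'
#' A gene passes when at least `min_psm` peptide-spectral matches map within
#' it in the tumor panel; genes absent from the panel fail with
#' "no-coverage" evidence.
#'
#' @param genes Character vector of gene ids.
#' @param proteomics PSM tibble with `gene_id`, `panel`, `psm_count`.
#' @param min_psm Minimum PSM count (default 1).
#' @return Tibble `gene_id`, `psm_total`, `proteomics` (pass/fail),
#'   `proteomics_detail`.
#' @export
verify_tumor_proteomics <- function(genes, proteomics, min_psm = 1L) {
  totals <- proteomics |>
    dplyr::filter(.data$panel == "tumor") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(psm_total = sum(.data$psm_count), .groups = "drop")
  tibble::tibble(gene_id = unique(genes)) |>
    dplyr::left_join(totals, by = "gene_id") |>
    dplyr::mutate(
      proteomics_detail = dplyr::if_else(is.na(.data$psm_total),
                                         "no-coverage", NA_character_),
      psm_total = dplyr::coalesce(.data$psm_total, 0L),
      proteomics = dplyr::if_else(.data$psm_total >= min_psm, "pass", "fail"))
}

#' Normal-brain expression filter for brain-compartment candidates
#'
#' Brain-tumor candidates highly expressed in normal brain (median
#' percentile rank at or above the third quartile, 0.75) are removed.
#' Solid-only candidates are not applicable.
#'
#' @param candidates Candidate tibble with `exon_id` and `compartment`.
#' @param group_median_ranks Exon x group matrix of median percentile ranks
#'   containing a `Brain` column.
#' @param brain_q High-expression rank threshold (default 0.75).
#' @param brain_tissue Name of the normal brain tissue column.
#' @return Tibble `exon_id`, `brain_normal` (pass/fail/not_applicable),
#'   `brain_median_rank`.
#' @export
brain_normal_filter <- function(candidates, group_median_ranks,
                                brain_q = 0.75, brain_tissue = "Brain") {
  if (!brain_tissue %in% colnames(group_median_ranks)) {
    abort(sprintf("Normal tissue '%s' not present.", brain_tissue))
  }
  br <- group_median_ranks[, brain_tissue]
  candidates |>
    dplyr::transmute(
      exon_id = .data$exon_id,
      brain_median_rank = br[.data$exon_id],
      brain_normal = dplyr::case_when(
        .data$compartment != "brain" ~ "not_applicable",
        brain_median_rank >= brain_q ~ "fail",
        TRUE ~ "pass"))
}

#' Exon-position (3') bias check
#'
#' Computes, per gene, the Pearson correlation between the mean normal-tissue
#' expression of each exon and its transcription-direction exon index
#' (1 = 5'-most).  A gene is removed when the correlation is positive and
#' significant (two-sided p < `alpha`, directional gate r > 0), the signature
#' of 3'-end coverage inflation in the normal cohort.  Genes with fewer than
#' 3 exons, or with zero variance in either variable, are not applicable.
#'
#' @param genes Character vector of gene ids to check.
#' @param expr Exon x sample FPKM matrix.
#' @param samples Sample table; normal-cohort samples are used.
#' @param models A `cse_models` object (for exon indices).
#' @param alpha Significance threshold (default 0.01).
#' @return Tibble `gene_id`, `bias_r`, `bias_p`, `position_bias`
#'   (pass/fail/not_applicable); "fail" means the gene is removed.
#' @export
exon_position_bias <- function(genes, expr, samples, models, alpha = 0.01) {
  normal_ids <- intersect(samples$sample_id[samples$cohort == "normal"],
                          colnames(expr))
  if (!length(normal_ids)) abort("No normal samples in expression matrix.")
  ex <- models$exons |> dplyr::filter(.data$gene_id %in% genes)
  mean_norm <- rowMeans(expr[ex$exon_id, normal_ids, drop = FALSE])
  purrr::map(unique(genes), function(g) {
    rows <- ex$gene_id == g
    if (sum(rows) < 3) {
      return(tibble::tibble(gene_id = g, bias_r = NA_real_, bias_p = NA_real_,
                            position_bias = "not_applicable"))
    }
    x <- ex$index_in_gene[rows]
    y <- mean_norm[rows]
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(tibble::tibble(gene_id = g, bias_r = NA_real_, bias_p = NA_real_,
                            position_bias = "pass"))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(
      gene_id = g, bias_r = unname(ct$estimate), bias_p = ct$p.value,
      position_bias = if (ct$p.value < alpha && ct$estimate > 0) "fail"
                      else "pass")
  }) |> dplyr::bind_rows()
}

#' Run all curation checks and assemble the QC report
#'
#' Applies, in order: cross-resource validation, tumor proteomics
#' verification, the normal-brain filter (brain-compartment candidates), and
#' the exon-position bias check (by default scoped to brain-compartment
#' candidates' genes; set `bias_scope = "all"` to apply globally).
#' `final_keep` is the AND over applicable checks.
#'
#' @param candidates Annotated candidate tibble (post localization filter).
#' @param ranks Compartment rank matrix (or a named list per compartment).
#' @param group_median_ranks Exon x group median-rank matrix (or named list
#'   per compartment).
#' @param samples Sample table.
#' @param expr Exon x sample FPKM matrix.
#' @param models A `cse_models` object.
#' @param proteomics PSM tibble.
#' @param min_psm,bias_alpha,brain_q Check thresholds.
#' @param bias_scope `"brain"` (default) or `"all"`.
#' @return QC tibble: one row per candidate exon with per-check outcomes,
#'   evidence columns, and `final_keep`.
#' @export
curate_candidates <- function(candidates, ranks, group_median_ranks, samples,
                              expr, models, proteomics, min_psm = 1L,
                              bias_alpha = 0.01, brain_q = 0.75,
                              bias_scope = c("brain", "all")) {
  bias_scope <- match.arg(bias_scope)
  get_comp <- function(obj, comp) if (is.list(obj)) obj[[comp]] else obj

  per_comp <- candidates |>
    dplyr::group_by(.data$compartment) |>
    dplyr::group_split() |>
    purrr::map(function(cand) {
      comp <- cand$compartment[1]
      r <- get_comp(ranks, comp)
      gm <- get_comp(group_median_ranks, comp)
      cr <- cross_resource_check(cand, r, samples)
      bn <- brain_normal_filter(cand, gm, brain_q = brain_q)
      cand |>
        dplyr::left_join(cr, by = "exon_id") |>
        dplyr::left_join(bn, by = "exon_id")
    }) |>
    dplyr::bind_rows()

  prot <- verify_tumor_proteomics(unique(candidates$gene_id), proteomics,
                                  min_psm = min_psm)
  bias_genes <- if (bias_scope == "brain") {
    unique(candidates$gene_id[candidates$compartment == "brain"])
  } else {
    unique(candidates$gene_id)
  }
  bias <- if (length(bias_genes)) {
    exon_position_bias(bias_genes, expr, samples, models, alpha = bias_alpha)
  } else {
    tibble::tibble(gene_id = character(0), bias_r = numeric(0),
                   bias_p = numeric(0), position_bias = character(0))
  }

  out <- per_comp |>
    dplyr::left_join(prot, by = "gene_id") |>
    dplyr::left_join(bias, by = "gene_id") |>
    dplyr::mutate(
      position_bias = dplyr::coalesce(.data$position_bias, "not_applicable"),
      final_keep = .data$cross_resource != "fail" &
        .data$proteomics != "fail" &
        .data$brain_normal != "fail" &
        .data$position_bias != "fail")
  out
}
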