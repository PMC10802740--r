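#' Evaluate a pipeline run against the planted ground truth
#'
#' Parameter-recovery metrics for synthetic runs: sensitivity and precision
#' of planted-target recovery at the gene level, classification accuracy for
#' recovered planted AS and gene-level targets, and per-confounder demotion
#' status (Tier 2 with the expected failed check named).
#'
#' @param run A `cse_run` object.
#' @param truth Ground-truth manifest from the generating bundle.
#' @return A list with `sensitivity`, `precision`, `n_recovered`,
#'   `n_planted`, `n_false`, `as_class_accuracy`, `gene_level_class_accuracy`,
#'   a `confounders` tibble (gene, type, tier, failed_checks, demoted_ok) for
#'   the tiering-check confounders, and a `bias_confounders` tibble recording
#'   whether each 3'-bias confounder was removed at curation for position
#'   bias.
#' @export
evaluate_recovery <- function(run, truth) {
  planted <- c(truth$planted_gene_level, truth$planted_as$gene_id)
  found <- run$targets$gene_id
  tp <- intersect(found, planted)
  fp <- setdiff(found, planted)

  cls <- run$targets[, c("gene_id", "target_class")]
  as_found <- cls$gene_id[cls$target_class == "AS"]
  gl_found <- cls$gene_id[cls$target_class == "gene_level"]
  as_tp <- intersect(truth$planted_as$gene_id, found)
  gl_tp <- intersect(truth$planted_gene_level, found)

  expected_check <- c(paired_normal = "paired_normal",
                      bone_marrow = "bone_marrow",
                      normal_protein = "gtex_proteomics")
  conf <- truth$confounders |>
    dplyr::filter(.data$type %in% names(expected_check)) |>
    dplyr::left_join(run$targets[, c("gene_id", "tier", "failed_checks")],
                     by = "gene_id") |>
    dplyr::mutate(
      expected = expected_check[.data$type],
      recovered = !is.na(.data$tier),
      demoted_ok = .data$recovered & .data$tier == 2L &
        stringr::str_detect(.data$failed_checks,
                            stringr::fixed(.data$expected)))

  bias_genes <- truth$confounders$gene_id[
    truth$confounders$type == "three_prime_bias"]
  bias <- tibble::tibble(gene_id = bias_genes) |>
    dplyr::mutate(
      selected = .data$gene_id %in% run$qc$gene_id,
      flagged = .data$gene_id %in%
        run$qc$gene_id[run$qc$position_bias == "fail"],
      removed_ok = .data$selected & .data$flagged &
        !.data$gene_id %in% found)

  list(
    sensitivity = length(tp) / length(planted),
    precision = if (length(found)) length(tp) / length(found) else NA_real_,
    n_recovered = length(tp), n_planted = length(planted),
    n_false = length(fp), false_genes = fp,
    as_class_accuracy = if (length(as_tp)) {
      mean(as_tp %in% as_found)
    } else NA_real_,
    gene_level_class_accuracy = if (length(gl_tp)) {
      mean(gl_tp %in% gl_found)
    } else NA_real_,
    confounders = conf,
    bias_confounders = bias)
}
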