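#' Simulate gene-set annotations
#'
#' Assigns every planted target and confounder gene to the surfaceome and/or
#' matrisome, a configurable fraction of null genes to those sets, and a
#' disjoint fraction of null genes to blacklist categories (tumor
#' suppressors, transcription factors, chromatin regulators).  Planted
#' targets are never blacklisted.
#'
#' @param models A `cse_models` object.
#' @param truth Ground-truth manifest from [sim_cohort()].
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return A list of class `cse_annotations` with character-vector sets
#'   `surfaceome`, `matrisome`, `oncofetal`, `transmembrane`, a named list
#'   `blacklist`, and a `report` tibble of set sizes and overlaps.
#' @export
sim_annotations <- function(models, truth, config = sim_config(), seed = 1L) {
  with_seed(sub_seed(seed, 3L), {
    planted <- unique(c(truth$planted_gene_level, truth$planted_as$gene_id,
                        truth$confounders$gene_id))
    nulls <- truth$null_genes

    assign_loc <- function(genes) {
      if (!length(genes)) {
        return(list(surf = character(0), matr = character(0)))
      }
      u <- runif(length(genes))
      list(surf = genes[u < 2 / 3],          # surfaceome only or both
           matr = genes[u >= 1 / 3])         # matrisome only or both
    }
    loc_p <- assign_loc(planted)
    n_ann <- round(config$frac_null_annotated * length(nulls))
    ann_nulls <- sample(nulls, n_ann)
    loc_n <- assign_loc(ann_nulls)

    bl_pool <- setdiff(nulls, character(0))
    n_bl <- round(config$frac_null_blacklist * length(nulls))
    bl_genes <- sample(bl_pool, min(n_bl, length(bl_pool)))
    cats <- c("tumor_suppressor", "transcription_factor", "chromatin_regulator")
    blacklist <- split(bl_genes, rep(cats, length.out = length(bl_genes)))
    blacklist <- blacklist[lengths(blacklist) > 0]

    surfaceome <- sort(c(loc_p$surf, loc_n$surf))
    matrisome <- sort(c(loc_p$matr, loc_n$matr))
    oncofetal <- if (length(planted)) {
      sort(sample(planted, max(1, round(0.2 * length(planted)))))
    } else character(0)
    transmembrane <- sort(sample(surfaceome,
                                 round(0.8 * length(surfaceome))))

    report <- tibble::tibble(
      set = c("surfaceome", "matrisome", "blacklist", "oncofetal"),
      n = c(length(surfaceome), length(matrisome),
            length(unlist(blacklist)), length(oncofetal)),
      n_planted = c(sum(surfaceome %in% planted), sum(matrisome %in% planted),
                    sum(unlist(blacklist) %in% planted),
                    sum(oncofetal %in% planted)))

    structure(list(surfaceome = surfaceome, matrisome = matrisome,
                   blacklist = blacklist, oncofetal = oncofetal,
                   transmembrane = transmembrane, report = report),
              class = "cse_annotations")
  })
}

#' Simulate tumor and normal proteomics PSM tables
#'
#' The tumor panel gives every planted target at least one peptide-spectral
#' match (PSM) per exon; null genes receive sparse low counts with partial
#' coverage.  The normal panel draws per-exon nPSM (PSM count normalized to
#' the amino-acid length coded by the exon) from a two-component log10-normal
#' mixture; genes flagged `normal_protein` in the ground truth are drawn from
#' the upper component, planted clean targets from the lower, and null genes
#' from either with equal probability.
#'
#' @inheritParams sim_annotations
#' @return A tibble with columns `gene_id`, `exon_id`, `panel`, `psm_count`,
#'   `aa_length`, `npsm`.
#' @export
sim_proteomics <- function(models, truth, config = sim_config(), seed = 1L) {
  with_seed(sub_seed(seed, 4L), {
    exons <- models$exons
    planted <- unique(c(truth$planted_gene_level, truth$planted_as$gene_id,
                        truth$confounders$gene_id))
    aa_len <- pmax(7L, (exons$end - exons$start + 1L) %/% 3L)

    # tumor panel
    is_planted <- exons$gene_id %in% planted
    covered_null <- !is_planted & runif(nrow(exons)) < 0.6
    tumor <- tibble::tibble(
      gene_id = exons$gene_id, exon_id = exons$exon_id, panel = "tumor",
      psm_count = ifelse(is_planted, rpois(nrow(exons), 5) + 1L,
                         ifelse(covered_null, rpois(nrow(exons), 1), 0L)),
      aa_length = aa_len)
    tumor <- tumor[is_planted | covered_null, ]

    # normal panel: mixture component per gene
    high_genes <- truth$confounders$gene_id[
      truth$confounders$type == "normal_protein"]
    comp <- ifelse(models$genes$gene_id %in% high_genes, "high",
                   ifelse(models$genes$gene_id %in% planted, "low",
                          ifelse(runif(nrow(models$genes)) < 0.5,
                                 "high", "low")))
    names(comp) <- models$genes$gene_id
    mu <- config$npsm_meanlog10[comp[exons$gene_id]]
    npsm_target <- 10^rnorm(nrow(exons), mu, config$npsm_sdlog10)
    normal <- tibble::tibble(
      gene_id = exons$gene_id, exon_id = exons$exon_id, panel = "normal",
      psm_count = as.integer(round(npsm_target * aa_len)),
      aa_length = aa_len)

    dplyr::bind_rows(tumor, normal) |>
      dplyr::mutate(npsm = .data$psm_count / .data$aa_length)
  })
}

#' Sample nPSM values from a two-component log10-normal mixture
#'
#' Standalone generator used to validate the bimodal cutoff estimator against
#' known generative parameters.
#'
#' @param n Number of values.
#' @param means_log10 Length-2 vector of component means (log10 scale).
#' @param sd_log10 Common component sd (log10 scale).
#' @param weights Length-2 mixing weights (normalized internally).
#' @param seed Integer seed.
#' @return Numeric vector of nPSM values (natural scale).
#' @export
sim_npsm_mixture <- function(n, means_log10 = c(-2, 0), sd_log10 = 0.3,
                             weights = c(0.5, 0.5), seed = 1L) {
  with_seed(sub_seed(seed, 8L), {
    w <- weights / sum(weights)
    comp <- sample(1:2, n, replace = TRUE, prob = w)
    10^rnorm(n, means_log10[comp], sd_log10)
  })
}
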