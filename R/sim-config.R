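#' Default tumor groups for the synthetic study design
#'
#' Ten pediatric tumor types split into the solid and brain compartments,
#' mirroring a multi-cohort study design.  The five solid types with a
#' paired normal tissue (adrenocortical tumor, Wilms tumor, rhabdomyosarcoma,
#' retinoblastoma, melanoma) are always present so the Tier-1 paired-normal
#' check can be exercised; osteosarcoma is profiled by two data sources so the
#' cross-resource curation check is non-vacuous.
#'
#' @return A tibble with columns `group`, `compartment` and a `sources`
#'   list-column of data-source labels.
#' @export
default_tumor_groups <- function() {
  tibble::tibble(
    group       = c("ACT", "WLM", "RHB", "RB", "MEL", "OS", "EWS",
                    "HGG", "EPN", "MB"),
    compartment = c(rep("solid", 7), rep("brain", 3)),
    sources     = list("ClinGen", "TARGET", "PCGP", "PCGP", "ClinGen",
                       c("ClinGen", "PCGP"), "PCGP",
                       "PCGP", "ClinGen", "PCGP")
  )
}

#' Default normal tissue panel
#'
#' Twenty-nine bulk RNA-seq normal tissue types, including the five tissues
#' paired to tumor types (Adrenal, Kidney, Muscle, Nerve, Skin) and Brain.
#' Bone marrow is deliberately absent: it is modeled as a separate gene-level
#' expression panel, reflecting that bulk normal-tissue compendia typically do
#' not profile it.
#'
#' @return Character vector of tissue names.
#' @export
default_normal_tissues <- function() {
  c("Adrenal", "Kidney", "Muscle", "Nerve", "Skin", "Brain",
    "Adipose", "Artery", "Bladder", "Breast", "Cervix", "Colon",
    "Esophagus", "Heart", "Liver", "Lung", "Ovary", "Pancreas",
    "Pituitary", "Prostate", "Salivary_Gland", "Small_Intestine",
    "Spleen", "Stomach", "Testis", "Thyroid", "Uterus", "Vagina",
    "Whole_Blood")
}

#' Default tumor-to-normal paired tissue map
#'
#' The five tumor types whose tissue of origin is profiled in the normal
#' panel; a Tier 1 target supported by one of these tumor types must not be
#' highly expressed in the paired tissue.
#'
#' @return Named character vector mapping tumor group to normal tissue.
#' @export
default_pair_map <- function() {
  c(ACT = "Adrenal", WLM = "Kidney", RHB = "Muscle", RB = "Nerve",
    MEL = "Skin")
}

#' Configuration for the synthetic data generator
#'
#' Defines the study conditions emulated by the generator: gene-model shape,
#' cohort structure, planted effect sizes, expression noise, and the
#' confounder genes that exercise each curation and tiering check.
#'
#' Background expression is log-normal per exon (`sdlog = sigma`) around a
#' per-gene baseline with a small per-exon deviation (`exon_dev_sd`), plus
#' per-gene-by-group offsets (`group_offset_sd`) representing between-group
#' biological variability.  The whole matrix is subject to a detection floor
#' (`min_detect`): FPKM below the floor is reported as exactly 0, emulating
#' count quantization in real RNA-seq.
#'
#' Planted targets are tumor-restricted: the target exons (all exons of a
#' gene-level target, the cassette exon of an AS target) sit far below the
#' detection floor (`restricted_normal_fpkm`) in every normal tissue, so
#' their normal values are tied at zero -- which is exactly what lets a real
#' target clear the "at most five normal tissues above median" rule -- while
#' all tumor groups are shifted up `fold_gene_level`/`fold_as`-fold.
#' Tiering confounder genes are planted gene-level targets given the
#' additional signal the corresponding check is designed to catch.  3'-bias
#' confounders emulate the false positives produced by 3'-biased normal
#' library protocols: a broadly expressed gene (`bias_gene_fpkm` in tumors
#' and normals alike) whose normal-cohort coverage ramps linearly from 0 at
#' the 5'-most exon to its full level at the 3'-most exon, so its 5' exons
#' masquerade as tumor-specific until the exon-position regression flags the
#' gene.
#'
#' @param n_genes Number of genes to simulate.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_length Integer range of exon lengths in bp.
#' @param intron_length Integer range of intron lengths in bp.
#' @param frac_multi_transcript Fraction of genes given a second, cassette
#'   exon-skipping transcript.
#' @param tumor_groups Tibble as returned by [default_tumor_groups()].
#' @param normal_tissues Character vector of normal tissue names; must contain
#'   the five paired tissues and Brain.
#' @param samples_per_tumor_group,samples_per_normal_tissue Group sizes.
#' @param n_planted_gene_level,n_planted_as Numbers of planted targets.
#' @param n_confounders Named integer vector with entries `paired_normal`,
#'   `bone_marrow`, `normal_protein`, `three_prime_bias`.
#' @param fold_gene_level,fold_as,fold_confounder Linear fold changes.
#' @param sigma Log-normal sdlog of within-group expression noise.
#' @param group_offset_sd Sd of per-gene-by-group mean offsets (log scale).
#' @param base_meanlog Mean and sd of the per-gene baseline (log scale).
#' @param exon_dev_sd Sd of the per-exon deviation around the gene baseline
#'   (log scale).
#' @param min_detect Detection floor in FPKM; simulated values below it are
#'   reported as exactly 0.
#' @param restricted_normal_fpkm Normal-tissue expression level (FPKM) of
#'   planted target exons; must sit far below `min_detect`.
#' @param bias_gene_fpkm Expression level of 3'-bias confounder genes in all
#'   samples before the positional coverage ramp is applied to normals.
#' @param frac_null_annotated Fraction of null genes placed in the surfaceome
#'   or matrisome.
#' @param frac_null_blacklist Fraction of null genes placed in a blacklist
#'   category.
#' @param n_bm_samples Number of bone-marrow samples in the gene-level panel.
#' @param n_calibration Named vector with `expressed` and `silent` calibration
#'   gene counts for the bone-marrow classifier.
#' @param npsm_meanlog10 Named vector `low`/`high`: log10 means of the two
#'   normal-proteome nPSM mixture components.
#' @param npsm_sdlog10 Common log10 sd of the nPSM mixture components.
#' @param variant_carrier_fraction Fraction of tumor samples carrying a
#'   splice-site-proximal variant at each planted AS exon.
#' @param variant_window Splice-site window in bp.
#' @param read_length Simulated read length for alignment fixtures.
#'
#' @return A list of class `cse_sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       exons_per_gene = c(4L, 10L),
                       exon_length = c(60L, 600L),
                       intron_length = c(200L, 2000L),
                       frac_multi_transcript = 0.3,
                       tumor_groups = default_tumor_groups(),
                       normal_tissues = default_normal_tissues(),
                       samples_per_tumor_group = 15L,
                       samples_per_normal_tissue = 30L,
                       n_planted_gene_level = 20L,
                       n_planted_as = 5L,
                       n_confounders = c(paired_normal = 2L, bone_marrow = 2L,
                                         normal_protein = 2L,
                                         three_prime_bias = 2L),
                       fold_gene_level = 8,
                       fold_as = 8,
                       fold_confounder = 8,
                       sigma = 0.3,
                       group_offset_sd = 0.1,
                       base_meanlog = c(mean = 1, sd = 1),
                       exon_dev_sd = 0.1,
                       min_detect = 0.25,
                       restricted_normal_fpkm = 0.05,
                       bias_gene_fpkm = 10,
                       frac_null_annotated = 0.3,
                       frac_null_blacklist = 0.2,
                       n_bm_samples = 20L,
                       n_calibration = c(expressed = 30L, silent = 30L),
                       npsm_meanlog10 = c(low = -2, high = 0),
                       npsm_sdlog10 = 0.3,
                       variant_carrier_fraction = 0.15,
                       variant_window = 10L,
                       read_length = 50L) {
  assert_range(exons_per_gene, "exons_per_gene")
  assert_range(exon_length, "exon_length")
  assert_range(intron_length, "intron_length")
  if (n_genes < 1) {
    abort("`n_genes` must be >= 1.", class = "csefinder_config_error")
  }
  if (exons_per_gene[1] < 2) {
    abort("`exons_per_gene` minimum must be >= 2.",
          class = "csefinder_config_error")
  }
  if (samples_per_tumor_group < 1 || samples_per_normal_tissue < 1) {
    abort("Group sizes must be positive.", class = "csefinder_config_error")
  }
  if (min_detect > 0 && restricted_normal_fpkm >= min_detect) {
    abort("`restricted_normal_fpkm` must lie below the `min_detect` floor.",
          class = "csefinder_config_error")
  }
  absent <- setdiff(c(unname(default_pair_map()), "Brain"), normal_tissues)
  if (length(absent)) {
    abort(paste0("Normal tissue panel is missing required tissues: ",
                 paste(absent, collapse = ", ")),
          class = "csefinder_config_error")
  }
  cfg <- mget(names(formals(sim_config)))
  structure(cfg, class = "cse_sim_config")
}
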