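#' Simulate a tumor/normal expression cohort with planted targets
#'
#' Builds an exon-by-sample FPKM matrix for the study design in `config`,
#' together with a sample table and a ground-truth manifest.  Background
#' expression is log-normal with a detection floor (values below
#' `min_detect` FPKM are reported as exactly 0, as count quantization does in
#' real data).  Planted target exons (all exons of a gene-level target, the
#' cassette exon of an AS target) are tumor-restricted: shifted up in every
#' tumor group and silenced below the detection floor in every normal
#' tissue, so their normal values tie at zero.  Confounder genes receive the
#' additional signal that each tiering or curation check is designed to
#' catch:
#'
#' * `paired_normal` confounders are also highly expressed in one of the five
#'   tumor-paired normal tissues;
#' * `bone_marrow` confounders are highly expressed in the separate
#'   bone-marrow gene-level panel;
#' * `normal_protein` confounders are flagged for the proteomics generator,
#'   which draws their normal-panel nPSM from the upper mixture component;
#' * `three_prime_bias` confounders emulate 3'-biased normal library
#'   coverage: the gene is expressed at `bias_gene_fpkm` in tumors and
#'   normals alike, but normal coverage ramps linearly from 0 at the 5'-most
#'   exon to the full level at the 3'-most exon, so the 5' exons masquerade
#'   as tumor-specific.
#'
#' Setting all fold parameters to 1 and `n_confounders` to zero yields a
#' no-signal cohort for null calibration.
#'
#' @param models A `cse_models` object.
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return A list of class `cse_cohort` with elements `expr` (exon x sample
#'   FPKM matrix), `samples` (tibble: sample_id, cohort, group, compartment,
#'   data_source), `truth` (ground-truth manifest), `bm` (gene x sample
#'   bone-marrow expression matrix including calibration genes), and
#'   `calibration` (tibble: gene_id, expressed).
#' @export
sim_cohort <- function(models, config = sim_config(), seed = 1L) {
  stopifnot(inherits(models, "cse_models"), inherits(config, "cse_sim_config"))
  with_seed(sub_seed(seed, 2L), {
    samples <- build_sample_table(config)
    exons <- models$exons
    ne <- nrow(exons)
    ns <- nrow(samples)

    truth <- plant_truth(models, config)

    # per-gene baseline + per-exon deviation, and per-gene x group offsets
    gene_ids <- models$genes$gene_id
    gene_base <- rnorm(length(gene_ids), config$base_meanlog[["mean"]],
                       config$base_meanlog[["sd"]])
    names(gene_base) <- gene_ids
    # 3'-bias confounders sit at a fixed, well-detected level
    tp <- truth$confounders[truth$confounders$type == "three_prime_bias", ]
    gene_base[tp$gene_id] <- log(config$bias_gene_fpkm)
    base <- gene_base[exons$gene_id] + rnorm(ne, 0, config$exon_dev_sd)
    groups <- unique(samples$group)
    offsets <- matrix(rnorm(length(gene_ids) * length(groups),
                            0, config$group_offset_sd),
                      nrow = length(gene_ids),
                      dimnames = list(gene_ids, groups))

    meanlog <- matrix(base, nrow = ne, ncol = ns)
    gidx <- match(exons$gene_id, gene_ids)
    sgrp <- match(samples$group, groups)
    meanlog <- meanlog + offsets[cbind(rep(gidx, times = ns),
                                       rep(sgrp, each = ne))]

    tumor_cols <- samples$cohort == "tumor"
    normal_cols <- samples$cohort == "normal"
    # planted gene-level: all exons up in all tumor groups
    gl_rows <- exons$gene_id %in% truth$planted_gene_level
    meanlog[gl_rows, tumor_cols] <-
      meanlog[gl_rows, tumor_cols] + log(config$fold_gene_level)
    # planted AS: cassette exon only
    as_rows <- exons$exon_id %in% truth$planted_as$exon_id
    meanlog[as_rows, tumor_cols] <-
      meanlog[as_rows, tumor_cols] + log(config$fold_as)

    # restricted exons are silent (below detection) in all normal tissues
    restricted_rows <- gl_rows | as_rows
    meanlog[restricted_rows, normal_cols] <- log(config$restricted_normal_fpkm)

    # paired-normal confounders: tumor-level expression in the flagged tissue
    pn <- truth$confounders[truth$confounders$type == "paired_normal", ]
    for (j in seq_len(nrow(pn))) {
      rows <- exons$gene_id == pn$gene_id[j]
      cols <- samples$group == pn$detail[j]
      meanlog[rows, cols] <- base[rows] + log(config$fold_confounder)
    }

    expr <- matrix(rlnorm(ne * ns, meanlog = meanlog, sdlog = config$sigma),
                   nrow = ne,
                   dimnames = list(exons$exon_id, samples$sample_id))

    # 3'-bias confounders: multiplicative 5'->3' coverage ramp in normals
    if (nrow(tp)) {
      for (g in tp$gene_id) {
        rows <- which(exons$gene_id == g)
        k <- exons$index_in_gene[rows]
        ramp <- (k - 1) / max(k - 1)
        expr[rows, normal_cols] <- expr[rows, normal_cols] * ramp
      }
    }

    # detection floor: sub-threshold FPKM is reported as exactly zero
    if (config$min_detect > 0) expr[expr < config$min_detect] <- 0

    bm <- sim_bone_marrow(models, truth, config)

    structure(list(expr = expr, samples = samples, truth = truth,
                   bm = bm$expr, calibration = bm$calibration),
              class = "cse_cohort")
  })
}

build_sample_table <- function(config) {
  tg <- config$tumor_groups
  tumor <- purrr::pmap(list(tg$group, tg$compartment, tg$sources),
    function(group, compartment, sources) {
      n <- config$samples_per_tumor_group
      src <- rep(sources, length.out = n)
      tibble::tibble(
        sample_id = sprintf("%s_%02d", group, seq_len(n)),
        cohort = "tumor", group = group, compartment = compartment,
        data_source = sort(src))
    }) |> dplyr::bind_rows()
  normal <- purrr::map(config$normal_tissues, function(t) {
    n <- config$samples_per_normal_tissue
    tibble::tibble(
      sample_id = sprintf("%s_N%02d", t, seq_len(n)),
      cohort = "normal", group = t, compartment = NA_character_,
      data_source = "GTEx")
  }) |> dplyr::bind_rows()
  dplyr::bind_rows(tumor, normal)
}

plant_truth <- function(models, config) {
  single_tx <- models$genes$gene_id[
    !models$genes$gene_id %in% models$cassettes$gene_id]
  cassette_genes <- models$cassettes$gene_id

  if (length(cassette_genes) < config$n_planted_as) {
    abort("Not enough cassette genes to plant the requested AS targets.",
          class = "csefinder_config_error")
  }
  as_genes <- sort(sample(cassette_genes, config$n_planted_as))
  # gene-level targets planted on single-isoform genes so ground-truth
  # classes are unambiguous
  if (length(single_tx) < config$n_planted_gene_level) {
    abort("Not enough single-transcript genes to plant gene-level targets.",
          class = "csefinder_config_error")
  }
  gl_genes <- sort(sample(single_tx, config$n_planted_gene_level))

  nc <- config$n_confounders
  n_tier_conf <- sum(nc[c("paired_normal", "bone_marrow", "normal_protein")])
  if (n_tier_conf > length(gl_genes)) {
    abort("Tiering confounders exceed the planted gene-level targets.",
          class = "csefinder_config_error")
  }
  pick <- function(pool, k) if (k > 0) sample(pool, k) else character(0)
  gl_pool <- gl_genes
  pn_genes <- pick(gl_pool, nc[["paired_normal"]])
  gl_pool <- setdiff(gl_pool, pn_genes)
  bm_genes <- pick(gl_pool, nc[["bone_marrow"]])
  gl_pool <- setdiff(gl_pool, bm_genes)
  np_genes <- pick(gl_pool, nc[["normal_protein"]])

  # 3'-bias confounders go on multi-exon single-transcript genes not already
  # planted, so the position-bias regression has enough exons to work with
  tp_pool <- models$genes$gene_id[
    models$genes$gene_id %in% single_tx &
      !models$genes$gene_id %in% gl_genes &
      models$genes$n_exons >= 6L]
  if (length(tp_pool) < nc[["three_prime_bias"]]) {
    abort("Not enough long single-transcript genes for 3'-bias confounders.",
          class = "csefinder_config_error")
  }
  tp_genes <- pick(tp_pool, nc[["three_prime_bias"]])

  null_genes <- setdiff(models$genes$gene_id,
                        c(gl_genes, as_genes, tp_genes))

  pairs <- default_pair_map()
  confounders <- dplyr::bind_rows(
    tibble::tibble(gene_id = pn_genes, type = "paired_normal",
                   detail = rep(unname(pairs), length.out = length(pn_genes))),
    tibble::tibble(gene_id = bm_genes, type = "bone_marrow", detail = "Bone_Marrow"),
    tibble::tibble(gene_id = np_genes, type = "normal_protein", detail = "upper"),
    tibble::tibble(gene_id = tp_genes, type = "three_prime_bias", detail = "normals"))

  planted_as <- models$cassettes |>
    dplyr::filter(.data$gene_id %in% as_genes)

  list(planted_gene_level = gl_genes,
       planted_as = planted_as,
       null_genes = null_genes,
       confounders = confounders,
       effects = list(fold_gene_level = config$fold_gene_level,
                      fold_as = config$fold_as,
                      fold_confounder = config$fold_confounder,
                      sigma = config$sigma))
}

# Gene-level bone-marrow panel (microarray-like): model genes plus labeled
# calibration genes for the logistic classifier.
sim_bone_marrow <- function(models, truth, config) {
  nb <- config$n_bm_samples
  gene_ids <- models$genes$gene_id
  high <- truth$confounders$gene_id[truth$confounders$type == "bone_marrow"]
  mu <- ifelse(gene_ids %in% high, 3, -1)
  n_exp <- config$n_calibration[["expressed"]]
  n_sil <- config$n_calibration[["silent"]]
  cal <- tibble::tibble(
    gene_id = c(sprintf("CAL_EXP%03d", seq_len(n_exp)),
                sprintf("CAL_SIL%03d", seq_len(n_sil))),
    expressed = rep(c(TRUE, FALSE), c(n_exp, n_sil)))
  mu_all <- c(mu, ifelse(cal$expressed, 3, -2))
  ids <- c(gene_ids, cal$gene_id)
  expr <- matrix(rlnorm(length(ids) * nb, meanlog = rep(mu_all, nb), sdlog = 0.5),
                 nrow = length(ids),
                 dimnames = list(ids, sprintf("BM_%02d", seq_len(nb))))
  list(expr = expr, calibration = cal)
}
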