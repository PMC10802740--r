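#' Pipeline thresholds and options
#'
#' All thresholds default to the workflow's standard constants: composite
#' Z-score > 1, at most 5 above-median normal tissues, <40% transcript CSE
#' coverage for AS candidacy, bias-test alpha 0.01, 1 FPKM expression floor,
#' 0.75 percentile-rank high-expression convention, 10 bp splice-site
#' window, and at least 1 tumor PSM.
#'
#' @param z_star Composite Z threshold.
#' @param max_normals Maximum above-median normal tissues.
#' @param coverage AS coverage threshold (strict <).
#' @param bias_alpha P-value threshold of the exon-position bias check.
#' @param fpkm_floor Expression floor for binned scores.
#' @param rank_high Median-percentile-rank threshold meaning high expression.
#' @param window Splice-site variant window (bp).
#' @param min_psm Minimum tumor PSM count.
#' @param rank_scope Percentile-rank population, "compartment" or "pair".
#' @param bias_scope Bias-check scope, "brain" or "all".
#' @param library_mode FPKM library-size definition for SAM input.
#' @param read_length Read length for FPKM short-exon substitution.
#' @param pair_map Tumor-to-paired-tissue map.
#' @return A list of class `cse_thresholds`.
#' @export
cse_thresholds <- function(z_star = 1, max_normals = 5, coverage = 0.40,
                           bias_alpha = 0.01, fpkm_floor = 1,
                           rank_high = 0.75, window = 10L, min_psm = 1L,
                           rank_scope = "compartment", bias_scope = "brain",
                           library_mode = "exonic", read_length = 100L,
                           pair_map = default_pair_map()) {
  stopifnot(z_star >= 0, max_normals >= 0, coverage > 0, coverage <= 1,
            bias_alpha > 0, bias_alpha < 1, rank_high > 0.5, rank_high <= 1,
            window >= 0, min_psm >= 0)
  structure(mget(names(formals(cse_thresholds))), class = "cse_thresholds")
}

#' Validate an input bundle
#'
#' Schema checks on every input: expression columns must be covered exactly
#' by the sample table, ids must be unique, required columns and tissues must
#' be present.  Errors are collected, not fail-fast.
#'
#' @param bundle A `cse_bundle` (in-memory) or a directory path.
#' @return Tibble `input`, `error`; zero rows when the bundle is valid.
#' @export
validate_inputs <- function(bundle) {
  if (is.character(bundle)) {
    needed <- c("models.gtf", "expression.tsv", "samples.tsv", "genesets.gmt",
                "proteomics.tsv", "bm_expression.tsv", "calibration.tsv",
                "variants.tsv")
    missing <- needed[!file.exists(file.path(bundle, needed))]
    if (length(missing)) {
      return(tibble::tibble(input = missing, error = "file missing"))
    }
    bundle <- read_bundle(bundle)
  }
  errs <- list()
  add <- function(input, error) {
    errs[[length(errs) + 1L]] <<- tibble::tibble(input = input, error = error)
  }
  s <- bundle$samples
  req <- c("sample_id", "cohort", "group", "compartment", "data_source")
  if (!all(req %in% names(s))) {
    add("samples", paste0("missing column(s): ",
                          paste(setdiff(req, names(s)), collapse = ", ")))
  } else {
    if (anyDuplicated(s$sample_id)) add("samples", "duplicated sample id")
    extra <- setdiff(colnames(bundle$expr), s$sample_id)
    absent <- setdiff(s$sample_id, colnames(bundle$expr))
    if (length(extra)) {
      add("expression", paste0("columns not in sample table: ",
                               paste(head(extra, 5), collapse = ", ")))
    }
    if (length(absent)) {
      add("expression", paste0("samples without expression column: ",
                               paste(head(absent, 5), collapse = ", ")))
    }
    tissues <- unique(s$group[s$cohort == "normal"])
    need_t <- c(unname(default_pair_map()), "Brain")
    miss_t <- setdiff(need_t, tissues)
    if (length(miss_t)) {
      add("samples", paste0("missing normal tissue(s): ",
                            paste(miss_t, collapse = ", ")))
    }
  }
  if (anyDuplicated(rownames(bundle$expr))) add("expression", "duplicated exon id")
  if (any(!is.finite(bundle$expr)) || any(bundle$expr < 0)) {
    add("expression", "non-finite or negative values")
  }
  unk <- setdiff(rownames(bundle$expr), bundle$models$exons$exon_id)
  if (length(unk)) {
    add("expression", paste0("exon ids not in gene models: ",
                             paste(head(unk, 5), collapse = ", ")))
  }
  preq <- c("gene_id", "panel", "psm_count", "aa_length")
  if (!all(preq %in% names(bundle$proteomics))) {
    add("proteomics", paste0("missing column(s): ",
                             paste(setdiff(preq, names(bundle$proteomics)),
                                   collapse = ", ")))
  }
  if (!all(c("gene_id", "expressed") %in% names(bundle$calibration))) {
    add("calibration", "missing gene_id/expressed columns")
  }
  dplyr::bind_rows(errs) %||%
    tibble::tibble(input = character(0), error = character(0))
}

#' Run the CSE discovery pipeline end-to-end
#'
#' Executes the five workflow steps on an input bundle: (1) exon
#' quantification (precomputed FPKM, or counting + FPKM when `sam_files` is
#' given), (2) tumor-versus-normal differential expression per compartment
#' with composite Z selection, (3) surfaceome/matrisome intersection with
#' blacklist removal, (4) curation of expression specificity, and (5)
#' AS-versus-gene-level classification with tier assignment, scoring and
#' splice-variant association.  A stage ledger records entity counts and
#' drop reasons at every step; reruns with the same bundle, thresholds and
#' seed are bit-identical.
#'
#' @param bundle A `cse_bundle` or a bundle directory path.
#' @param thresholds A [cse_thresholds()] object.
#' @param sam_files Optional named SAM paths; when given, expression is
#'   computed from alignments instead of the bundle matrix.
#' @param out_dir Optional directory for the portal export bundle.
#' @return Object of class `cse_run`: list with `targets` (final target
#'   table), `candidates`, `qc`, `classification`, `tiers`, `scores`,
#'   `diffexp` (per compartment), `ledger`, `npsm_cutoff`, `bm_classifier`,
#'   `variant_tests`, `thresholds`.
#' @export
run_pipeline <- function(bundle, thresholds = cse_thresholds(),
                         sam_files = NULL, out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(thresholds, "cse_thresholds"))
  th <- thresholds
  errs <- validate_inputs(bundle)
  if (nrow(errs)) {
    abort(paste0("Input validation failed:\n",
                 paste(errs$input, errs$error, sep = ": ", collapse = "\n")),
          class = "csefinder_validation_error")
  }
  ledger <- list()
  note <- function(stage, n_exons, n_genes, detail = NA_character_) {
    ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      stage = stage, n_exons = n_exons, n_genes = n_genes, detail = detail)
  }

  # 1. quantification
  expr <- if (!is.null(sam_files)) {
    counts <- count_exon_reads(sam_files, bundle$models,
                               library_mode = th$library_mode)
    fpkm_normalize(counts, read_length = th$read_length)
  } else {
    bundle$expr
  }
  note("quantify", nrow(expr), length(unique(exon_gene(rownames(expr)))))

  # 2. differential expression + CSE selection per compartment
  comps <- sort(unique(stats::na.omit(bundle$samples$compartment)))
  diffs <- stats::setNames(lapply(comps, function(cp) {
    run_differential(expr, bundle$samples, cp, rank_scope = th$rank_scope)
  }), comps)
  candidates <- dplyr::bind_rows(lapply(diffs, select_cse,
                                        z_star = th$z_star,
                                        max_normals = th$max_normals))
  note("select_cse", length(unique(candidates$exon_id)),
       length(unique(candidates$gene_id)))

  # 3. surfaceome/matrisome + blacklist
  localized <- filter_localization(candidates, bundle$annotations)
  dropped_ann <- attr(localized, "dropped")
  note("localization", length(unique(localized$exon_id)),
       length(unique(localized$gene_id)),
       paste0("dropped_genes=", nrow(dropped_ann)))

  # 4. curation QC
  ranks_by_comp <- lapply(diffs, `[[`, "ranks")
  gm_by_comp <- lapply(diffs, `[[`, "group_median_ranks")
  qc <- if (nrow(localized)) {
    curate_candidates(localized, ranks_by_comp, gm_by_comp, bundle$samples,
                      expr, bundle$models, bundle$proteomics,
                      min_psm = th$min_psm, bias_alpha = th$bias_alpha,
                      brain_q = th$rank_high, bias_scope = th$bias_scope)
  } else {
    localized |> dplyr::mutate(final_keep = logical(0))
  }
  curated <- qc |> dplyr::filter(.data$final_keep)
  note("curation", length(unique(curated$exon_id)),
       length(unique(curated$gene_id)))

  # 5a. classification (needed by the bone-marrow tier check)
  classification <- if (nrow(curated)) {
    classify_targets(curated, bundle$models,
                     coverage_threshold = th$coverage)
  } else {
    tibble::tibble(gene_id = character(0), target_class = character(0),
                   chosen_exon = character(0), coverage_min = numeric(0),
                   cse_exon_ids = list())
  }

  # per-gene target skeleton: representative exon = top-composite CSE
  targets <- if (nrow(curated) == 0L) {
    tibble::tibble(
      gene_id = character(0), representative_exon = character(0),
      composite_z_max = numeric(0), compartments = character(0),
      compartment = character(0), supporting_groups = list(),
      localization = character(0), oncofetal = logical(0),
      n_cse_exons = integer(0), target_class = character(0),
      chosen_exon = character(0), coverage_min = numeric(0),
      cse_exon_ids = list())
  } else curated |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      representative_exon = .data$exon_id[which.max(.data$composite_z)],
      composite_z_max = max(.data$composite_z),
      compartments = paste(sort(unique(.data$compartment)), collapse = ";"),
      compartment = .data$compartment[which.max(.data$composite_z)],
      supporting_groups = list(sort(unique(unlist(.data$supporting_groups)))),
      localization = .data$localization[1],
      oncofetal = .data$oncofetal[1],
      n_cse_exons = dplyr::n_distinct(.data$exon_id),
      .groups = "drop") |>
    dplyr::left_join(classification, by = "gene_id") |>
    dplyr::mutate(representative_exon = dplyr::coalesce(
      .data$chosen_exon, .data$representative_exon))

  # 5b. tiering
  bm_classifier <- fit_bm_classifier(bundle$calibration, bundle$bm)
  npsm_fit <- bimodal_cutoff(
    bundle$proteomics$npsm[bundle$proteomics$panel == "normal"] %||%
      with(bundle$proteomics[bundle$proteomics$panel == "normal", ],
           psm_count / aa_length))
  tiers <- if (nrow(targets)) {
    assign_tiers(targets, gm_by_comp, bundle$bm, bm_classifier,
                 bundle$proteomics, npsm_fit$cutoff,
                 pair_map = th$pair_map, rank_high = th$rank_high)
  } else {
    targets |> dplyr::mutate(tier = integer(0), failed_checks = character(0))
  }
  note("tier_classify", length(unique(curated$exon_id)), nrow(tiers),
       paste0("tier1=", sum(tiers$tier == 1L), ";tier2=",
              sum(tiers$tier == 2L), ";AS=",
              sum(tiers$target_class == "AS")))

  # 5c. splice-variant association for AS targets
  as_targets <- tiers |> dplyr::filter(.data$target_class == "AS")
  variant_tests <- purrr::pmap(
    list(as_targets$gene_id, as_targets$chosen_exon),
    function(g, e) {
      ex <- bundle$models$exons[bundle$models$exons$exon_id == e, ]
      carriers <- near_splice_variants(
        bundle$variants[bundle$variants$gene_id == g, ], ex,
        window = th$window)
      splice_variant_test(expr[e, ], carriers, bundle$samples) |>
        dplyr::mutate(gene_id = g, exon_id = e, n_carrier_total =
                        length(carriers), .before = 1)
    }) |> dplyr::bind_rows()

  # 5d. scoring
  scores <- if (nrow(tiers)) {
    score_exons(expr, bundle$samples,
                exon_ids = unique(tiers$representative_exon),
                floor = th$fpkm_floor)
  } else {
    NULL
  }
  final <- tiers
  if (!is.null(scores)) {
    final <- final |>
      dplyr::left_join(scores$summary,
                       by = c(representative_exon = "exon_id"))
  }

  run <- structure(list(
    targets = final, candidates = candidates, localized = localized,
    qc = qc, classification = classification, tiers = tiers,
    scores = scores, diffexp = diffs, ledger = dplyr::bind_rows(ledger),
    npsm_cutoff = npsm_fit, bm_classifier = bm_classifier,
    variant_tests = variant_tests, dropped_annotation = dropped_ann,
    thresholds = th), class = "cse_run")
  attr(run, "models") <- bundle$models
  if (!is.null(out_dir)) export_portal(run, out_dir)
  run
}

#' @export
print.cse_run <- function(x, ...) {
  cat(sprintf(
    "<cse_run> %d targets (%d Tier 1, %d Tier 2; %d AS, %d gene-level)\n",
    nrow(x$targets), sum(x$targets$tier == 1), sum(x$targets$tier == 2),
    sum(x$targets$target_class == "AS"),
    sum(x$targets$target_class == "gene_level")))
  print(x$ledger)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `cse_run` object.
#' @param ... Unused.
#' @method tidy cse_run
#' @export
tidy.cse_run <- function(x, ...) {
  x$targets |>
    dplyr::select("gene_id", "target_class", "tier", "representative_exon",
                  "composite_z_max", "compartments", "localization",
                  "oncofetal", "failed_checks",
                  dplyr::any_of(c("tumor_score", "normal_score")))
}

#' @rdname run_pipeline
#' @method glance cse_run
#' @export
glance.cse_run <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$targets),
    n_tier1 = sum(x$targets$tier == 1),
    n_tier2 = sum(x$targets$tier == 2),
    n_as = sum(x$targets$target_class == "AS"),
    n_gene_level = sum(x$targets$target_class == "gene_level"),
    n_candidate_exons = length(unique(x$candidates$exon_id)),
    n_candidate_genes = length(unique(x$candidates$gene_id)),
    npsm_cutoff_log10 = x$npsm_cutoff$cutoff_log10)
}
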