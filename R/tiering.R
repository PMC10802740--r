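#' Paired normal tissue check
#'
#' A target fails when any of its supporting tumor types has a paired normal
#' tissue (by default ACT/Adrenal, WLM/Kidney, RHB/Muscle, RB/Nerve,
#' MEL/Skin) whose median percentile rank for the target exon is at or above
#' `rank_high`.  Supporting types without a pair are exempt.
#'
#' @param supporting_groups Character vector of supporting tumor types.
#' @param exon_median_ranks Named vector of the exon's median percentile rank
#'   per group (a row of the group-median matrix).
#' @param pair_map Named character vector tumor type -> normal tissue.
#' @param rank_high High-expression rank threshold (default 0.75).
#' @return List with `status` ("pass"/"fail"/"not_applicable") and `detail`.
#' @export
paired_normal_check <- function(supporting_groups, exon_median_ranks,
                                pair_map = default_pair_map(),
                                rank_high = 0.75) {
  unknown <- setdiff(unname(pair_map), names(exon_median_ranks))
  if (length(unknown)) {
    abort(paste0("pair_map references unknown tissue(s): ",
                 paste(unknown, collapse = ", ")))
  }
  paired <- intersect(supporting_groups, names(pair_map))
  if (!length(paired)) {
    return(list(status = "not_applicable", detail = NA_character_))
  }
  tissues <- pair_map[paired]
  high <- exon_median_ranks[tissues] >= rank_high
  if (any(high)) {
    list(status = "fail",
         detail = paste(paste0(paired[high], "/", tissues[high]),
                        collapse = ";"))
  } else {
    list(status = "pass", detail = NA_character_)
  }
}

#' Fit the bone-marrow expression classifier
#'
#' Logistic regression of expressed status on `log2(median bone-marrow
#' expression + 1)` over labeled calibration genes.  When the groups are
#' perfectly separated (so the unpenalized likelihood diverges), the model is
#' refit with a small fixed ridge penalty (lambda = 0.01) by iteratively
#' reweighted least squares; the decision boundary is the probability-0.5
#' point either way.
#'
#' @param calibration Tibble with `gene_id` and logical `expressed`; at least
#'   10 genes of each class.
#' @param bm_expr Gene x sample bone-marrow expression matrix containing the
#'   calibration genes.
#' @return Object of class `cse_bm_classifier` with `coef` (intercept,
#'   slope), `method`, `boundary` (expression value at probability 0.5) and
#'   `training_accuracy`.
#' @export
fit_bm_classifier <- function(calibration, bm_expr) {
  if (sum(calibration$expressed) < 10 || sum(!calibration$expressed) < 10) {
    abort("Need >= 10 expressed and >= 10 silent calibration genes.")
  }
  miss <- setdiff(calibration$gene_id, rownames(bm_expr))
  if (length(miss)) {
    abort(paste0("Calibration genes missing from bone-marrow matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  x <- log2(row_medians(bm_expr[calibration$gene_id, , drop = FALSE]) + 1)
  y <- as.numeric(calibration$expressed)

  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  separated <- any(abs(coef(fit)) > 20) ||
    all(abs(fit$fitted.values - y) < 1e-8)
  method <- "glm"
  beta <- unname(coef(fit))
  if (separated) {
    beta <- unname(ridge_logistic(x, y, lambda = 0.01))
    method <- "ridge"
  }
  prob <- plogis(beta[1] + beta[2] * x)
  structure(list(
    coef = c(intercept = beta[1], slope = beta[2]),
    method = method,
    boundary = unname(2^(-beta[1] / beta[2]) - 1),
    training_accuracy = mean((prob >= 0.5) == (y == 1))),
    class = "cse_bm_classifier")
}

# Ridge-penalized logistic regression (penalty on the slope only) by IRLS;
# the fixed penalty keeps coefficients finite under complete separation.
ridge_logistic <- function(x, y, lambda = 0.01, iter = 50L) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  P <- diag(c(0, lambda))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X) + P, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

#' Predict expressed-probability from the bone-marrow classifier
#' @param object A `cse_bm_classifier`.
#' @param bm_values Numeric vector of (median) bone-marrow expression values.
#' @param ... Unused.
#' @return Probabilities of being expressed in bone marrow.
#' @export
predict.cse_bm_classifier <- function(object, bm_values, ...) {
  x <- log2(bm_values + 1)
  plogis(object$coef[["intercept"]] + object$coef[["slope"]] * x)
}

#' Bone-marrow low-expression check for gene-level targets
#'
#' Gene-level targets pass when the classifier's expressed-probability is
#' below 0.5.  AS targets are not applicable (the bone-marrow panel is
#' gene-level).  Genes missing from the panel fail safe with "no-data"
#' evidence (demoted, never promoted).
#'
#' @param genes Character vector of gene ids.
#' @param target_class Character vector, "gene_level" or "AS", same length.
#' @param bm_expr Gene x sample bone-marrow expression matrix.
#' @param classifier A `cse_bm_classifier`.
#' @return Tibble `gene_id`, `bm_prob`, `bone_marrow`
#'   (pass/fail/not_applicable), `bone_marrow_detail`.
#' @export
bm_low_expression <- function(genes, target_class, bm_expr, classifier) {
  purrr::map2(genes, target_class, function(g, cls) {
    if (cls == "AS") {
      return(tibble::tibble(gene_id = g, bm_prob = NA_real_,
                            bone_marrow = "not_applicable",
                            bone_marrow_detail = NA_character_))
    }
    if (!g %in% rownames(bm_expr)) {
      return(tibble::tibble(gene_id = g, bm_prob = NA_real_,
                            bone_marrow = "fail",
                            bone_marrow_detail = "no-data"))
    }
    p <- unname(predict(classifier, median(bm_expr[g, ])))
    tibble::tibble(gene_id = g, bm_prob = p,
                   bone_marrow = if (p < 0.5) "pass" else "fail",
                   bone_marrow_detail = NA_character_)
  }) |> dplyr::bind_rows()
}

#' Bimodal nPSM cutoff
#'
#' Normal-proteome nPSM values are bimodal on the log10 scale (unexpressed
#' versus expressed proteins).  A two-component equal-variance Gaussian
#' mixture is fit to `log10` of the positive values and the cutoff is the
#' point between the component means where the posterior responsibilities are
#' equal (closed form for equal variances).  When the fitted components are
#' closer than `tol`, the fit is degenerate and the distribution median is
#' returned with `fallback = TRUE`.
#'
#' @param npsm Numeric nPSM values; at least `min_n` must be positive.
#' @param min_n Minimum number of positive values (default 20).
#' @param tol Minimum component separation in log10 units (default 0.1).
#' @return List with `cutoff_log10`, `cutoff` (nPSM scale), `fallback`, and
#'   the mixture parameters (`means`, `sd`, `weights`).
#' @export
bimodal_cutoff <- function(npsm, min_n = 20L, tol = 0.1) {
  v <- log10(npsm[is.finite(npsm) & npsm > 0])
  if (length(v) < min_n) {
    abort(sprintf("Need at least %d positive nPSM values.", min_n))
  }
  # unqualified call: Mclust() resolves mclustBIC() in the calling namespace,
  # so both are imported
  fit <- Mclust(v, G = 2, modelNames = "E", verbose = FALSE)
  if (is.null(fit)) {
    warn("Mixture fit failed; falling back to the median.")
    cut <- median(v)
    return(list(cutoff_log10 = cut, cutoff = 10^cut, fallback = TRUE,
                means = c(NA_real_, NA_real_), sd = NA_real_,
                weights = c(NA_real_, NA_real_)))
  }
  mu <- unname(sort(fit$parameters$mean))
  pro <- unname(fit$parameters$pro[order(fit$parameters$mean)])
  s2 <- unname(fit$parameters$variance$sigmasq)
  if (diff(mu) < tol) {
    warn("Degenerate mixture fit; falling back to the median.")
    cut <- median(v)
    return(list(cutoff_log10 = cut, cutoff = 10^cut, fallback = TRUE,
                means = mu, sd = sqrt(s2), weights = pro))
  }
  # equal-posterior point for equal variances
  cut <- (mu[1] + mu[2]) / 2 + s2 * log(pro[1] / pro[2]) / (mu[2] - mu[1])
  if (cut < mu[1] || cut > mu[2]) cut <- (mu[1] + mu[2]) / 2
  list(cutoff_log10 = cut, cutoff = 10^cut, fallback = FALSE,
       means = mu, sd = sqrt(s2), weights = pro)
}

#' Flag high normal protein abundance
#'
#' A gene is flagged "high" when its average nPSM over covered exons in the
#' normal panel is at or above the cutoff (the >= convention puts a value
#' exactly at the cutoff in the high class); such candidates are downgraded
#' to Tier 2.  Genes absent from the normal panel are "low" (no evidence of
#' normal protein).
#'
#' @param genes Character vector of gene ids.
#' @param proteomics PSM tibble with `panel`, `gene_id`, `psm_count`,
#'   `aa_length`.
#' @param cutoff nPSM cutoff on the natural scale (see [bimodal_cutoff()]).
#' @return Tibble `gene_id`, `mean_npsm`, `protein_abundance` (high/low).
#' @export
protein_abundance_flag <- function(genes, proteomics, cutoff) {
  means <- proteomics |>
    dplyr::filter(.data$panel == "normal", .data$gene_id %in% genes) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_npsm = mean(.data$psm_count / .data$aa_length),
                     .groups = "drop")
  tibble::tibble(gene_id = unique(genes)) |>
    dplyr::left_join(means, by = "gene_id") |>
    dplyr::mutate(mean_npsm = dplyr::coalesce(.data$mean_npsm, 0),
                  protein_abundance = dplyr::if_else(.data$mean_npsm >= cutoff,
                                                     "high", "low"))
}

#' Assign Tier 1 / Tier 2
#'
#' A target is Tier 1 iff every applicable check passed: absence of high
#' expression in paired normal tissues, low bone-marrow expression
#' (gene-level targets), and low normal protein abundance.  Any failure --
#' including missing evidence, which fails safe -- demotes to Tier 2 with the
#' failed checks named.
#'
#' @param targets Tibble with one row per target gene: `gene_id`,
#'   `target_class`, `representative_exon`, `supporting_groups` (list-col).
#' @param group_median_ranks Exon x group median-rank matrix (or named list
#'   per compartment keyed by the target's `compartment` column).
#' @param bm_expr,classifier Bone-marrow panel and fitted classifier.
#' @param proteomics PSM tibble.
#' @param npsm_cutoff nPSM cutoff (natural scale).
#' @param pair_map Tumor-to-tissue pairing.
#' @param rank_high High-expression rank threshold (default 0.75).
#' @return Tibble `gene_id`, `tier`, `failed_checks` (comma-joined, "" when
#'   none), plus per-check evidence columns.
#' @export
assign_tiers <- function(targets, group_median_ranks, bm_expr, classifier,
                         proteomics, npsm_cutoff,
                         pair_map = default_pair_map(), rank_high = 0.75) {
  get_comp <- function(comp) {
    if (is.list(group_median_ranks)) group_median_ranks[[comp]]
    else group_median_ranks
  }
  paired <- purrr::pmap(
    list(targets$supporting_groups, targets$representative_exon,
         targets$compartment),
    function(supp, exon, comp) {
      gm <- get_comp(comp)
      res <- paired_normal_check(supp, gm[exon, ], pair_map = pair_map,
                                 rank_high = rank_high)
      tibble::tibble(paired_normal = res$status,
                     paired_normal_detail = res$detail)
    }) |> dplyr::bind_rows()

  bm <- bm_low_expression(targets$gene_id, targets$target_class, bm_expr,
                          classifier)
  prot <- protein_abundance_flag(targets$gene_id, proteomics, npsm_cutoff)

  out <- targets |>
    dplyr::bind_cols(paired) |>
    dplyr::left_join(bm, by = "gene_id") |>
    dplyr::left_join(prot, by = "gene_id") |>
    dplyr::mutate(
      gtex_proteomics = dplyr::if_else(.data$protein_abundance == "high",
                                       "fail", "pass"))
  checks <- c("paired_normal", "bone_marrow", "gtex_proteomics")
  failed <- purrr::pmap_chr(out[checks], function(...) {
    status <- c(...)
    paste(checks[status == "fail"], collapse = ",")
  })
  out |>
    dplyr::mutate(failed_checks = failed,
                  tier = dplyr::if_else(failed == "", 1L, 2L))
}
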