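#' Mann-Whitney U statistic with half-credit ties
#'
#' `U = sum_i sum_j S(x_i, y_j)` where the pair score S is 1 when the normal
#' value is below the tumor value, 1/2 at a tie, and 0 otherwise.  Computed
#' via mid-ranks (`U = R_x - n1 (n1 + 1) / 2`), which is algebraically equal
#' to the pairwise enumeration for any ties.
#'
#' @param x Tumor-group values (length n1 >= 1).
#' @param y Normal-group values (length n2 >= 1).
#' @return The U statistic, in `[0, n1 * n2]`.
#' @export
u_statistic <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("Both groups must be non-empty.")
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Normal approximation Z-score for the U statistic
#'
#' `z = (U - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12)`.  No tie
#' correction is applied to the variance; [sigma_u_corrected()] provides the
#' tie-corrected standard deviation for sensitivity analysis.
#'
#' @param u U statistic.
#' @param n1,n2 Group sizes (>= 1).
#' @param sigma_u Optional standard deviation override (e.g. tie-corrected).
#' @return Z-score (vectorized over `u`).
#' @export
z_from_u <- function(u, n1, n2, sigma_u = NULL) {
  if (any(n1 < 1) || any(n2 < 1)) abort("Group sizes must be >= 1.")
  m_u <- n1 * n2 / 2
  s_u <- sigma_u %||% sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  (u - m_u) / s_u
}

#' Tie-corrected standard deviation of U
#'
#' Standard rank-sum tie correction; offered behind a flag of
#' [run_differential()] for sensitivity analysis, not used by default.
#'
#' @param x,y Group values.
#' @return Corrected sigma of U.
#' @export
sigma_u_corrected <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  t <- table(c(x, y))
  corr <- sum(t^3 - t) / (n * (n - 1))
  sqrt(n1 * n2 / 12 * (n + 1 - corr))
}

#' Percentile-rank differential weight for one tumor/normal pair
#'
#' `w = median(rank(X)) - median(rank(Y))` over the shared percentile-rank
#' space.  Lies in (-1, 1); negative weights are kept as-is, preserving
#' antisymmetry of the composite under group exchange.
#'
#' @param pr_x,pr_y Percentile ranks of the tumor and normal samples,
#'   values in (0, 1).
#' @return The weight.
#' @export
pair_weight <- function(pr_x, pr_y) {
  if (!length(pr_x) || !length(pr_y)) abort("Both rank vectors must be non-empty.")
  if (any(pr_x <= 0 | pr_x >= 1) || any(pr_y <= 0 | pr_y >= 1)) {
    abort("Percentile ranks must lie strictly in (0, 1).")
  }
  median(pr_x) - median(pr_y)
}

#' Weighted Stouffer composite Z-score
#'
#' Combines k pairwise Z-scores as `sum(w_i z_i) / sqrt(sum(w_i^2))`, the
#' normalization under which the composite has unit variance under the null
#' for fixed weights.  With k = 1 this reduces to `sign(w) * z`; with equal
#' positive weights, to the unweighted Stouffer `sum(z) / sqrt(k)`.
#'
#' @param zs,ws Equal-length vectors of Z-scores and weights.
#' @return A list with `composite_z` and `degenerate` (TRUE when all weights
#'   are zero, in which case the composite is 0).
#' @export
composite_z <- function(zs, ws) {
  if (length(zs) != length(ws)) abort("`zs` and `ws` must have equal length.")
  if (!length(zs)) abort("At least one pair is required.")
  s2 <- sum(ws^2)
  if (s2 == 0) {
    return(list(composite_z = 0, degenerate = TRUE))
  }
  list(composite_z = sum(ws * zs) / sqrt(s2), degenerate = FALSE)
}

#' Tumor-versus-normal differential expression for one compartment
#'
#' For every exon and every (tumor group) x (normal tissue) pair in the
#' compartment, computes the U statistic, its normal-approximation Z, and the
#' percentile-rank differential weight, then combines the k pairs per exon
#' into a weighted Stouffer composite Z-score.  Percentile ranks are computed
#' once over all samples of the compartment analysis (the compartment's tumor
#' groups plus all normal tissues) unless `rank_scope = "pair"`, in which
#' case each pair is ranked within its own samples.
#'
#' Solid and brain tumors are analyzed as separate compartments.
#'
#' @param expr Exon x sample FPKM matrix.
#' @param samples Sample table with columns `sample_id`, `cohort`
#'   (tumor/normal), `group`, `compartment`.
#' @param compartment `"solid"` or `"brain"`.
#' @param rank_scope `"compartment"` (default) or `"pair"`.
#' @param tie_correction Use the tie-corrected sigma of U (default FALSE,
#'   matching the plain normal approximation).
#' @param low_power_n Pairs with either group smaller than this are flagged
#'   `low_power` in the pairwise table (computed regardless).
#' @return Object of class `cse_diffexp`: list with tibbles `pairwise`
#'   (exon_id, tumor_group, normal_group, n1, n2, u, z, w, low_power) and
#'   `composite` (exon_id, gene_id, compartment, k, composite_z, degenerate),
#'   plus the compartment `ranks` matrix and `group_median_ranks`
#'   (exon x group matrix of median percentile ranks).
#' @export
run_differential <- function(expr, samples, compartment,
                             rank_scope = c("compartment", "pair"),
                             tie_correction = FALSE,
                             low_power_n = 3L) {
  rank_scope <- match.arg(rank_scope)
  tgroups <- samples |>
    dplyr::filter(.data$cohort == "tumor", .data$compartment == !!compartment)
  if (!nrow(tgroups)) {
    abort(sprintf("No tumor groups in compartment '%s'.", compartment))
  }
  ngroups <- samples |> dplyr::filter(.data$cohort == "normal")
  if (!nrow(ngroups)) abort("No normal tissue samples present.")
  used <- dplyr::bind_rows(tgroups, ngroups)
  ranks <- percentile_ranks(expr, used$sample_id)

  group_ids <- split(used$sample_id, used$group)
  gm <- vapply(group_ids, function(ids) {
    row_medians(ranks[, ids, drop = FALSE])
  }, numeric(nrow(ranks)))
  rownames(gm) <- rownames(ranks)

  tg <- sort(unique(tgroups$group))
  ng <- sort(unique(ngroups$group))
  ne <- nrow(expr)
  k <- length(tg) * length(ng)
  z_mat <- w_mat <- u_mat <- matrix(NA_real_, ne, k)
  pair_meta <- vector("list", k)
  p <- 0L
  for (g in tg) {
    xi <- group_ids[[g]]
    n1 <- length(xi)
    for (t in ng) {
      yi <- group_ids[[t]]
      n2 <- length(yi)
      p <- p + 1L
      sub <- expr[, c(xi, yi), drop = FALSE]
      r <- t(apply(sub, 1L, rank, ties.method = "average"))
      u <- rowSums(r[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
      if (tie_correction) {
        s_u <- vapply(seq_len(ne), function(i) {
          sigma_u_corrected(sub[i, seq_len(n1)], sub[i, -seq_len(n1)])
        }, numeric(1))
        z <- ifelse(s_u > 0, (u - n1 * n2 / 2) / s_u, 0)
      } else {
        z <- z_from_u(u, n1, n2)
      }
      if (rank_scope == "compartment") {
        w <- gm[, g] - gm[, t]
      } else {
        pr <- (r - 0.5) / (n1 + n2)
        w <- row_medians(pr[, seq_len(n1), drop = FALSE]) -
          row_medians(pr[, -seq_len(n1), drop = FALSE])
      }
      u_mat[, p] <- u
      z_mat[, p] <- z
      w_mat[, p] <- w
      pair_meta[[p]] <- tibble::tibble(
        tumor_group = g, normal_group = t, n1 = n1, n2 = n2,
        low_power = n1 < low_power_n | n2 < low_power_n)
    }
  }
  meta <- dplyr::bind_rows(pair_meta)
  pairwise <- tibble::tibble(
    exon_id = rep(rownames(expr), times = k),
    tumor_group = rep(meta$tumor_group, each = ne),
    normal_group = rep(meta$normal_group, each = ne),
    n1 = rep(meta$n1, each = ne), n2 = rep(meta$n2, each = ne),
    u = as.vector(u_mat),
    z = as.vector(z_mat), w = as.vector(w_mat),
    low_power = rep(meta$low_power, each = ne))

  s2 <- rowSums(w_mat^2)
  comp <- ifelse(s2 > 0, rowSums(w_mat * z_mat) / sqrt(pmax(s2, 1e-300)), 0)
  composite <- tibble::tibble(
    exon_id = rownames(expr),
    gene_id = exon_gene(rownames(expr)),
    compartment = compartment, k = k,
    composite_z = comp, degenerate = s2 == 0)

  structure(list(pairwise = pairwise, composite = composite, ranks = ranks,
                 group_median_ranks = gm, compartment = compartment,
                 tumor_groups = tg, normal_groups = ng,
                 samples = used),
            class = "cse_diffexp")
}

#' @export
print.cse_diffexp <- function(x, ...) {
  cat(sprintf("<cse_diffexp> compartment=%s, %d exons, k=%d pairs (%d tumor x %d normal)\n",
              x$compartment, nrow(x$composite), x$composite$k[1],
              length(x$tumor_groups), length(x$normal_groups)))
  invisible(x)
}

#' @rdname run_differential
#' @param x A `cse_diffexp` object.
#' @param ... Unused.
#' @method tidy cse_diffexp
#' @export
tidy.cse_diffexp <- function(x, ...) x$composite

#' @rdname run_differential
#' @method glance cse_diffexp
#' @export
glance.cse_diffexp <- function(x, ...) {
  tibble::tibble(compartment = x$compartment,
                 n_exons = nrow(x$composite),
                 k = x$composite$k[1],
                 n_degenerate = sum(x$composite$degenerate),
                 n_low_power = sum(x$pairwise$low_power))
}
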