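#' Quartile binned scores for one exon
#'
#' Values below `floor` (1 FPKM) are binned 0.  Quartile breaks are computed
#' from the exon's values at or above the floor across all samples
#' (linear-interpolation quantiles); remaining values are binned 0 when at or
#' below Q1, 1 in (Q1, Q2], 2 in (Q2, Q3] (right-closed intervals), and 3
#' strictly above Q3.  When no value reaches the floor all bins are 0.
#'
#' @param values Named numeric vector (one exon across samples).
#' @param breaks Optional precomputed breaks `c(q1, q2, q3)`.
#' @param floor Expression floor in FPKM (default 1).
#' @return Integer vector of bins in `{0, 1, 2, 3}` with the same names.
#' @export
binned_scores <- function(values, breaks = NULL, floor = 1) {
  if (is.null(breaks)) {
    pos <- values[values >= floor]
    if (!length(pos)) {
      return(stats::setNames(integer(length(values)), names(values)))
    }
    breaks <- unname(quantile(pos, c(0.25, 0.5, 0.75), type = 7))
  }
  if (is.unsorted(breaks)) abort("`breaks` must be non-decreasing.")
  bins <- (values > breaks[1]) + (values > breaks[2]) + (values > breaks[3])
  bins[values < floor] <- 0L
  stats::setNames(as.integer(bins), names(values))
}

#' Per-type mean binned scores and tumor/normal averages
#'
#' Averages the per-sample bins within each tumor type and normal tissue
#' type, then takes the unweighted mean of the type means as the tumor score
#' and the normal score (so duplicating a type's samples leaves the scores
#' unchanged).  Types with zero samples are excluded with a warning.
#'
#' @param bins Named integer vector of per-sample bins (one exon).
#' @param samples Sample table.
#' @return List with `type_means` (tibble `group`, `cohort`, `mean_bin`,
#'   `n`), `tumor_score`, `normal_score`.
#' @export
type_scores <- function(bins, samples) {
  s <- samples[samples$sample_id %in% names(bins), ]
  empty <- setdiff(unique(samples$group), s$group)
  if (length(empty)) {
    warn(paste0("Type(s) with zero samples excluded: ",
                paste(empty, collapse = ", ")))
  }
  tm <- s |>
    dplyr::group_by(.data$group, .data$cohort) |>
    dplyr::summarise(mean_bin = mean(bins[.data$sample_id]),
                     n = dplyr::n(), .groups = "drop")
  list(type_means = tm,
       tumor_score = mean(tm$mean_bin[tm$cohort == "tumor"]),
       normal_score = mean(tm$mean_bin[tm$cohort == "normal"]))
}

#' Fourth-quartile prevalence per type
#'
#' Fraction of each type's samples whose bin is 3 (the top expression
#' quartile); the conventional "high prevalence" call is >= 25%.
#'
#' @inheritParams type_scores
#' @return Tibble `group`, `cohort`, `prevalence`.
#' @export
prevalence <- function(bins, samples) {
  s <- samples[samples$sample_id %in% names(bins), ]
  s |>
    dplyr::group_by(.data$group, .data$cohort) |>
    dplyr::summarise(prevalence = mean(bins[.data$sample_id] == 3L),
                     .groups = "drop")
}

#' Score a set of exons for the pan-target scatter
#'
#' Computes per-sample quartile bins, per-type means, tumor/normal average
#' scores, and per-type prevalence for each exon.
#'
#' @param expr Exon x sample FPKM matrix.
#' @param samples Sample table.
#' @param exon_ids Exons to score (default all rows).
#' @param floor Expression floor in FPKM (default 1).
#' @return Object of class `cse_scores`: list with `summary` (tibble
#'   `exon_id`, `tumor_score`, `normal_score`), `type_means` and
#'   `prevalence` (long tibbles), and the `bins` matrix.
#' @export
score_exons <- function(expr, samples, exon_ids = rownames(expr), floor = 1) {
  expr <- expr[exon_ids, , drop = FALSE]
  bins <- t(apply(expr, 1L, binned_scores, floor = floor))
  colnames(bins) <- colnames(expr)
  grp <- samples[match(colnames(bins), samples$sample_id), ]
  type_ids <- split(seq_len(ncol(bins)), grp$group)
  cohort_of <- vapply(type_ids, function(i) grp$cohort[i[1]], character(1))
  tm <- vapply(type_ids, function(i) rowMeans(bins[, i, drop = FALSE]),
               numeric(nrow(bins)))
  pv <- vapply(type_ids, function(i) rowMeans(bins[, i, drop = FALSE] == 3L),
               numeric(nrow(bins)))
  if (nrow(expr) == 1L) {
    tm <- matrix(tm, nrow = 1, dimnames = list(rownames(expr), names(type_ids)))
    pv <- matrix(pv, nrow = 1, dimnames = list(rownames(expr), names(type_ids)))
  }
  summary <- tibble::tibble(
    exon_id = rownames(expr),
    tumor_score = rowMeans(tm[, cohort_of == "tumor", drop = FALSE]),
    normal_score = rowMeans(tm[, cohort_of == "normal", drop = FALSE]))
  long <- function(m, col) {
    tibble::as_tibble(m, rownames = "exon_id") |>
      tidyr::pivot_longer(-"exon_id", names_to = "group", values_to = col) |>
      dplyr::mutate(cohort = unname(cohort_of[.data$group]))
  }
  structure(list(summary = summary,
                 type_means = long(tm, "mean_bin"),
                 prevalence = long(pv, "prevalence"),
                 bins = bins),
            class = "cse_scores")
}

#' @export
print.cse_scores <- function(x, ...) {
  cat(sprintf("<cse_scores> %d exons x %d samples\n",
              nrow(x$bins), ncol(x$bins)))
  invisible(x)
}

#' @rdname score_exons
#' @param x A `cse_scores` object.
#' @param ... Unused.
#' @method tidy cse_scores
#' @export
tidy.cse_scores <- function(x, ...) x$summary
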