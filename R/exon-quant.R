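#' Count reads per exon with union/nonunique-all semantics
#'
#' Counts alignment records against exon intervals the way
#' `htseq-count -a 0 -s no -m union --nonunique all` does: every alignment
#' record (primary or secondary, any MAPQ) that overlaps an exon by at least
#' `min_overlap` bp increments that exon; a record overlapping k exons
#' increments all k, so a junction-spanning read is counted for both exons it
#' touches and every alignment of a multi-mapped read contributes.  Strand is
#' ignored.  Spliced alignments are resolved into their aligned blocks, so an
#' `N` gap does not create overlap.
#'
#' @param sam_files Named character vector of SAM file paths (names are
#'   sample ids; unnamed files are named after the file).
#' @param models A `cse_models` object providing the exon intervals.
#' @param min_overlap Minimum overlap in bp for a record to count (default 1).
#' @param library_mode How per-sample library sizes are defined: `"exonic"`
#'   (records overlapping at least one exon, the quantity this counter sees;
#'   default) or `"mapped"` (all mapped records).
#' @return An object of class `cse_counts`: list with `values` (exon x sample
#'   integer matrix), `library_sizes`, `exon_lengths`, and a `log` tibble of
#'   per-sample counted/skipped record totals.
#' @export
count_exon_reads <- function(sam_files, models, min_overlap = 1L,
                             library_mode = c("exonic", "mapped")) {
  library_mode <- match.arg(library_mode)
  nm <- names(sam_files)
  if (is.null(nm)) nm <- rep("", length(sam_files))
  nm[nm == ""] <- basename(sam_files[nm == ""])
  names(sam_files) <- nm
  exons <- exon_granges(models)
  values <- matrix(0L, nrow = length(exons), ncol = length(sam_files),
                   dimnames = list(models$exons$exon_id, names(sam_files)))
  lib <- stats::setNames(numeric(length(sam_files)), names(sam_files))
  logs <- vector("list", length(sam_files))
  for (s in seq_along(sam_files)) {
    gal <- read_sam_alignments(sam_files[[s]])
    blocks <- GenomicAlignments::grglist(gal)
    hits <- GenomicRanges::findOverlaps(blocks, exons,
                                        minoverlap = min_overlap,
                                        ignore.strand = TRUE)
    pairs <- unique(cbind(S4Vectors::queryHits(hits),
                          S4Vectors::subjectHits(hits)))
    tab <- tabulate(pairs[, 2L], nbins = length(exons))
    values[, s] <- tab
    n_exonic <- length(unique(pairs[, 1L]))
    lib[s] <- if (library_mode == "exonic") n_exonic else length(gal)
    logs[[s]] <- tibble::tibble(sample_id = names(sam_files)[s],
                                n_records = length(gal),
                                n_exonic = n_exonic)
  }
  structure(list(values = values, library_sizes = lib,
                 exon_lengths = stats::setNames(
                   models$exons$end - models$exons$start + 1L,
                   models$exons$exon_id),
                 log = dplyr::bind_rows(logs)),
            class = "cse_counts")
}

read_sam_alignments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  # no flag or MAPQ filter: secondary alignments and MAPQ 0 are retained
  GenomicAlignments::readGAlignments(bam)
}

#' FPKM normalization with read-length substitution for short exons
#'
#' Converts counts to fragments per kilobase per million:
#' `FPKM = count * 1e9 / (L_eff * library_size)` with
#' `L_eff = max(exon_length, read_length)`.  Substituting the read length for
#' exons shorter than a read compensates for the double counting of
#' junction-spanning reads, which otherwise inflates short exons.
#'
#' @param counts A `cse_counts` object, or an exon x sample count matrix.
#' @param exon_lengths Named vector of exon lengths (taken from `counts` when
#'   it is a `cse_counts`).
#' @param read_length Sequencing read length in bp (> 0).
#' @param library_sizes Per-sample library sizes (taken from `counts` when it
#'   is a `cse_counts`).
#' @return Exon x sample FPKM matrix.
#' @export
fpkm_normalize <- function(counts, exon_lengths = NULL, read_length = 100L,
                           library_sizes = NULL) {
  if (inherits(counts, "cse_counts")) {
    exon_lengths <- exon_lengths %||% counts$exon_lengths
    library_sizes <- library_sizes %||% counts$library_sizes
    counts <- counts$values
  }
  if (read_length <= 0) abort("`read_length` must be > 0.")
  if (is.null(exon_lengths) || is.null(library_sizes)) {
    abort("`exon_lengths` and `library_sizes` are required.")
  }
  if (!is.null(names(exon_lengths))) {
    miss <- setdiff(rownames(counts), names(exon_lengths))
    if (length(miss)) {
      abort(paste0("Missing exon lengths for: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    exon_lengths <- exon_lengths[rownames(counts)]
  }
  if (any(exon_lengths <= 0)) abort("Exon lengths must be > 0.")
  bad <- library_sizes == 0 & colSums(counts) > 0
  if (any(bad)) {
    abort(paste0("Zero library size with nonzero counts for sample(s): ",
                 paste(colnames(counts)[bad], collapse = ", ")))
  }
  l_eff <- pmax(exon_lengths, read_length)
  denom <- outer(l_eff, library_sizes)
  out <- counts * 1e9 / denom
  out[, library_sizes == 0] <- 0
  out
}

#' Per-exon percentile ranks across samples
#'
#' For each exon (row), ranks the samples with mid-rank tie handling and maps
#' rank r to `(r - 0.5) / N`, so values lie strictly in (0, 1) and each row
#' averages exactly 0.5.  This single rank space, computed over all samples of
#' a compartment analysis, underlies the rank-differential weights, the
#' above-median criteria, and the exported heatmaps.
#'
#' @param expr Exon x sample expression matrix.
#' @param sample_subset Optional character vector of sample ids (columns) to
#'   rank within; must contain at least 2 samples.
#' @return Matrix of percentile ranks with the same dimnames as the selected
#'   columns of `expr`.
#' @export
percentile_ranks <- function(expr, sample_subset = NULL) {
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, colnames(expr))
    if (length(miss)) {
      abort(paste0("Samples not in expression matrix: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    expr <- expr[, sample_subset, drop = FALSE]
  }
  n <- ncol(expr)
  if (n < 2) abort("Percentile ranks need at least 2 samples.")
  r <- t(apply(expr, 1L, rank, ties.method = "average"))
  (r - 0.5) / n
}
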