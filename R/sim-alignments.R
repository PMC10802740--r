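#' Simulate SAM alignment fixtures with known per-exon counts
#'
#' Emits single-end alignment records of four kinds, in configurable numbers,
#' with the implied per-exon counts recorded as ground truth:
#'
#' * reads fully inside one exon (count that exon);
#' * junction-spanning reads across two adjacent exons of a transcript
#'   (`aMbNcM` CIGAR; count both exons);
#' * multi-mapped read groups: one primary plus one secondary record at a
#'   different exon, MAPQ 0 (count both exons);
#' * intergenic reads (count nothing).
#'
#' @param models A `cse_models` object.
#' @param n_internal,n_junction,n_multimap,n_intergenic Read numbers.
#' @param read_length Read length in bp.
#' @param sample_id Sample name used in read names.
#' @param seed Integer seed.
#' @return A list of class `cse_sim_alignments` with `lines` (SAM text,
#'   header included), `truth` (tibble `exon_id`, `count` covering all model
#'   exons), `n_exonic_records`, and `n_mapped_records`.
#' @export
sim_alignments <- function(models, n_internal = 100L, n_junction = 20L,
                           n_multimap = 10L, n_intergenic = 10L,
                           read_length = 50L, sample_id = "S1", seed = 1L) {
  with_seed(sub_seed(seed, 5L), {
    exons <- models$exons
    counts <- stats::setNames(integer(nrow(exons)), exons$exon_id)
    recs <- list()
    qn <- 0L
    add <- function(qname, flag, chrom, pos, mapq, cigar, extra = character(0)) {
      seqlen <- sum(as.integer(
        regmatches(cigar, gregexpr("[0-9]+(?=M)", cigar, perl = TRUE))[[1]]))
      c(qname, flag, chrom, pos, mapq, cigar, "*", "0", "0",
        strrep("A", seqlen), "*", extra)
    }

    wide <- which(exons$end - exons$start + 1L >= read_length)
    if (!length(wide) && n_internal + n_multimap > 0) {
      abort("No exon is at least `read_length` long.",
            class = "csefinder_config_error")
    }
    for (i in seq_len(n_internal)) {
      e <- wide[sample.int(length(wide), 1L)]
      pos <- exons$start[e] +
        sample.int(exons$end[e] - exons$start[e] - read_length + 2L, 1L) - 1L
      qn <- qn + 1L
      recs[[length(recs) + 1L]] <- add(sprintf("%s_int_%05d", sample_id, qn),
                                       "0", exons$chrom[e], pos, "60",
                                       paste0(read_length, "M"))
      counts[e] <- counts[e] + 1L
    }

    # adjacent exon pairs in genomic order within a transcript
    adj <- models$transcripts |>
      dplyr::left_join(exons, by = c("gene_id", "exon_id")) |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::summarise(left = list(.data$exon_id[-dplyr::n()]),
                       right = list(.data$exon_id[-1]), .groups = "drop") |>
      tidyr::unnest(c("left", "right"))
    for (i in seq_len(n_junction)) {
      p <- adj[sample.int(nrow(adj), 1L), ]
      e1 <- match(p$left, exons$exon_id)
      e2 <- match(p$right, exons$exon_id)
      a <- sample(10:(read_length - 10L), 1L)
      b <- read_length - a
      pos <- exons$end[e1] - a + 1L
      gap <- exons$start[e2] - exons$end[e1] - 1L
      qn <- qn + 1L
      recs[[length(recs) + 1L]] <- add(
        sprintf("%s_jx_%05d", sample_id, qn), "0", exons$chrom[e1], pos, "60",
        sprintf("%dM%dN%dM", a, gap, b))
      counts[e1] <- counts[e1] + 1L
      counts[e2] <- counts[e2] + 1L
    }

    for (i in seq_len(n_multimap)) {
      es <- wide[sample.int(length(wide), min(2L, length(wide)))]
      if (length(es) == 1L) es <- c(es, es)
      qn <- qn + 1L
      qname <- sprintf("%s_mm_%05d", sample_id, qn)
      for (j in 1:2) {
        e <- es[j]
        pos <- exons$start[e] +
          sample.int(exons$end[e] - exons$start[e] - read_length + 2L, 1L) - 1L
        recs[[length(recs) + 1L]] <- add(
          qname, if (j == 1L) "0" else "256", exons$chrom[e], pos, "0",
          paste0(read_length, "M"), "NH:i:2")
        counts[e] <- counts[e] + 1L
      }
    }

    chroms <- models$chrom_lengths
    for (i in seq_len(n_intergenic)) {
      ch <- chroms[sample.int(nrow(chroms), 1L), ]
      pos <- ch$length - 20000L + sample.int(10000L, 1L)  # beyond last gene
      qn <- qn + 1L
      recs[[length(recs) + 1L]] <- add(sprintf("%s_ig_%05d", sample_id, qn),
                                       "0", ch$chrom, pos, "60",
                                       paste0(read_length, "M"))
    }

    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", chroms$chrom, chroms$length))
    body <- vapply(recs, paste, character(1), collapse = "\t")
    if (length(body)) {
      ord <- order(vapply(recs, `[`, character(1), 3L),
                   as.integer(vapply(recs, `[`, character(1), 4L)))
      body <- body[ord]
    }
    structure(list(
      lines = c(header, body),
      truth = tibble::tibble(exon_id = names(counts), count = unname(counts)),
      n_exonic_records = n_internal + n_junction + 2L * n_multimap,
      n_mapped_records = n_internal + n_junction + 2L * n_multimap +
        n_intergenic,
      sample_id = sample_id),
      class = "cse_sim_alignments")
  })
}

#' Write simulated alignments to a SAM file
#' @param aln A `cse_sim_alignments` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  writeLines(aln$lines, path)
  invisible(path)
}

#' Simulate splice-site-proximal variants for planted AS exons
#'
#' Places one variant per carrier tumor sample within `window` bp of a
#' randomly chosen boundary (acceptor or donor side) of each planted AS exon.
#'
#' @param models A `cse_models` object.
#' @param truth Ground-truth manifest from [sim_cohort()].
#' @param samples Sample table from [sim_cohort()].
#' @param carrier_fraction Fraction of tumor samples carrying a variant.
#' @param window Window around each exon boundary, in bp.
#' @param seed Integer seed.
#' @return Tibble with columns `sample_id`, `chrom`, `pos`, `gene_id`.
#' @export
sim_variants <- function(models, truth, samples, carrier_fraction = 0.15,
                         window = 10L, seed = 1L) {
  empty <- tibble::tibble(sample_id = character(0), chrom = character(0),
                          pos = integer(0), gene_id = character(0))
  if (!nrow(truth$planted_as) || carrier_fraction <= 0) {
    return(empty)
  }
  with_seed(sub_seed(seed, 6L), {
    tumor <- samples$sample_id[samples$cohort == "tumor"]
    out <- purrr::pmap(truth$planted_as, function(gene_id, exon_id) {
      ex <- models$exons[models$exons$exon_id == exon_id, ]
      carriers <- tumor[runif(length(tumor)) < carrier_fraction]
      if (!length(carriers)) return(NULL)
      boundary <- ifelse(runif(length(carriers)) < 0.5, ex$start, ex$end)
      pos <- boundary + sample(-window:window, length(carriers), replace = TRUE)
      tibble::tibble(sample_id = carriers, chrom = ex$chrom, pos = pos,
                     gene_id = gene_id)
    })
    dplyr::bind_rows(empty, dplyr::bind_rows(out))
  })
}

#' Couple variant carriers to exon expression
#'
#' Positive-control helper: multiplies carriers' expression of their AS exon
#' by `exp(delta)`, so the splice-variant association test has signal to find.
#'
#' @param expr Exon x sample expression matrix.
#' @param variants Variant tibble from [sim_variants()].
#' @param truth Ground-truth manifest (maps gene to AS exon).
#' @param delta Log-scale shift added to carriers.
#' @return Modified copy of `expr`.
#' @export
apply_variant_effect <- function(expr, variants, truth, delta) {
  for (g in unique(variants$gene_id)) {
    ex <- truth$planted_as$exon_id[truth$planted_as$gene_id == g]
    carriers <- variants$sample_id[variants$gene_id == g]
    carriers <- intersect(carriers, colnames(expr))
    expr[ex, carriers] <- expr[ex, carriers] * exp(delta)
  }
  expr
}
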