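#' Simulate gene models with optional cassette exons
#'
#' Generates a deterministic set of gene models: genes laid out along
#' synthetic chromosomes, each with an ordered set of non-overlapping exons
#' and one or two transcripts.  A configurable fraction of genes receives a
#' second transcript that skips one internal exon (a cassette exon), the
#' substrate for planting alternatively spliced targets.
#'
#' `index_in_gene` is 1-based and strand-aware: index 1 is the 5'-most exon
#' in transcription direction.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical (config, seed) gives identical models.
#' @return An object of class `cse_models`: a list with tibbles `genes`,
#'   `exons`, `transcripts`, `cassettes`, and `chrom_lengths`.
#' @export
sim_gene_models <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "cse_sim_config"))
  with_seed(sub_seed(seed, 1L), {
    n <- config$n_genes
    genes_per_chrom <- 50L
    rint <- function(range, m) {
      range[1] + sample.int(range[2] - range[1] + 1L, m, replace = TRUE) - 1L
    }
    n_exons <- rint(config$exons_per_gene, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    n_multi <- max(round(config$frac_multi_transcript * n),
                   config$n_planted_as)
    n_multi <- min(n_multi, n)
    multi <- sort(sample.int(n, n_multi))

    exon_rows <- vector("list", n)
    tx_rows <- vector("list", n)
    cassette_rows <- vector("list", n)
    cursor <- integer(0)  # per-chromosome cursor
    for (i in seq_len(n)) {
      gene_id <- sprintf("G%04d", i)
      chrom <- sprintf("chrS%d", (i - 1L) %/% genes_per_chrom + 1L)
      if (!chrom %in% names(cursor)) cursor[chrom] <- 10000L
      k <- n_exons[i]
      lens <- rint(config$exon_length, k)
      gaps <- rint(config$intron_length, k)
      starts <- cursor[chrom] + cumsum(gaps) + c(0L, cumsum(lens[-k]))
      ends <- starts + lens - 1L
      cursor[chrom] <- ends[k] + 10000L

      # genomic order left->right; transcription index depends on strand
      idx <- if (strand[i] == "+") seq_len(k) else rev(seq_len(k))
      exon_id <- sprintf("%s:E%03d", gene_id, idx)
      exon_rows[[i]] <- tibble::tibble(
        exon_id = exon_id, gene_id = gene_id, chrom = chrom,
        start = starts, end = ends, strand = strand[i], index_in_gene = idx)

      ord <- order(idx)  # transcription order
      tx1 <- tibble::tibble(
        transcript_id = paste0(gene_id, ".T1"), gene_id = gene_id,
        exon_id = exon_id[ord], exon_order = seq_len(k))
      if (i %in% multi && k >= 3) {
        internal <- idx[idx > 1 & idx < k]
        skip <- internal[sample.int(length(internal), 1L)]
        keep <- ord[idx[ord] != skip]
        tx2 <- tibble::tibble(
          transcript_id = paste0(gene_id, ".T2"), gene_id = gene_id,
          exon_id = exon_id[keep], exon_order = seq_along(keep))
        tx_rows[[i]] <- dplyr::bind_rows(tx1, tx2)
        cassette_rows[[i]] <- tibble::tibble(
          gene_id = gene_id, exon_id = exon_id[idx == skip])
      } else {
        tx_rows[[i]] <- tx1
      }
    }
    exons <- dplyr::bind_rows(exon_rows)
    transcripts <- dplyr::bind_rows(tx_rows)
    cassettes <- dplyr::bind_rows(cassette_rows)
    genes <- exons |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(n_exons = dplyr::n(), start = min(.data$start),
                       end = max(.data$end), .groups = "drop")
    chrom_lengths <- exons |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(length = max(.data$end) + 50000L, .groups = "drop")
    structure(list(genes = genes, exons = exons, transcripts = transcripts,
                   cassettes = cassettes, chrom_lengths = chrom_lengths),
              class = "cse_models")
  })
}

#' @export
print.cse_models <- function(x, ...) {
  cat(sprintf("<cse_models> %d genes, %d exons, %d transcripts (%d cassette genes)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$transcripts$transcript_id)), nrow(x$cassettes)))
  invisible(x)
}

exon_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = models$exons$chrom,
    ranges = IRanges::IRanges(models$exons$start, models$exons$end),
    strand = models$exons$strand,
    exon_id = models$exons$exon_id,
    gene_id = models$exons$gene_id)
}

#' Write gene models to GTF
#'
#' Coordinates are 1-based inclusive per the GTF convention.  Output is
#' deterministic (rows ordered by transcript then exon order), so identical
#' models yield byte-identical files.
#'
#' @param models A `cse_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- models$transcripts |>
    dplyr::left_join(models$exons, by = c("gene_id", "exon_id")) |>
    dplyr::arrange(.data$transcript_id, .data$exon_order)
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; exon_id "%s"; exon_number "%d";',
    rows$gene_id, rows$transcript_id, rows$exon_id, rows$exon_order)
  lines <- paste(rows$chrom, "csefinder", "exon", rows$start, rows$end, ".",
                 rows$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Reconstructs a `cse_models` object from exon features.  Exon transcription
#' indices are recomputed strand-aware from the coordinates, so any GTF with
#' `gene_id`/`transcript_id` exon attributes can be used.
#'
#' @param path GTF file path.
#' @return A `cse_models` object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- tibble::tibble(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  exons <- df |>
    dplyr::distinct(.data$gene_id, .data$chrom, .data$start, .data$end,
                    .data$strand) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(index_in_gene = if (.data$strand[1] == "+") {
      dplyr::row_number()
    } else {
      dplyr::n() - dplyr::row_number() + 1L
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(exon_id = sprintf("%s:E%03d", .data$gene_id,
                                    .data$index_in_gene)) |>
    dplyr::select("exon_id", "gene_id", "chrom", "start", "end", "strand",
                  "index_in_gene")
  transcripts <- df |>
    dplyr::left_join(exons,
                     by = c("gene_id", "chrom", "start", "end", "strand")) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$index_in_gene, .by_group = TRUE) |>
    dplyr::mutate(exon_order = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("transcript_id", "gene_id", "exon_id", "exon_order")
  genes <- exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(n_exons = dplyr::n(), start = min(.data$start),
                     end = max(.data$end), .groups = "drop")
  n_tx <- transcripts |>
    dplyr::distinct(.data$gene_id, .data$transcript_id) |>
    dplyr::count(.data$gene_id)
  present <- transcripts |>
    dplyr::distinct(.data$gene_id, .data$transcript_id, .data$exon_id) |>
    dplyr::count(.data$gene_id, .data$exon_id, name = "n_present") |>
    dplyr::left_join(n_tx, by = "gene_id")
  cassettes <- present |>
    dplyr::filter(.data$n > 1, .data$n_present < .data$n) |>
    dplyr::select("gene_id", "exon_id")
  chrom_lengths <- exons |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(length = max(.data$end) + 50000L, .groups = "drop")
  structure(list(genes = genes, exons = exons, transcripts = transcripts,
                 cassettes = cassettes, chrom_lengths = chrom_lengths),
            class = "cse_models")
}
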