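#' Write a matrix as TSV with an id first column
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id Name of the first column (default "exon_id").
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id = "exon_id") {
  df <- tibble::as_tibble(m, rownames = id)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path File path.
#' @param id Name of the id column.
#' @return Numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path, id = "exon_id") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[setdiff(names(df), id)])
  rownames(m) <- df[[id]]
  m
}

# GMT: set name, description, then member genes, tab-separated.
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1L))
}

annotations_from_gmt <- function(sets) {
  bl <- sets[startsWith(names(sets), "blacklist_")]
  names(bl) <- sub("^blacklist_", "", names(bl))
  structure(list(
    surfaceome = sets[["surfaceome"]] %||% character(0),
    matrisome = sets[["matrisome"]] %||% character(0),
    oncofetal = sets[["oncofetal"]] %||% character(0),
    transmembrane = sets[["transmembrane"]] %||% character(0),
    blacklist = bl), class = "cse_annotations")
}

annotations_to_gmt_sets <- function(ann) {
  bl <- ann$blacklist
  names(bl) <- paste0("blacklist_", names(bl))
  c(list(surfaceome = ann$surfaceome, matrisome = ann$matrisome,
         oncofetal = ann$oncofetal, transmembrane = ann$transmembrane), bl)
}

#' Simulate a full input bundle and optionally write it to disk
#'
#' Runs every generator (gene models, cohort, annotations, proteomics,
#' variants) from a single seed and returns the in-memory bundle the pipeline
#' consumes.  With `dir` set, also writes the file-based bundle: `models.gtf`,
#' `expression.tsv`, `samples.tsv`, `genesets.gmt`, `proteomics.tsv`,
#' `bm_expression.tsv`, `calibration.tsv`, `variants.tsv` and `truth.json`.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; the same (config, seed) reproduces the bundle
#'   byte-identically.
#' @param dir Optional output directory (created if missing).
#' @return A list of class `cse_bundle` with `models`, `expr`, `samples`,
#'   `annotations`, `proteomics`, `bm`, `calibration`, `variants`, `truth`.
#' @export
simulate_bundle <- function(config = sim_config(), seed = 1L, dir = NULL) {
  models <- sim_gene_models(config, seed)
  cohort <- sim_cohort(models, config, seed)
  annotations <- sim_annotations(models, cohort$truth, config, seed)
  proteomics <- sim_proteomics(models, cohort$truth, config, seed)
  variants <- sim_variants(models, cohort$truth, cohort$samples,
                           carrier_fraction = config$variant_carrier_fraction,
                           window = config$variant_window, seed = seed)
  bundle <- structure(list(
    models = models, expr = cohort$expr, samples = cohort$samples,
    annotations = annotations, proteomics = proteomics,
    bm = cohort$bm, calibration = cohort$calibration,
    variants = variants, truth = cohort$truth), class = "cse_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' @rdname simulate_bundle
#' @param bundle A `cse_bundle` object.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(bundle$models, p("models.gtf"))
  write_matrix_tsv(bundle$expr, p("expression.tsv"))
  readr::write_tsv(bundle$samples, p("samples.tsv"), progress = FALSE)
  write_gmt(annotations_to_gmt_sets(bundle$annotations), p("genesets.gmt"))
  readr::write_tsv(bundle$proteomics, p("proteomics.tsv"), progress = FALSE)
  write_matrix_tsv(bundle$bm, p("bm_expression.tsv"), id = "gene_id")
  readr::write_tsv(bundle$calibration, p("calibration.tsv"), progress = FALSE)
  readr::write_tsv(bundle$variants, p("variants.tsv"), progress = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(
    list(planted_gene_level = truth$planted_gene_level,
         planted_as = truth$planted_as,
         null_genes = truth$null_genes,
         confounders = truth$confounders,
         effects = truth$effects),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an input bundle from disk
#' @param dir Directory written by [write_bundle()].
#' @return A `cse_bundle` object (with `truth = NULL` if no manifest).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  models <- read_gtf(p("models.gtf"))
  truth <- NULL
  if (file.exists(p("truth.json"))) {
    tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    truth <- list(planted_gene_level = tj$planted_gene_level,
                  planted_as = tibble::as_tibble(tj$planted_as),
                  null_genes = tj$null_genes,
                  confounders = tibble::as_tibble(tj$confounders),
                  effects = tj$effects)
  }
  structure(list(
    models = models,
    expr = read_matrix_tsv(p("expression.tsv")),
    samples = readr::read_tsv(p("samples.tsv"), show_col_types = FALSE,
                              progress = FALSE),
    annotations = annotations_from_gmt(read_gmt(p("genesets.gmt"))),
    proteomics = readr::read_tsv(p("proteomics.tsv"), show_col_types = FALSE,
                                 progress = FALSE),
    bm = read_matrix_tsv(p("bm_expression.tsv"), id = "gene_id"),
    calibration = readr::read_tsv(p("calibration.tsv"),
                                  show_col_types = FALSE, progress = FALSE),
    variants = readr::read_tsv(p("variants.tsv"), show_col_types = FALSE,
                               progress = FALSE),
    truth = truth), class = "cse_bundle")
}
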