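# Shared small fixtures.  Configs keep the required tissues (the five paired
# tissues + Brain are mandatory) but shrink gene and sample counts so unit
# tests stay fast.  Objects are built lazily and cached per test run.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 30,
         n_planted_gene_level = 8L,
         n_planted_as = 2L,
         samples_per_tumor_group = 8L,
         samples_per_normal_tissue = 10L),
    list(...))
  do.call(sim_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_bundle <- function() {
  cached("tiny_bundle", simulate_bundle(tiny_config(), seed = 42))
}

tiny_models <- function() tiny_bundle()$models

tiny_run <- function() {
  cached("tiny_run", run_pipeline(tiny_bundle()))
}

# minimal hand-built gene models for classification tests: gene GX with five
# 100-bp exons, transcript T1 carrying all five and T2 skipping exon 3
toy_models <- function() {
  exons <- tibble::tibble(
    exon_id = sprintf("GX:E%03d", 1:5),
    gene_id = "GX",
    chrom = "chrT",
    start = seq(1000L, by = 500L, length.out = 5),
    end = seq(1099L, by = 500L, length.out = 5),
    strand = "+",
    index_in_gene = 1:5)
  transcripts <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "GX.T1", gene_id = "GX",
                   exon_id = exons$exon_id, exon_order = 1:5),
    tibble::tibble(transcript_id = "GX.T2", gene_id = "GX",
                   exon_id = exons$exon_id[-3], exon_order = 1:4))
  structure(list(exons = exons, transcripts = transcripts),
            class = "cse_models")
}

# a deterministic hand-built two-group expression matrix for rank tests
toy_expr <- function() {
  m <- matrix(c(5, 1, 3,
                2, 2, 2,
                1, 4, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA:E001", "GA:E002", "GB:E001"),
                              c("s1", "s2", "s3")))
  m
}
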