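# Generators: gene models, cohort, annotations, proteomics, variants.

test_that("sim_config validates its arguments", {
  expect_s3_class(sim_config(), "cse_sim_config")
  expect_error(sim_config(n_genes = 0), class = "csefinder_config_error")
  expect_error(sim_config(exons_per_gene = c(1L, 10L)),
               class = "csefinder_config_error")
  expect_error(sim_config(exon_length = c(600L, 60L)),
               class = "csefinder_config_error")
  expect_error(sim_config(samples_per_tumor_group = 0L),
               class = "csefinder_config_error")
  # the detection-floor mechanism requires restricted exons below the floor
  expect_error(sim_config(restricted_normal_fpkm = 0.5),
               class = "csefinder_config_error")
  # required tissues (paired tissues + Brain) must be present
  expect_error(sim_config(normal_tissues = c("Adrenal", "Kidney")),
               class = "csefinder_config_error")
})

test_that("sub-stream seeds are deterministic, distinct and below 2^31", {
  s <- vapply(1:8, function(k) csefinder:::sub_seed(123, k), integer(1))
  expect_identical(s, vapply(1:8, function(k) csefinder:::sub_seed(123, k),
                             integer(1)))
  expect_equal(length(unique(s)), 8L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_true(is.integer(csefinder:::sub_seed(2e9, 5L)))
})

test_that("generators do not disturb the global RNG state", {
  set.seed(99)
  r1 <- runif(3)
  set.seed(99)
  invisible(sim_gene_models(tiny_config(), seed = 7))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("gene models are well-formed and strand-aware", {
  m <- tiny_models()
  cfg <- tiny_config()
  expect_s3_class(m, "cse_models")
  expect_equal(nrow(m$genes), cfg$n_genes)
  expect_true(all(m$exons$end >= m$exons$start))
  lens <- m$exons$end - m$exons$start + 1L
  expect_true(all(lens >= cfg$exon_length[1] & lens <= cfg$exon_length[2]))
  # exons within a gene never overlap
  overlap <- m$exons |>
    dplyr::group_by(gene_id) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(start) > (end - start + 1L)[-dplyr::n()]),
                     .groups = "drop")
  expect_true(all(overlap$ok))
  # index_in_gene is a permutation of 1..k and follows transcription direction
  idx_ok <- m$exons |>
    dplyr::group_by(gene_id) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(
      perm = setequal(index_in_gene, seq_len(dplyr::n())),
      dir = if (strand[1] == "+") !is.unsorted(index_in_gene)
            else !is.unsorted(rev(index_in_gene)),
      .groups = "drop")
  expect_true(all(idx_ok$perm))
  expect_true(all(idx_ok$dir))
  # every cassette exon is skipped by exactly the T2 transcript of its gene
  expect_true(all(m$cassettes$gene_id %in% m$transcripts$gene_id))
  for (i in seq_len(nrow(m$cassettes))) {
    tx <- m$transcripts[m$transcripts$gene_id == m$cassettes$gene_id[i], ]
    in_tx <- tapply(tx$exon_id, tx$transcript_id,
                    function(e) m$cassettes$exon_id[i] %in% e)
    expect_true(any(in_tx) && !all(in_tx))
  }
})

test_that("GTF round trip reconstructs the gene models", {
  m <- tiny_models()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(m, path)
  m2 <- read_gtf(path)
  expect_equal(dplyr::arrange(m2$exons, exon_id),
               dplyr::arrange(m$exons, exon_id))
  expect_equal(dplyr::arrange(m2$transcripts, transcript_id, exon_order),
               dplyr::arrange(m$transcripts, transcript_id, exon_order))
  expect_equal(dplyr::arrange(m2$cassettes, gene_id),
               dplyr::arrange(m$cassettes, gene_id))
})

test_that("cohort matrix matches the design and the detection floor", {
  b <- tiny_bundle()
  cfg <- tiny_config()
  n_samples <- nrow(default_tumor_groups()) * cfg$samples_per_tumor_group +
    length(default_normal_tissues()) * cfg$samples_per_normal_tissue
  expect_equal(dim(b$expr), c(nrow(b$models$exons), n_samples))
  expect_identical(colnames(b$expr), b$samples$sample_id)
  expect_true(all(b$expr >= 0))
  # detection floor: every value is exactly 0 or at least min_detect
  expect_true(all(b$expr == 0 | b$expr >= cfg$min_detect))
})

test_that("planted target exons are tumor-restricted (ties at zero)", {
  b <- tiny_bundle()
  normal_cols <- b$samples$sample_id[b$samples$cohort == "normal"]
  tumor_cols <- b$samples$sample_id[b$samples$cohort == "tumor"]
  # paired-normal confounders are deliberately re-expressed in one normal
  # tissue, so the all-zero property holds for the clean planted genes
  pn <- b$truth$confounders$gene_id[
    b$truth$confounders$type == "paired_normal"]
  gl_rows <- b$models$exons$exon_id[
    b$models$exons$gene_id %in% setdiff(b$truth$planted_gene_level, pn)]
  as_rows <- b$truth$planted_as$exon_id
  restricted <- c(gl_rows, as_rows)
  expect_true(all(b$expr[restricted, normal_cols] == 0))
  # the paired-normal confounder is expressed in its flagged tissue
  conf <- b$truth$confounders[b$truth$confounders$type == "paired_normal", ]
  for (j in seq_len(nrow(conf))) {
    rows <- b$models$exons$exon_id[b$models$exons$gene_id == conf$gene_id[j]]
    cols <- b$samples$sample_id[b$samples$group == conf$detail[j]]
    expect_gt(mean(b$expr[rows, cols]), 1)
  }
  expect_true(all(rowMeans(b$expr[restricted, tumor_cols]) >
                    rowMeans(b$expr[restricted, normal_cols])))
})

test_that("3'-bias confounders ramp 5'->3' in normals only", {
  b <- tiny_bundle()
  normal_cols <- b$samples$sample_id[b$samples$cohort == "normal"]
  tumor_cols <- b$samples$sample_id[b$samples$cohort == "tumor"]
  tp <- b$truth$confounders$gene_id[
    b$truth$confounders$type == "three_prime_bias"]
  expect_true(length(tp) >= 1)
  for (g in tp) {
    ex <- b$models$exons[b$models$exons$gene_id == g, ]
    ex <- ex[order(ex$index_in_gene), ]
    norm_mean <- rowMeans(b$expr[ex$exon_id, normal_cols])
    # the 5'-most exon has zero normal coverage, the 3'-most is fully covered
    expect_equal(unname(norm_mean[1]), 0)
    expect_gt(norm_mean[length(norm_mean)], 0)
    expect_gt(cor(ex$index_in_gene, norm_mean), 0.5)
    # tumors see the whole gene
    expect_true(all(rowMeans(b$expr[ex$exon_id, tumor_cols]) > 0))
  }
})

test_that("confounders are disjoint and drawn from the right pools", {
  b <- tiny_bundle()
  conf <- b$truth$confounders
  expect_equal(anyDuplicated(conf$gene_id), 0L)
  tier_conf <- conf$gene_id[conf$type != "three_prime_bias"]
  expect_true(all(tier_conf %in% b$truth$planted_gene_level))
  tp <- conf$gene_id[conf$type == "three_prime_bias"]
  expect_false(any(tp %in% c(b$truth$planted_gene_level,
                             b$truth$planted_as$gene_id)))
  expect_true(all(b$models$genes$n_exons[
    match(tp, b$models$genes$gene_id)] >= 6L))
  # an over-subscribed confounder budget is rejected
  expect_error(
    simulate_bundle(tiny_config(
      n_planted_gene_level = 2L,
      n_confounders = c(paired_normal = 2L, bone_marrow = 2L,
                        normal_protein = 2L, three_prime_bias = 0L)),
      seed = 1),
    class = "csefinder_config_error")
})

test_that("annotations cover the planted genes and never blacklist them", {
  b <- tiny_bundle()
  ann <- b$annotations
  planted <- unique(c(b$truth$planted_gene_level, b$truth$planted_as$gene_id,
                      b$truth$confounders$gene_id))
  expect_true(all(planted %in% c(ann$surfaceome, ann$matrisome)))
  expect_false(any(planted %in% unlist(ann$blacklist)))
  expect_true(all(ann$oncofetal %in% planted))
})

test_that("tumor proteomics covers every planted exon with at least one PSM", {
  b <- tiny_bundle()
  planted <- unique(c(b$truth$planted_gene_level, b$truth$planted_as$gene_id,
                      b$truth$confounders$gene_id))
  tum <- b$proteomics[b$proteomics$panel == "tumor" &
                        b$proteomics$gene_id %in% planted, ]
  expect_true(all(tum$psm_count >= 1L))
  n_planted_exons <- sum(b$models$exons$gene_id %in% planted)
  expect_equal(nrow(tum), n_planted_exons)
  expect_equal(b$proteomics$npsm,
               b$proteomics$psm_count / b$proteomics$aa_length)
})

test_that("variants land near planted AS exon boundaries in tumor carriers", {
  b <- tiny_bundle()
  v <- b$variants
  cfg <- tiny_config()
  expect_true(all(v$gene_id %in% b$truth$planted_as$gene_id))
  tumor <- b$samples$sample_id[b$samples$cohort == "tumor"]
  expect_true(all(v$sample_id %in% tumor))
  for (i in seq_len(nrow(v))) {
    ex <- b$models$exons[
      b$models$exons$exon_id ==
        b$truth$planted_as$exon_id[b$truth$planted_as$gene_id == v$gene_id[i]], ]
    expect_true(abs(v$pos[i] - ex$start) <= cfg$variant_window ||
                  abs(v$pos[i] - ex$end) <= cfg$variant_window)
    expect_equal(v$chrom[i], ex$chrom)
  }
})

test_that("the nPSM mixture generator hits its generative parameters", {
  x <- sim_npsm_mixture(5000, means_log10 = c(-2, 0), sd_log10 = 0.1,
                        seed = 3)
  lx <- log10(x)
  expect_equal(mean(lx < -1), 0.5, tolerance = 0.05)
  expect_equal(mean(lx[lx < -1]), -2, tolerance = 0.02)
  expect_equal(mean(lx[lx >= -1]), 0, tolerance = 0.02)
})

test_that("simulate_bundle is deterministic in (config, seed)", {
  b1 <- simulate_bundle(tiny_config(n_genes = 12, n_planted_gene_level = 2L,
                                    n_planted_as = 1L,
                                    n_confounders = c(paired_normal = 0L,
                                                      bone_marrow = 0L,
                                                      normal_protein = 0L,
                                                      three_prime_bias = 0L)),
                        seed = 11)
  b2 <- simulate_bundle(tiny_config(n_genes = 12, n_planted_gene_level = 2L,
                                    n_planted_as = 1L,
                                    n_confounders = c(paired_normal = 0L,
                                                      bone_marrow = 0L,
                                                      normal_protein = 0L,
                                                      three_prime_bias = 0L)),
                        seed = 11)
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$proteomics, b2$proteomics)
})
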