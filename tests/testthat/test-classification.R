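# Classification: transcript CSE coverage, AS versus gene-level calls,
# top-AS-exon choice, and splice-variant association.

test_that("transcript coverage is length-weighted over CSE exons", {
  m <- toy_models()
  # five equal 100 bp exons: one CSE exon covers 1/5 of T1
  cov <- transcript_cse_coverage("GX", "GX:E003", m)
  expect_equal(cov$coverage[cov$transcript_id == "GX.T1"], 0.2)
  # T2 skips exon 3, so its CSE coverage is zero
  expect_equal(cov$coverage[cov$transcript_id == "GX.T2"], 0)
  # unequal lengths weight by base pairs, not exon counts
  m2 <- toy_models()
  m2$exons$end[1] <- m2$exons$start[1] + 299L   # exon 1 is 300 bp
  cov2 <- transcript_cse_coverage("GX", "GX:E001", m2)
  expect_equal(cov2$coverage[cov2$transcript_id == "GX.T1"], 300 / 700)
  expect_error(transcript_cse_coverage("GX", "GY:E001", m),
               "not in gene")
})

test_that("classification requires both low coverage and cassette behavior", {
  m <- toy_models()
  cand <- function(exons, z = 5) {
    tibble::tibble(exon_id = exons, gene_id = "GX", composite_z = z)
  }
  # cassette CSE exon: T2 coverage 0 < 0.40 and exon 3 is differentially
  # included -> AS
  as_call <- classify_targets(cand("GX:E003"), m)
  expect_equal(as_call$target_class, "AS")
  expect_equal(as_call$chosen_exon, "GX:E003")
  expect_equal(as_call$coverage_min, 0)
  # a constitutive CSE exon is in every transcript: no differential
  # inclusion, so gene-level despite low coverage
  gl_call <- classify_targets(cand("GX:E002"), m)
  expect_equal(gl_call$target_class, "gene_level")
  expect_true(is.na(gl_call$chosen_exon))
  # when every transcript is well covered the gene is gene-level even if a
  # cassette exon is among the CSEs
  all_call <- classify_targets(cand(sprintf("GX:E%03d", 1:5)), m)
  expect_equal(all_call$target_class, "gene_level")
  # coverage is relative to each transcript's own exons, all of which are CSE
  expect_equal(all_call$coverage_min, 1)
})

test_that("the coverage threshold is a strict upper bound", {
  # single transcript of 5 equal exons: 2 CSE exons -> coverage 0.4 exactly
  m <- toy_models()
  m$transcripts <- rbind(
    m$transcripts[m$transcripts$transcript_id == "GX.T1", ],
    tibble::tibble(transcript_id = "GX.T3", gene_id = "GX",
                   exon_id = sprintf("GX:E%03d", c(1, 2, 4, 5)),
                   exon_order = 1:4))
  cand <- tibble::tibble(exon_id = c("GX:E003", "GX:E004"), gene_id = "GX",
                         composite_z = c(5, 4))
  # T3 coverage = 100 / 400 = 0.25 < 0.40 -> AS
  expect_equal(classify_targets(cand, m)$target_class, "AS")
  # at exactly the threshold the strict < fails -> gene-level
  expect_equal(classify_targets(cand, m, coverage_threshold = 0.25)$target_class,
               "gene_level")
})

test_that("single-transcript genes are always gene-level", {
  m <- toy_models()
  m$transcripts <- m$transcripts[m$transcripts$transcript_id == "GX.T1", ]
  cand <- tibble::tibble(exon_id = "GX:E003", gene_id = "GX", composite_z = 5)
  out <- classify_targets(cand, m)
  expect_equal(out$target_class, "gene_level")
})

test_that("pick_top_as maximizes composite Z with positional tie-break", {
  m <- toy_models()
  comp <- tibble::tibble(exon_id = sprintf("GX:E%03d", 1:4),
                         composite_z = c(2, 7, 7, 1))
  # E002 and E003 tie at 7; E002 has the lower start coordinate
  expect_equal(pick_top_as(sprintf("GX:E%03d", 1:4), comp, m), "GX:E002")
  expect_equal(pick_top_as(c("GX:E003", "GX:E004"), comp, m), "GX:E003")
})

test_that("near_splice_variants uses an inclusive window on both boundaries", {
  exon <- list(chrom = "chrT", start = 2000L, end = 2099L)
  variants <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e", "f"),
    chrom = c("chrT", "chrT", "chrT", "chrT", "chrT", "chrZ"),
    pos = c(1990L, 1989L, 2109L, 2110L, 2050L, 2000L))
  hit <- near_splice_variants(variants, exon, window = 10L)
  # start - 10 and end + 10 are inclusive; start - 11 and end + 11 are out;
  # mid-exon positions and other chromosomes never qualify
  expect_setequal(hit, c("a", "c"))
  expect_identical(near_splice_variants(variants[0, ], exon), character(0))
  # duplicated carrier rows collapse to unique sample ids
  dup <- variants[c(1, 1), ]
  expect_equal(near_splice_variants(dup, exon), "a")
})

test_that("splice_variant_test restricts to high-expressing tumors", {
  samples <- tibble::tibble(
    sample_id = c(sprintf("t%02d", 1:10), "n1", "n2"),
    cohort = rep(c("tumor", "normal"), c(10, 2)))
  # tumors t01..t05 express below the tumor median and are ineligible
  expr_row <- stats::setNames(c(rep(1, 5), 10, 11, 12, 20, 22, 0, 0),
                              samples$sample_id)
  carriers <- c("t09", "t10", "t01")   # t01 is ineligible
  out <- splice_variant_test(expr_row, carriers, samples)
  expect_equal(out$status, "ok")
  expect_equal(out$n_carrier, 2L)
  expect_equal(out$n_noncarrier, 3L)
  expect_equal(out$mean_carrier, 21)
  expect_equal(out$mean_noncarrier, 11)
  # one-sided: carriers higher gives a small p, carriers lower a large one
  expect_lt(out$p_value, 0.2)
  flipped <- splice_variant_test(expr_row, c("t06", "t07"), samples)
  expect_gt(flipped$p_value, 0.5)
})

test_that("splice_variant_test reports insufficient groups without a p-value", {
  samples <- tibble::tibble(sample_id = sprintf("t%02d", 1:6),
                            cohort = "tumor")
  expr_row <- stats::setNames(c(1, 1, 1, 5, 6, 7), samples$sample_id)
  out <- splice_variant_test(expr_row, carriers = "t06", samples)
  expect_equal(out$status, "insufficient")
  expect_true(is.na(out$p_value))
  expect_equal(out$n_carrier, 1L)
})

test_that("pipeline classification recovers the planted AS exons", {
  b <- tiny_bundle()
  run <- tiny_run()
  as_found <- run$targets[run$targets$target_class == "AS", ]
  planted_as <- b$truth$planted_as
  common <- intersect(as_found$gene_id, planted_as$gene_id)
  expect_true(length(common) >= 1)
  for (g in common) {
    expect_equal(as_found$chosen_exon[as_found$gene_id == g],
                 planted_as$exon_id[planted_as$gene_id == g])
  }
  # variant tests were run for AS targets only
  expect_true(all(run$variant_tests$gene_id %in% as_found$gene_id))
})
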