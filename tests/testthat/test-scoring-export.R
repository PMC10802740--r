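# Scoring: quartile bins, type scores, prevalence; portal export and bundle
# round trips.

test_that("binned_scores reproduces the quartile oracle", {
  v <- stats::setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  # type-7 quantiles of {1,2,3,4}: Q1 = 1.75, Q2 = 2.5, Q3 = 3.25
  b <- binned_scores(v)
  expect_identical(unname(b), 0:3)
  expect_identical(names(b), names(v))
  # explicit breaks follow right-closed intervals with strict upper opens
  b2 <- binned_scores(stats::setNames(c(1, 1.75, 2.5, 3.25, 3.26), paste0("t", 1:5)),
                      breaks = c(1.75, 2.5, 3.25))
  expect_identical(unname(b2), c(0L, 0L, 1L, 2L, 3L))
  expect_error(binned_scores(v, breaks = c(3, 2, 1)), "non-decreasing")
})

test_that("the expression floor forces bin 0 below 1 FPKM", {
  v <- stats::setNames(c(0.2, 0.999, 1, 5, 10, 20), paste0("s", 1:6))
  b <- binned_scores(v)
  expect_identical(unname(b[1:2]), c(0L, 0L))
  # breaks come from the at-or-above-floor values only
  q <- unname(quantile(c(1, 5, 10, 20), c(0.25, 0.5, 0.75), type = 7))
  expect_identical(unname(b[3:6]),
                   as.integer((v[3:6] > q[1]) + (v[3:6] > q[2]) +
                                (v[3:6] > q[3])))
  # no value at the floor -> all zero
  expect_identical(unname(binned_scores(c(a = 0.1, b = 0.5))), c(0L, 0L))
  # the floor is configurable
  expect_identical(unname(binned_scores(v, floor = 100)), rep(0L, 6))
})

test_that("type scores average per type first, then across types", {
  samples <- tibble::tibble(
    sample_id = c("t1", "t2", "t3", "t4", "n1", "n2"),
    cohort = c(rep("tumor", 4), rep("normal", 2)),
    group = c("TA", "TA", "TB", "TB", "NA1", "NA2"))
  bins <- stats::setNames(c(3L, 1L, 0L, 2L, 0L, 3L), samples$sample_id)
  ts <- type_scores(bins, samples)
  expect_equal(ts$tumor_score, mean(c(2, 1)))   # TA mean 2, TB mean 1
  expect_equal(ts$normal_score, mean(c(0, 3)))
  # per-type averaging is invariant to duplicating a type's samples
  samples2 <- dplyr::bind_rows(samples, samples[1:2, ] |>
                                 dplyr::mutate(sample_id = c("t1b", "t2b")))
  bins2 <- c(bins, stats::setNames(c(3L, 1L), c("t1b", "t2b")))
  expect_equal(type_scores(bins2, samples2)$tumor_score, ts$tumor_score)
  # zero-sample types are excluded with a warning
  samples3 <- dplyr::bind_rows(samples,
                               tibble::tibble(sample_id = "z1",
                                              cohort = "tumor", group = "TZ"))
  expect_warning(ts3 <- type_scores(bins, samples3), "TZ")
  expect_equal(ts3$tumor_score, ts$tumor_score)
})

test_that("prevalence is the fraction of top-quartile samples per type", {
  samples <- tibble::tibble(
    sample_id = c("t1", "t2", "t3", "t4", "n1", "n2"),
    cohort = c(rep("tumor", 4), rep("normal", 2)),
    group = c("TA", "TA", "TA", "TA", "NA1", "NA1"))
  bins <- stats::setNames(c(3L, 3L, 1L, 0L, 3L, 0L), samples$sample_id)
  pv <- prevalence(bins, samples)
  expect_equal(pv$prevalence[pv$group == "TA"], 0.5)
  expect_equal(pv$prevalence[pv$group == "NA1"], 0.5)
})

test_that("score_exons yields bounded scores consistent with its pieces", {
  b <- tiny_bundle()
  ids <- rownames(b$expr)[1:8]
  sc <- score_exons(b$expr, b$samples, exon_ids = ids)
  expect_s3_class(sc, "cse_scores")
  expect_true(all(sc$bins %in% 0:3))
  expect_true(all(sc$summary$tumor_score >= 0 & sc$summary$tumor_score <= 3))
  expect_true(all(sc$summary$normal_score >= 0 & sc$summary$normal_score <= 3))
  expect_true(all(sc$prevalence$prevalence >= 0 &
                    sc$prevalence$prevalence <= 1))
  # row 1 of the matrix path matches the scalar path
  one <- binned_scores(b$expr[ids[1], ])
  expect_identical(sc$bins[ids[1], ], one)
  ts <- suppressWarnings(type_scores(one, b$samples))
  expect_equal(unname(sc$summary$tumor_score[1]), ts$tumor_score)
  expect_equal(unname(sc$summary$normal_score[1]), ts$normal_score)
  # a single exon keeps matrix shape
  sc1 <- score_exons(b$expr, b$samples, exon_ids = ids[1])
  expect_equal(nrow(sc1$summary), 1)
  expect_identical(tidy(sc1), sc1$summary)
  expect_output(print(sc1), "cse_scores")
})

test_that("matrix and GMT round trips are faithful", {
  m <- matrix(c(0, 1.5, 2, 3), 2, 2,
              dimnames = list(c("e1", "e2"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  expect_equal(read_matrix_tsv(path), m)
  sets <- list(surfaceome = c("G1", "G2"), matrisome = "G3")
  gpath <- withr::local_tempfile(fileext = ".gmt")
  csefinder:::write_gmt(sets, gpath)
  expect_identical(csefinder:::read_gmt(gpath), sets)
})

test_that("bundle round trip preserves the pipeline inputs", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$expr, b$expr)
  expect_equal(b2$samples, b$samples, ignore_attr = TRUE)
  expect_equal(dplyr::arrange(b2$models$exons, exon_id),
               dplyr::arrange(b$models$exons, exon_id))
  expect_setequal(b2$annotations$surfaceome, b$annotations$surfaceome)
  expect_setequal(unlist(b2$annotations$blacklist, use.names = FALSE),
                  unlist(b$annotations$blacklist, use.names = FALSE))
  expect_equal(b2$truth$planted_gene_level, b$truth$planted_gene_level)
  expect_equal(sort(b2$truth$confounders$gene_id),
               sort(b$truth$confounders$gene_id))
})

test_that("export_portal writes the portal views deterministically", {
  run <- tiny_run()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_portal(run, d1)
  export_portal(run, d2)
  files <- c("scatter.tsv", "table_view.tsv", "heatmap.tsv",
             "gene_view.json", "manifest.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  scatter <- readr::read_tsv(file.path(d1, "scatter.tsv"),
                             show_col_types = FALSE)
  expect_setequal(
    names(scatter),
    c("gene_id", "exon_id", "tumor_score", "normal_score", "tier",
      "target_class", "localization"))
  expect_equal(nrow(scatter), nrow(run$targets))
  expect_true(all(scatter$tier %in% 1:2))
  heat <- readr::read_tsv(file.path(d1, "heatmap.tsv"),
                          show_col_types = FALSE)
  rank_cols <- setdiff(names(heat),
                       c("exon_id", "compartment", "gene_id", "is_cse"))
  vals <- unlist(heat[rank_cols])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$n_targets, nrow(run$targets))
})
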