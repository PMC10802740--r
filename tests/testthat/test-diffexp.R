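# Differential expression: U statistic, Z-scores, weights, composites.

# brute-force pairwise-enumeration oracle for the U statistic
u_brute <- function(x, y) {
  s <- outer(x, y, function(a, b) (b < a) + 0.5 * (b == a))
  sum(s)
}

test_that("the U statistic matches hand-computed tie cases", {
  # x = (3, 1, 2), y = (2, 2): pairs 3>2 (x2) -> 2; 1<2 (x2) -> 0;
  # 2 = 2 (x2) -> 1; U = 3
  expect_equal(u_statistic(c(3, 1, 2), c(2, 2)), 3)
  # a single tied pair scores exactly one half
  expect_equal(u_statistic(1, 1), 0.5)
  expect_equal(u_statistic(5, 1), 1)
  expect_equal(u_statistic(1, 5), 0)
  expect_error(u_statistic(numeric(0), 1), "non-empty")
})

test_that("mid-rank computation equals pairwise enumeration under heavy ties", {
  set.seed(101)
  for (i in 1:300) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    # values from a small alphabet force many ties, including cross-group
    x <- sample(0:3, n1, replace = TRUE)
    y <- sample(0:3, n2, replace = TRUE)
    expect_identical(u_statistic(x, y), u_brute(x, y))
  }
})

test_that("z_from_u applies the plain normal approximation", {
  # n1 = n2 = 2, U = 4: z = (4 - 2) / sqrt(2 * 2 * 5 / 12)
  expect_equal(z_from_u(4, 2, 2), 2 / sqrt(20 / 12))
  expect_equal(z_from_u(2, 2, 2), 0)
  # vectorized over u, and antisymmetric about the null mean
  expect_equal(z_from_u(c(0, 4), 2, 2), -rev(z_from_u(c(0, 4), 2, 2)))
  expect_error(z_from_u(1, 0, 2), ">= 1")
  # sigma override is honored
  expect_equal(z_from_u(4, 2, 2, sigma_u = 1), 2)
})

test_that("the tie-corrected sigma shrinks under ties and matches no-tie sigma", {
  x <- c(1, 2, 3)
  y <- c(4, 5, 6)
  expect_equal(sigma_u_corrected(x, y), sqrt(3 * 3 * 7 / 12))
  expect_lt(sigma_u_corrected(c(1, 1, 1), c(1, 1, 2)), sqrt(3 * 3 * 7 / 12))
})

test_that("pair weights are median rank differences with domain checks", {
  expect_equal(pair_weight(c(0.8, 0.85, 0.9), c(0.1, 0.15, 0.2)), 0.7)
  # antisymmetric under group exchange
  expect_equal(pair_weight(c(0.1, 0.15, 0.2), c(0.8, 0.85, 0.9)), -0.7)
  expect_error(pair_weight(c(0, 0.5), c(0.4)), "strictly")
  expect_error(pair_weight(c(0.5), c(1)), "strictly")
  expect_error(pair_weight(numeric(0), 0.5), "non-empty")
})

test_that("composite identities hold exactly", {
  # k = 1 reduces to sign(w) * z
  expect_equal(composite_z(2.5, 0.3)$composite_z, 2.5)
  expect_equal(composite_z(2.5, -0.3)$composite_z, -2.5)
  # equal positive weights reduce to the unweighted Stouffer sum
  zs <- c(1.2, -0.4, 2.2, 0.9)
  expect_equal(composite_z(zs, rep(0.25, 4))$composite_z, sum(zs) / sqrt(4))
  # invariant under simultaneous sign flip (group exchange flips z and w)
  ws <- c(0.5, -0.1, 0.3, 0.2)
  expect_equal(composite_z(-zs, -ws)$composite_z,
               composite_z(zs, ws)$composite_z)
  # degenerate all-zero weights
  d <- composite_z(zs, rep(0, 4))
  expect_true(d$degenerate)
  expect_equal(d$composite_z, 0)
  expect_error(composite_z(1:2, 1), "equal length")
  expect_error(composite_z(numeric(0), numeric(0)), "At least one")
})

test_that("run_differential assembles all tumor x normal pairs", {
  b <- tiny_bundle()
  d <- cached("tiny_diff_solid",
              run_differential(b$expr, b$samples, "solid"))
  n_solid <- sum(default_tumor_groups()$compartment == "solid")
  n_norm <- length(default_normal_tissues())
  k <- n_solid * n_norm
  expect_s3_class(d, "cse_diffexp")
  expect_equal(unique(d$composite$k), k)
  expect_equal(nrow(d$pairwise), nrow(b$expr) * k)
  expect_equal(nrow(d$composite), nrow(b$expr))
  expect_setequal(d$tumor_groups,
                  default_tumor_groups()$group[
                    default_tumor_groups()$compartment == "solid"])
  # rank matrix spans exactly the compartment's tumor plus all normal samples
  is_solid_tumor <- b$samples$cohort == "tumor" &
    !is.na(b$samples$compartment) & b$samples$compartment == "solid"
  used <- b$samples$sample_id[is_solid_tumor | b$samples$cohort == "normal"]
  expect_setequal(colnames(d$ranks), used)
  expect_equal(unname(rowMeans(d$ranks)), rep(0.5, nrow(d$ranks)))
  expect_setequal(colnames(d$group_median_ranks),
                  c(d$tumor_groups, d$normal_groups))
})

test_that("pairwise rows agree with the scalar primitives", {
  b <- tiny_bundle()
  d <- cached("tiny_diff_solid",
              run_differential(b$expr, b$samples, "solid"))
  row <- d$pairwise[d$pairwise$exon_id == rownames(b$expr)[5] &
                      d$pairwise$tumor_group == d$tumor_groups[1] &
                      d$pairwise$normal_group == "Kidney", ]
  xi <- b$samples$sample_id[b$samples$group == d$tumor_groups[1]]
  yi <- b$samples$sample_id[b$samples$group == "Kidney"]
  x <- b$expr[rownames(b$expr)[5], xi]
  y <- b$expr[rownames(b$expr)[5], yi]
  expect_equal(row$u, u_statistic(x, y))
  expect_equal(row$z, z_from_u(row$u, length(x), length(y)))
  gm <- d$group_median_ranks
  expect_equal(row$w, unname(gm[rownames(b$expr)[5], d$tumor_groups[1]] -
                               gm[rownames(b$expr)[5], "Kidney"]))
  # the composite row reproduces the weighted Stouffer combination
  pw <- d$pairwise[d$pairwise$exon_id == rownames(b$expr)[5], ]
  expect_equal(
    d$composite$composite_z[d$composite$exon_id == rownames(b$expr)[5]],
    composite_z(pw$z, pw$w)$composite_z)
})

test_that("tie correction and pair-scoped ranks are functional alternatives", {
  b <- tiny_bundle()
  d0 <- cached("tiny_diff_solid",
               run_differential(b$expr, b$samples, "solid"))
  # restricted planted exons tie at zero across normals, so the corrected
  # sigma (and hence z) must differ there
  gl_ex <- b$models$exons$exon_id[
    b$models$exons$gene_id %in% b$truth$planted_gene_level]
  sub <- unique(c(gl_ex[1:4], rownames(b$expr)[1:8]))
  dt <- run_differential(b$expr[sub, ], b$samples, "solid",
                         tie_correction = TRUE)
  key <- function(p) paste(p$exon_id, p$tumor_group, p$normal_group)
  z0 <- d0$pairwise$z[match(key(dt$pairwise), key(d0$pairwise))]
  expect_false(isTRUE(all.equal(dt$pairwise$z, z0)))
  # where the corrected sigma shrinks, |z| grows
  expect_true(all(abs(dt$pairwise$z) >= abs(z0) - 1e-12))
  dp <- run_differential(b$expr[sub, ], b$samples, "solid",
                         rank_scope = "pair")
  expect_s3_class(dp, "cse_diffexp")
  expect_equal(nrow(dp$composite), 12)
  expect_error(run_differential(b$expr, b$samples, "nope"),
               "No tumor groups")
})

test_that("diffexp tidiers expose the composite table and pair counts", {
  d <- cached("tiny_diff_solid",
              run_differential(tiny_bundle()$expr, tiny_bundle()$samples,
                               "solid"))
  expect_identical(tidy(d), d$composite)
  g <- glance(d)
  expect_equal(g$n_exons, nrow(d$composite))
  expect_equal(g$compartment, "solid")
  expect_output(print(d), "cse_diffexp")
})
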