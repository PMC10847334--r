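test_that("identical config and seed give bit-identical output", {
  cfg <- simulation_config(n_genes = 20, n_cells = 50, phi = 0.7, seed = 11)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$matrix$counts_A, s2$matrix$counts_A)
  expect_identical(s1$truth, s2$truth)
  t1 <- split_to_snp_reads(s1$matrix, cfg)
  t2 <- split_to_snp_reads(s2$matrix, cfg)
  expect_identical(t1, t2)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(kon_range = c(-1, 2)), "positive lower")
  expect_error(simulation_config(kon_range = c(3, 1)), "lower <= upper")
  expect_error(simulation_config(phi = 1.2), "probability")
  expect_error(simulation_config(dropout_rate = 1), "probability")
  expect_error(simulation_config(n_snps_range = c(0, 2)), "counts >= 1")
  expect_error(simulation_config(q_range = c(0, 0.5)), "strictly inside")
})

test_that("ground-truth p0/p2 match the coupled-snapshot closed form", {
  # phi = 0.5, q = 0.4: Monte-Carlo oracle (2e6 draws) gave
  # p0_state = 0.2800, p2_state = 0.4798 for the closed form
  # p0 = phi*q + (1-phi)*q^2, p2 = phi*(1-q) + (1-phi)*(1-q)^2
  cfg <- simulation_config(n_genes = 5, n_cells = 10, kon_range = c(1.5, 1.5),
                           koff_range = c(1, 1), s_range = c(30, 30),
                           phi = 0.5, seed = 1)
  tr <- simulate_counts(cfg)$truth
  expect_equal(tr$q, rep(0.4, 5))
  expect_equal(tr$expected_p0_state, rep(0.28, 5))
  expect_equal(tr$expected_p2_state, rep(0.48, 5))
  # phi = 0, q = 0.5, s large: independence with symmetric q
  cfg2 <- simulation_config(n_genes = 3, n_cells = 10, kon_range = c(2, 2),
                            koff_range = c(2, 2), s_range = c(500, 500),
                            phi = 0, seed = 1)
  tr2 <- simulate_counts(cfg2)$truth
  expect_equal(tr2$expected_p0, rep(0.25, 3), tolerance = 1e-10)
  expect_equal(tr2$expected_p2, rep(0.25, 3), tolerance = 1e-10)
  # phi = 1: state-level p0 + p2 = 1 exactly
  cfg3 <- simulation_config(n_genes = 3, n_cells = 10, phi = 1, seed = 1)
  tr3 <- simulate_counts(cfg3)$truth
  expect_equal(tr3$expected_p0_state + tr3$expected_p2_state, rep(1, 3))
})

test_that("observed p0/p2 track the ground-truth expectations", {
  cfg <- simulation_config(n_genes = 60, n_cells = 4000, phi = 0.5,
                           kon_range = c(0.5, 2), koff_range = c(1, 6),
                           s_range = c(15, 40), seed = 8)
  sim <- simulate_counts(cfg)
  pp <- compute_p0_p2(sim$matrix)
  expect_lt(max(abs(pp$p0 - sim$truth$expected_p0)), 0.05)
  expect_lt(max(abs(pp$p2 - sim$truth$expected_p2)), 0.05)
})

test_that("per-allele count marginals are invariant to the coupling phi", {
  base <- list(n_genes = 100, n_cells = 2000, kon_range = c(1, 1),
               koff_range = c(3, 3), s_range = c(25, 25))
  m0 <- do.call(simulation_config, c(base, phi = 0, seed = 31))
  m1 <- do.call(simulation_config, c(base, phi = 1, seed = 32))
  s0 <- simulate_counts(m0); s1 <- simulate_counts(m1)
  # mean per allele ~ s * (1 - q) = 25 * 0.25 = 6.25 for any phi
  expect_equal(mean(s0$matrix$counts_A), 6.25, tolerance = 0.05)
  expect_equal(mean(s1$matrix$counts_A), 6.25, tolerance = 0.05)
  expect_equal(mean(s0$matrix$counts_B), mean(s1$matrix$counts_B),
               tolerance = 0.05)
})

test_that("phi = 0 genes fall on the independence curve, phi = 1 on the diagonal", {
  cfg0 <- simulation_config(n_genes = 200, n_cells = 2000, phi = 0,
                            q_range = c(0.3, 0.7), s_range = c(30, 30),
                            seed = 13)
  pp0 <- compute_p0_p2(simulate_counts(cfg0)$matrix)
  expect_lt(median(abs(pp0$p2 - independence_curve(pp0$p0))), 0.02)
  cfg1 <- simulation_config(n_genes = 100, n_cells = 500, phi = 1,
                            s_range = c(30, 50), seed = 14)
  pp1 <- compute_p0_p2(simulate_counts(cfg1)$matrix)
  expect_lt(max(abs(pp1$p0 + pp1$p2 - 1)), 1e-6)
})

test_that("X-linked fixture genes have allele A silenced everywhere", {
  cfg <- simulation_config(n_genes = 10, n_cells = 200, n_xlinked = 4,
                           phi = 0.5, seed = 3)
  sim <- simulate_counts(cfg)
  xl <- sim$matrix$genes$xlinked
  expect_identical(sum(xl), 4L)
  expect_true(all(sim$matrix$counts_A[xl, ] == 0))
  expect_gt(sum(sim$matrix$counts_B[xl, ]), 0)
  expect_true(all(sim$matrix$genes$chrom[xl] == "chrX"))
})

test_that("SNP split conserves reads and is recovered by aggregation", {
  cfg <- simulation_config(n_genes = 25, n_cells = 60, phi = 0.5,
                           n_snps_range = c(3, 3), depth_mean = Inf,
                           s_range = c(20, 40), seed = 4)
  sim <- simulate_counts(cfg)
  tab <- split_to_snp_reads(sim$matrix, cfg)
  # conservation: per (gene, cell) SNP reads sum to the gene count
  sums <- stats::xtabs(reads_A ~ gene_id + cell_id, tab)
  gg <- rownames(sums)
  expect_equal(unclass(sums)[, colnames(sums)],
               sim$matrix$counts_A[gg, colnames(sums)],
               ignore_attr = TRUE)
  # round trip through the aggregation module: equal up to the known
  # 1/n_snps scale of across-SNP averaging
  acm <- aggregate_snp_to_gene(tab, gene_meta = sim$matrix$genes,
                               cell_meta = sim$matrix$cells[, c("cell_id", "stage")])
  shared <- acm$genes$gene_id
  expect_gt(length(shared), 20)
  expect_equal(acm$counts_A[shared, ] * 3,
               sim$matrix$counts_A[shared, acm$cells$cell_id],
               ignore_attr = TRUE)
  # allelic proportions conserved exactly
  r_in <- allelic_ratio(sim$matrix)[shared, acm$cells$cell_id]
  r_out <- allelic_ratio(acm)[shared, ]
  expect_equal(r_out, r_in, ignore_attr = TRUE)
})

test_that("sequencing depth scales SNP reads like a thinned/amplified Poisson", {
  cfg <- simulation_config(n_genes = 40, n_cells = 200, phi = 0.5,
                           n_snps_range = c(2, 4), depth_mean = 5,
                           s_range = c(20, 40), seed = 6)
  sim <- simulate_counts(cfg)
  tab <- split_to_snp_reads(sim$matrix, cfg)
  # totals are Poisson(5 * molecules): the grand total has mean
  # 5 * sum(counts) and CV < 1%, so a 3% band is a sharp check
  expect_equal(sum(tab$reads_A) + sum(tab$reads_B),
               5 * (sum(round(sim$matrix$counts_A)) +
                      sum(round(sim$matrix$counts_B))),
               tolerance = 0.03)
})

test_that("dropout zeroes only low-count entries", {
  cfg <- simulation_config(n_genes = 40, n_cells = 300, phi = 0.5,
                           n_snps_range = c(2, 2), depth_mean = Inf,
                           dropout_rate = 0.5, dropout_max_reads = 5,
                           s_range = c(10, 30), seed = 7)
  sim <- simulate_counts(cfg)
  tab <- split_to_snp_reads(sim$matrix, cfg)
  agg_A <- stats::xtabs(reads_A ~ gene_id + cell_id, tab)
  orig <- sim$matrix$counts_A[rownames(agg_A), colnames(agg_A)]
  lost <- orig - unclass(agg_A)
  expect_true(all(lost >= 0))
  expect_gt(sum(lost > 0), 0)                  # some entries dropped
  expect_true(all(orig[lost > 0] <= 5))        # only low-count ones
})

test_that("coverage simulation honours enrichment levels and symmetry", {
  genes <- make_genes(20)
  tr_eq <- simulate_coverage(genes, 1.5, 1.5, noise_sd = 0, seed = 5)
  expect_identical(tr_eq$A, tr_eq$B)
  tr <- simulate_coverage(genes, 2, 1, noise_sd = 0, seed = 5)
  sA <- gene_region_scores(tr$A, genes, flank_bp = 0)
  sB <- gene_region_scores(tr$B, genes, flank_bp = 0)
  expect_equal(unname(sA), rep(2, 20))
  expect_equal(unname(sB), rep(1, 20))
  expect_error(simulate_coverage(genes, -1, 1), "non-negative")
})

test_that("noisy coverage still separates alleles by Mann-Whitney", {
  genes <- make_genes(100)
  tr <- simulate_coverage(genes, 2, 1, noise_sd = 0.1, seed = 12)
  sA <- gene_region_scores(tr$A, genes, flank_bp = 0)
  sB <- gene_region_scores(tr$B, genes, flank_bp = 0)
  expect_lt(compare_allelic_enrichment(sA, sB)$p, 0.01)
})
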