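test_that("per-cell monoallelic call uses the inclusive 95% rule", {
  expect_identical(call_cell_state(19, 1), "mono_A")    # ratio exactly 0.95
  expect_identical(call_cell_state(1, 19), "mono_B")
  expect_identical(call_cell_state(94, 6), "biallelic") # 0.94 < 0.95
  expect_identical(call_cell_state(0, 0), "silent")
  expect_identical(call_cell_state(0, 7), "mono_B")
  expect_identical(call_cell_state(c(19, 0), c(1, 0)), c("mono_A", "silent"))
})

test_that("raising the monoallelic threshold never adds mono calls", {
  set.seed(5)
  A <- rpois(500, 6); B <- rpois(500, 6)
  n_mono <- function(thr) sum(call_cell_state(A, B, thr) %in%
                                c("mono_A", "mono_B"))
  thresholds <- seq(0.5, 1, by = 0.05)
  counts <- vapply(thresholds, n_mono, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gene classification separates silent, monoallelic and biallelic", {
  n <- 100
  A <- rbind(c(rep(10, 2), rep(0, n - 2)),    # detected in 2% of cells: silent
             rep(10, n),                      # all mono_A: monoallelic
             c(rep(10, 60), rep(0, n - 60)))  # mixed calls: biallelic
  B <- rbind(rep(0, n), rep(0, n), c(rep(0, 30), rep(10, n - 30)))
  acm <- make_acm(A, B)
  cl <- classify_gene_expression(acm)
  expect_identical(cl$expr_class, c("silent", "monoallelic", "biallelic"))
  # burst_class is not_applicable exactly for non-biallelic genes
  expect_identical(cl$burst_class[1:2], rep("not_applicable", 2))
  expect_false(cl$burst_class[3] == "not_applicable")
})

test_that("X-linked fixture is classified monoallelic for the CAST allele", {
  cfg <- simulation_config(n_genes = 5, n_cells = 200, n_xlinked = 5,
                           phi = 0.5, kon_range = c(1, 2),
                           koff_range = c(1, 3), s_range = c(20, 40),
                           seed = 2)
  sim <- simulate_counts(cfg)
  cl <- classify_gene_expression(sim$matrix)
  xl <- sim$matrix$genes$xlinked
  expect_true(all(cl$expr_class[xl] == "monoallelic"))
  states <- cell_state_matrix(sim$matrix)[xl, ]
  expect_true(all(states %in% c("mono_B", "silent")))
})

test_that("simulated biallelic genes are overwhelmingly classified biallelic", {
  cfg <- simulation_config(n_genes = 1000, n_cells = 300, phi = 0.5,
                           kon_range = c(1, 1), koff_range = c(1, 1),
                           s_range = c(10, 50), seed = 9)  # q = 0.5
  cl <- classify_gene_expression(simulate_counts(cfg)$matrix)
  expect_gte(mean(cl$expr_class == "biallelic"), 0.95)
})

test_that("bursty versus constitutive follows the both-zero-window rule", {
  n <- 200
  # both alleles in every cell -> constitutive
  acm1 <- make_acm(matrix(5, 1, n), matrix(5, 1, n))
  expect_identical(unname(classify_bursty(acm1, 1)), "constitutive")
  # one allele near-ubiquitous (>= 95% of cells) -> constitutive
  A2 <- matrix(c(rep(5, 195), rep(0, 5)), 1, n)
  B2 <- matrix(rbinom(n, 1, 0.4) * 3, 1, n)
  expect_identical(unname(classify_bursty(make_acm(A2, B2), 1)), "constitutive")
  # kon = 0.5, koff = 2, phi = 1: q = 0.8, P(no both-zero cell in 500)
  # = (1 - 0.8)^500 < 1e-20, so a both-zero window is guaranteed
  cfg <- simulation_config(n_genes = 20, n_cells = 500,
                           kon_range = c(0.5, 0.5), koff_range = c(2, 2),
                           s_range = c(30, 30), phi = 1, seed = 6)
  sim <- simulate_counts(cfg)
  expect_true(all(classify_bursty(sim$matrix, seq_len(20)) == "bursty"))
})

test_that("aRME categories partition the calls", {
  expect_identical(classify_arme(c("mono_A", "mono_A")), "Cat1_nonrandom_mono")
  expect_identical(classify_arme(c("mono_A", "biallelic")), "Cat2_rme_one_allele")
  expect_identical(classify_arme(c("mono_A", "mono_B", "biallelic")),
                   "Cat3_rme_either_allele")
  expect_identical(classify_arme(c("mono_A", "mono_B")), "Cat3_rme_either_allele")
  expect_identical(classify_arme(c("biallelic", "silent")), "Cat4_biallelic")
  expect_error(classify_arme("silent"), "expressing cell")
  # cell order is irrelevant
  calls <- c("mono_A", "biallelic", "mono_B", "silent")
  expect_identical(classify_arme(calls), classify_arme(rev(calls)))
})

test_that("every expressed gene receives exactly one aRME category", {
  cfg <- simulation_config(n_genes = 200, n_cells = 100, phi = 0.3, seed = 17)
  sim <- simulate_counts(cfg)
  arme <- classify_arme_matrix(sim$matrix)
  expect_identical(anyDuplicated(arme$gene_id), 0L)
  expect_true(all(arme$category %in%
                    c("Cat1_nonrandom_mono", "Cat2_rme_one_allele",
                      "Cat3_rme_either_allele", "Cat4_biallelic")))
  expressed <- rowSums(sim$matrix$counts_A + sim$matrix$counts_B) > 0
  expect_identical(nrow(arme), sum(expressed))
})

test_that("class crosstabs recover known trajectories", {
  s1 <- data.frame(gene_id = c("g1", "g2", "g3"),
                   burst_class = c("bursty", "bursty", "constitutive"))
  s2 <- s1
  ct <- crosstab_classes(list(d0 = s1, d8 = s2))
  expect_identical(sum(ct$trajectories$n), 3L)
  expect_true(all(ct$genes$d0 == ct$genes$d8))       # diagonal
  s2$burst_class[1] <- "constitutive"                # one gene flips
  ct2 <- crosstab_classes(list(d0 = s1, d8 = s2))
  expect_identical(unname(ct2$table["bursty", "constitutive"]), 1L)
  # restriction to shared genes; empty overlap warns
  s3 <- data.frame(gene_id = "g9", burst_class = "bursty")
  expect_warning(ct3 <- crosstab_classes(list(s1, s3)), "no genes shared")
  expect_identical(nrow(ct3$trajectories), 0L)
})

test_that("three-stage trajectories are bookkept correctly", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:30)
  cls <- function(flip) data.frame(
    gene_id = genes,
    burst_class = ifelse(seq_along(genes) %in% flip, "constitutive", "bursty"))
  ct <- crosstab_classes(list(a = cls(NULL), b = cls(NULL), c = cls(1:5)))
  tr <- ct$trajectories
  expect_identical(tr$n[tr$trajectory == "bursty -> bursty -> bursty"], 25L)
  expect_identical(tr$n[tr$trajectory == "bursty -> bursty -> constitutive"], 5L)
})
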