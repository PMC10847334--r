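test_that("p0/p2 are direct detection fractions", {
  A <- matrix(c(0, 3, 5, 0), 1, 4)
  B <- matrix(c(0, 2, 0, 1), 1, 4)
  pp <- compute_p0_p2(make_acm(A, B))
  expect_equal(pp$p0, 0.25)
  expect_equal(pp$p2, 0.25)
  all0 <- compute_p0_p2(make_acm(matrix(0, 1, 4), matrix(0, 1, 4)))
  expect_equal(c(all0$p0, all0$p2), c(1, 0))
})

test_that("independence curve is (1 - sqrt(p0))^2", {
  expect_equal(independence_curve(0), 1)
  expect_equal(independence_curve(1), 0)
  expect_equal(independence_curve(0.25), 0.25)
  expect_error(independence_curve(-0.1), "in \\[0,1\\]")
})

test_that("coordination classification follows threshold, band and precedence", {
  # sum 0.95 > 0.90: highly coordinated even though near p0 extremes
  expect_identical(classify_coordination(0.5, 0.45)$category,
                   "highly_coordinated")
  # on the curve: independent
  expect_identical(classify_coordination(0.25, 0.25)$category, "independent")
  # above the band but under the diagonal: semi-coordinated
  rec <- classify_coordination(0.3, 0.45)
  expect_identical(rec$category, "semi_coordinated")
  expect_equal(rec$deviation, 0.45 - (1 - sqrt(0.3))^2, tolerance = 1e-12)
  # corner overlap: the highly-coordinated rule wins over the band
  expect_identical(classify_coordination(0.95, 0.01)$category,
                   "highly_coordinated")
  expect_identical(classify_coordination(0.02, 0.95)$category,
                   "highly_coordinated")
  expect_true(classify_coordination(0.02, 0.95)$low_p0_high_p2)
  # below the lower band: independent with a negative-deviation flag
  low <- classify_coordination(0.25, 0.1)
  expect_identical(low$category, "independent")
  expect_true(low$negative_deviation)
  # just inside the band edges
  expect_identical(classify_coordination(0.25, 0.25 + 0.05)$category,
                   "independent")
  expect_identical(classify_coordination(0.25, 0.25 + 0.0501)$category,
                   "semi_coordinated")
  expect_error(classify_coordination(0.6, 0.6), "cannot exceed 1")
})

test_that("phi = 1 simulations are classified highly coordinated", {
  cfg <- simulation_config(n_genes = 200, n_cells = 300, phi = 1,
                           s_range = c(20, 50), seed = 23)
  rec <- coordination_records(simulate_counts(cfg)$matrix)
  expect_gte(mean(rec$category == "highly_coordinated"), 0.95)
})

test_that("phi = 0 simulations sit on the independence curve", {
  cfg <- simulation_config(n_genes = 300, n_cells = 1000, phi = 0,
                           q_range = c(0.2, 0.8), s_range = c(20, 20),
                           seed = 24)
  rec <- coordination_records(simulate_counts(cfg)$matrix)
  expect_lte(median(abs(rec$deviation)), 0.05)
  ok <- rec$category %in% c("independent", "highly_coordinated")
  expect_gte(mean(ok), 0.8)
})

test_that("mean p0 + p2 is monotone in the coupling phi", {
  sums <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(phi) {
    cfg <- simulation_config(n_genes = 150, n_cells = 800, phi = phi,
                             kon_range = c(1, 1), koff_range = c(2, 2),
                             s_range = c(25, 25), seed = 42)
    pp <- compute_p0_p2(simulate_counts(cfg)$matrix)
    mean(pp$p0 + pp$p2)
  }, numeric(1))
  # closed form: p0 + p2 = 1 - 2 (1 - phi) q (1 - q); allow MC jitter
  expect_true(all(diff(sums) > -0.01))
  expect_equal(sums[1], 1 - 2 * (2 / 3) * (1 / 3), tolerance = 0.02)
  expect_equal(sums[5], 1, tolerance = 1e-3)
})

test_that("expression comparison by category detects constructed differences", {
  set.seed(77)
  n_cells <- 50
  high <- matrix(rpois(20 * n_cells, 60), 20)    # highly coordinated, high s
  low <- matrix(rpois(20 * n_cells, 12), 20)     # independent, low s
  acm <- make_acm(rbind(high, low), rbind(high, low))
  r <- rpkm_normalize(acm)
  rec <- data.frame(gene_id = r$genes$gene_id,
                    category = rep(c("highly_coordinated", "independent"),
                                   each = 20))
  res <- expression_by_category(r, rec)
  expect_lt(res$tests$p, 0.01)
  med <- res$summary$median_rpkm
  names(med) <- res$summary$category
  expect_gt(med["highly_coordinated"], med["independent"])
  # categories below the gene floor are skipped with a warning
  rec2 <- rec
  rec2$category[1:2] <- "semi_coordinated"
  rec2$category[3:22] <- "highly_coordinated"
  expect_warning(expression_by_category(r, rec2), "skipped")
})

test_that("identical category distributions give null p-values over seeds", {
  ps <- vapply(1:20, function(i) {
    set.seed(i)
    vals <- matrix(rpois(40 * 30, 30), 40)
    acm <- make_acm(vals, vals)
    r <- rpkm_normalize(acm)
    rec <- data.frame(gene_id = r$genes$gene_id,
                      category = sample(rep(c("a", "b"), each = 20)))
    expression_by_category(r, rec)$tests$p
  }, numeric(1))
  expect_gt(median(ps), 0.05)
})
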