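# numerically solve the factorial-moment system as an independent oracle:
# Newton iteration on log-parameters with a numerical Jacobian
solve_moments_numeric <- function(m, start) {
  f <- function(p) {
    th <- coburst:::telegraph_theoretical_moments(exp(p[1]), exp(p[2]), exp(p[3]))
    as.numeric(th / m - 1)
  }
  nrm <- function(v) {
    fv <- f(v)
    if (any(!is.finite(fv))) Inf else max(abs(fv))
  }
  x <- log(start)
  for (it in 1:200) {
    if (nrm(x) < 1e-12) break
    J <- pracma::jacobian(f, x)
    dx <- solve(J, -f(x))
    t <- 1
    while (t > 1e-6 && nrm(x + t * dx) >= nrm(x)) t <- t / 2
    if (t <= 1e-6) break
    x <- x + t * dx
  }
  stopifnot(nrm(x) < 1e-10)
  exp(x)
}

test_that("closed-form moment solution solves the system exactly", {
  skip_if_not_installed("pracma")
  set.seed(20)
  for (i in 1:20) {
    kon <- exp(runif(1, log(0.2), log(5)))
    koff <- exp(runif(1, log(0.5), log(20)))
    s <- exp(runif(1, log(5), log(80)))
    m <- coburst:::telegraph_theoretical_moments(kon, koff, s)
    sol <- solve_telegraph_moments(m[1], m[2], m[3])
    expect_true(sol$valid)
    # residual of the forward system at the solution
    m_back <- coburst:::telegraph_theoretical_moments(sol$kon, sol$koff, sol$s)
    expect_lt(max(abs(m_back / m - 1)), 1e-8)
    # agreement with an independent numerical root (perturbed start)
    num <- solve_moments_numeric(m, c(kon, koff, s) * c(1.1, 0.9, 1.05))
    expect_equal(c(sol$kon, sol$koff, sol$s), num, tolerance = 1e-8)
  }
})

test_that("moment solution is scale-equivariant in s", {
  m <- coburst:::telegraph_theoretical_moments(0.8, 4, 25)
  c2 <- 3.7
  scaled <- solve_telegraph_moments(c2 * m[1], c2^2 * m[2], c2^3 * m[3])
  base <- solve_telegraph_moments(m[1], m[2], m[3])
  expect_equal(scaled$kon, base$kon, tolerance = 1e-10)
  expect_equal(scaled$koff, base$koff, tolerance = 1e-10)
  expect_equal(scaled$s, c2 * base$s, tolerance = 1e-10)
})

test_that("degenerate inputs return valid = FALSE, never an error", {
  expect_false(estimate_telegraph(rep(0, 100))$valid)
  expect_identical(estimate_telegraph(rep(0, 100))$reason, "silent")
  expect_false(estimate_telegraph(rep(7, 100))$valid)       # constant counts
  expect_false(estimate_telegraph(rpois(10, 5))$valid)       # too few cells
  expect_identical(estimate_telegraph(rpois(10, 5))$reason, "too_few_cells")
  # Poisson data (no bursting signal) must not yield a spurious solution
  set.seed(30)
  x <- rpois(2000, 10)
  est <- estimate_telegraph(x)
  expect_true(!est$valid || est$kon > 5)  # ~constitutive: huge kon or invalid
  expect_error(estimate_telegraph(c(-1, rpois(99, 5))), "non-negative")
})

test_that("moment estimator recovers telegraph parameters", {
  set.seed(41)
  cases <- expand.grid(kon = c(0.5, 1.5), koff = c(2, 8), s = c(15, 40))
  rel <- t(apply(cases, 1, function(cs) {
    x <- rtelegraph(5000, cs[1], cs[2], cs[3])
    e <- estimate_telegraph(x)
    c(abs(e$kon - cs[1]) / cs[1],
      abs(e$burst_size - cs[3] / cs[2]) / (cs[3] / cs[2]))
  }))
  expect_lt(median(rel[, 1]), 0.2)
  expect_lt(median(rel[, 2]), 0.2)
})

test_that("likelihood refinement stays near the truth and returns valid params", {
  set.seed(55)
  x <- rtelegraph(3000, 1, 3, 20)
  e0 <- estimate_telegraph(x)
  e1 <- estimate_telegraph(x, refine = TRUE)
  expect_true(e1$valid)
  expect_lt(abs(log(e1$kon / 1)), log(2))       # within 2-fold of truth
  expect_lt(abs(log(e1$burst_size / (20 / 3))), log(2))
  expect_equal(e1$burst_size, e1$s / e1$koff)
})

test_that("identical allelic counts give r = 1 and null p-values", {
  set.seed(60)
  G <- 12; n <- 400
  kon <- exp(runif(G, log(0.5), log(2)))
  A <- t(vapply(seq_len(G), function(g) rtelegraph(n, kon[g], 3, 30),
                numeric(n)))
  acm <- make_acm(A, A)
  ak <- allelic_kinetics(acm, B = 200, seed = 1)
  expect_equal(ak$r_frequency$r, 1)
  expect_equal(ak$r_size$r, 1)
  expect_true(all(ak$table$p_freq[!is.na(ak$table$p_freq)] > 0.9))
})

test_that("shared-kinetics simulation shows strong allelic correlation", {
  cfg <- simulation_config(n_genes = 300, n_cells = 2000, phi = 0.5,
                           emission = "beta", seed = 71)
  sim <- simulate_counts(cfg)
  ak <- allelic_kinetics(sim$matrix, B = 0, seed = 1)
  expect_gt(ak$r_frequency$r, 0.6)
  expect_gt(ak$r_size$r, 0.6)
})

test_that("bootstrap flags genes with true allelic kinetic differences", {
  cfg <- simulation_config(n_genes = 120, n_cells = 1000, phi = 0.5,
                           emission = "beta", diff_frac = 0.1, kon_fold = 4,
                           seed = 81)
  sim <- simulate_counts(cfg)
  ak <- allelic_kinetics(sim$matrix, B = 1000, seed = 82)
  tab <- merge(ak$table, sim$truth[, c("gene_id", "allelic_diff")])
  sig <- !is.na(tab$q_freq) & tab$q_freq < 0.05
  expect_gte(mean(sig[tab$allelic_diff]), 0.5)          # power
  expect_lte(mean(sig[!tab$allelic_diff]), 0.1)         # specificity
})

test_that("pearson_r matches hand-computed and boundary cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3))$r, 0.6)
  expect_true(is.na(pearson_r(x, rep(1, 4))$r))          # zero variance
  expect_true(is.na(pearson_r(1:2, 2:1)$r))              # too few pairs
})
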