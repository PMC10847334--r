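#' Factorial moments of a count sample
#'
#' First three sample factorial moments `E[X]`, `E[X(X-1)]`,
#' `E[X(X-1)(X-2)]`. Real-valued (SNP-averaged) counts are accepted; the
#' factorial products are computed on the values as given.
#'
#' @param x numeric vector of non-negative counts.
#' @return numeric `c(m1, m2, m3)`.
#' @export
factorial_moments <- function(x) {
  c(m1 = mean(x),
    m2 = mean(x * (x - 1)),
    m3 = mean(x * (x - 1) * (x - 2)))
}

#' Solve the telegraph three-moment system
#'
#' For the Poisson-Beta stationary law of the two-state promoter model
#' (decay rate d = 1) the factorial moments are
#' `f_k = s^k * prod_{j<k} (kon + j) / (kon + koff + j)`. With
#' `u1 = f1`, `u2 = f2/f1`, `u3 = f3/f2` the system inverts in closed form:
#' \deqn{s = (2 u1 u3 - u1 u2 - u2 u3) / (u1 - 2 u2 + u3)}
#' \deqn{kon = 2 u1 (u3 - u2) / (u1 u2 - 2 u1 u3 + u2 u3)}
#' \deqn{koff = 2 (u2 - u1)(u1 - u3)(u3 - u2) /
#'   ((u1 u2 - 2 u1 u3 + u2 u3)(u1 - 2 u2 + u3))}
#' Moment triples admitting no positive finite solution (negative or
#' degenerate roots, vanishing denominators) are reported invalid rather
#' than clipped — silent clipping would corrupt downstream allelic
#' correlations.
#'
#' @param m1,m2,m3 factorial moments (vectorised).
#' @return data.frame with columns `kon`, `koff`, `s`, `valid`, `reason`.
#' @export
solve_telegraph_moments <- function(m1, m2, m3) {
  n <- max(length(m1), length(m2), length(m3))
  m1 <- rep_len(m1, n); m2 <- rep_len(m2, n); m3 <- rep_len(m3, n)
  kon <- koff <- s <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  bad_m <- !is.finite(m1) | !is.finite(m2) | !is.finite(m3) |
    m1 <= 0 | m2 <= 0 | m3 <= 0
  reason[bad_m] <- "nonpositive_moments"

  u1 <- m1
  u2 <- ifelse(bad_m, NA, m2 / m1)
  u3 <- ifelse(bad_m, NA, m3 / m2)
  den_s <- u1 - 2 * u2 + u3
  den_k <- u1 * u2 - 2 * u1 * u3 + u2 * u3
  degen <- !bad_m & (abs(den_s) < 1e-12 | abs(den_k) < 1e-12)
  reason[degen] <- "degenerate_moments"

  ok <- !bad_m & !degen
  s[ok] <- (2 * u1[ok] * u3[ok] - u1[ok] * u2[ok] - u2[ok] * u3[ok]) / den_s[ok]
  kon[ok] <- 2 * u1[ok] * (u3[ok] - u2[ok]) / den_k[ok]
  koff[ok] <- 2 * (u2[ok] - u1[ok]) * (u1[ok] - u3[ok]) * (u3[ok] - u2[ok]) /
    (den_k[ok] * den_s[ok])

  pos <- ok & is.finite(kon) & is.finite(koff) & is.finite(s) &
    kon > 0 & koff > 0 & s > 0
  reason[ok & !pos] <- "no_positive_solution"
  kon[!pos] <- NA_real_; koff[!pos] <- NA_real_; s[!pos] <- NA_real_
  data.frame(kon = kon, koff = koff, s = s, valid = pos,
             reason = ifelse(pos, "", reason), stringsAsFactors = FALSE)
}

# theoretical factorial moments of the Poisson-Beta law; used by tests and
# by the scale-equivariance checks
telegraph_theoretical_moments <- function(kon, koff, s) {
  ab <- kon + koff
  c(m1 = s * kon / ab,
    m2 = s^2 * kon * (kon + 1) / (ab * (ab + 1)),
    m3 = s^3 * kon * (kon + 1) * (kon + 2) / (ab * (ab + 1) * (ab + 2)))
}

#' Estimate telegraph-model parameters from one allele's counts
#'
#' Method-of-moments estimator for the two-state promoter model: the first
#' three sample factorial moments are matched to the Poisson-Beta
#' stationary law (decay rate d = 1, so kon and koff are per mean mRNA
#' lifetime), giving burst frequency `kon` and burst size `s/koff` in
#' closed form via [solve_telegraph_moments()]. Optionally the moment
#' solution seeds a maximum-likelihood refinement of the Poisson-Beta
#' likelihood (Gauss-Legendre quadrature in the Beta quantile domain;
#' counts are rounded to integers for the likelihood).
#'
#' The estimator never raises on pathological input: silent genes,
#' degenerate moments (e.g. constant counts in the constitutive regime) or
#' moment systems without a positive root return `valid = FALSE` with a
#' reason.
#'
#' @param counts per-cell counts of one allele (real-valued accepted).
#' @param min_cells minimum number of cells (default 50).
#' @param refine logical; run the likelihood refinement (default FALSE).
#' @return object of class `telegraph_params`: list with `kon`, `koff`,
#'   `s`, `burst_frequency` (= kon), `burst_size` (= s/koff), `valid`,
#'   `reason`, `n`.
#' @export
estimate_telegraph <- function(counts, min_cells = 50, refine = FALSE) {
  n <- length(counts)
  invalid <- function(reason)
    structure(list(kon = NA_real_, koff = NA_real_, s = NA_real_,
                   burst_frequency = NA_real_, burst_size = NA_real_,
                   valid = FALSE, reason = reason, n = n),
              class = "telegraph_params")
  if (n < min_cells) return(invalid("too_few_cells"))
  if (anyNA(counts) || any(counts < 0)) stop_config("counts must be non-negative")
  if (all(counts == 0)) return(invalid("silent"))
  if (stats::var(counts) == 0) return(invalid("degenerate_moments"))

  m <- factorial_moments(counts)
  sol <- solve_telegraph_moments(m[1], m[2], m[3])
  if (!sol$valid) return(invalid(sol$reason))
  kon <- sol$kon; koff <- sol$koff; s <- sol$s
  if (refine) {
    ref <- refine_telegraph_ml(round(counts), kon, koff, s)
    kon <- ref[1]; koff <- ref[2]; s <- ref[3]
  }
  structure(list(kon = kon, koff = koff, s = s,
                 burst_frequency = kon, burst_size = s / koff,
                 valid = TRUE, reason = "", n = n),
            class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("telegraph_params: invalid (%s), n = %d\n", x$reason, x$n))
  } else {
    cat(sprintf(
      "telegraph_params: kon = %.3g, koff = %.3g, s = %.3g (burst size %.3g), n = %d\n",
      x$kon, x$koff, x$s, x$burst_size, x$n))
  }
  invisible(x)
}

# Gauss-Legendre nodes/weights on (0,1) by Golub-Welsch
gauss_legendre_01 <- function(k = 64) {
  i <- seq_len(k - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, k); J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- (e$values + 1) / 2
  weights <- (e$vectors[1, ]^2) / 2 * 2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

# Poisson-Beta log-likelihood via quadrature on u with t = qbeta(u, a, b):
# P(x) = int dpois(x, s * qbeta(u, a, b)) du, which is smooth in u even for
# shape parameters < 1.
poisson_beta_loglik <- function(x, kon, koff, s, gl = gauss_legendre_01()) {
  t <- stats::qbeta(gl$nodes, kon, koff)
  tab <- table(x)
  xs <- as.numeric(names(tab))
  px <- vapply(xs, function(xi)
    sum(gl$weights * stats::dpois(xi, s * t)), numeric(1))
  px <- pmax(px, 1e-300)
  sum(as.integer(tab) * log(px))
}

refine_telegraph_ml <- function(x, kon, koff, s) {
  gl <- gauss_legendre_01()
  fit <- try(stats::optim(log(c(kon, koff, s)), function(p) {
    -poisson_beta_loglik(x, exp(p[1]), exp(p[2]), exp(p[3]), gl)
  }, method = "Nelder-Mead"), silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0)
    return(c(kon, koff, s))
  exp(fit$par)
}

#' Per-allele burst kinetics with a bootstrap test for allelic differences
#'
#' Estimates telegraph parameters for both alleles of every (bursty) gene,
#' reports the across-gene Pearson correlation of allelic log burst
#' frequency and log burst size, and tests per-gene allelic differences by
#' a cell bootstrap: cells are resampled with replacement (the same
#' resample for both alleles), both alleles are re-estimated, and a
#' two-sided percentile test asks whether the bootstrap distribution of
#' `log(kon_A) - log(kon_B)` (resp. log burst size) straddles zero.
#' P-values are Benjamini-Hochberg adjusted across genes per statistic.
#'
#' @param matrix an [allelic_count_matrix()].
#' @param genes gene ids (or indices) to analyse, typically the biallelic
#'   bursty genes; default all genes.
#' @param B bootstrap replicates (default 1000; `B = 0` skips testing).
#' @param min_cells minimum cells for estimation (default 50).
#' @param min_valid_boot minimum valid bootstrap replicates for a p-value
#'   (default 50); below it the p-value is `NA`.
#' @param seed integer seed for the bootstrap resamples.
#' @return list of class `allelic_kinetics`: `table` (per gene: kinetics of
#'   both alleles, `p_freq`, `q_freq`, `p_size`, `q_size`),
#'   `r_frequency`, `r_size` (Pearson r between alleles over genes valid on
#'   both, `NA` when fewer than 3), `n_valid`.
#' @export
allelic_kinetics <- function(matrix, genes = NULL, B = 1000, min_cells = 50,
                             min_valid_boot = 50, seed = 1L) {
  stopifnot(inherits(matrix, "allelic_count_matrix"))
  if (is.null(genes)) genes <- matrix$genes$gene_id
  if (is.numeric(genes)) genes <- matrix$genes$gene_id[genes]
  idx <- match(genes, matrix$genes$gene_id)
  if (anyNA(idx)) stop_config("unknown gene id(s)")
  n <- ncol(matrix$counts_A)

  est <- function(x) estimate_telegraph(x, min_cells = min_cells)
  res <- withr::with_seed(as.integer(seed), {
    lapply(idx, function(g) {
      xA <- matrix$counts_A[g, ]
      xB <- matrix$counts_B[g, ]
      eA <- est(xA); eB <- est(xB)
      p_freq <- p_size <- NA_real_
      if (B > 0 && eA$valid && eB$valid) {
        bi <- base::matrix(sample.int(n, n * B, replace = TRUE), n, B)
        bootA <- boot_moments_solve(xA, bi)
        bootB <- boot_moments_solve(xB, bi)
        okb <- bootA$valid & bootB$valid
        if (sum(okb) >= min_valid_boot) {
          dfreq <- log(bootA$kon[okb]) - log(bootB$kon[okb])
          dsize <- log(bootA$s[okb] / bootA$koff[okb]) -
            log(bootB$s[okb] / bootB$koff[okb])
          p_freq <- percentile_p(dfreq)
          p_size <- percentile_p(dsize)
        }
      }
      data.frame(gene_id = matrix$genes$gene_id[g],
                 kon_A = eA$kon, koff_A = eA$koff, s_A = eA$s,
                 size_A = eA$burst_size, valid_A = eA$valid,
                 kon_B = eB$kon, koff_B = eB$koff, s_B = eB$s,
                 size_B = eB$burst_size, valid_B = eB$valid,
                 p_freq = p_freq, p_size = p_size,
                 stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, res)
  tab$q_freq <- stats::p.adjust(tab$p_freq, method = "BH")
  tab$q_size <- stats::p.adjust(tab$p_size, method = "BH")
  both <- tab$valid_A & tab$valid_B
  r_frequency <- r_size <- list(r = NA_real_, p = NA_real_)
  if (sum(both) >= 3) {
    r_frequency <- pearson_r(log(tab$kon_A[both]), log(tab$kon_B[both]))
    r_size <- pearson_r(log(tab$size_A[both]), log(tab$size_B[both]))
  }
  structure(list(table = tab, r_frequency = r_frequency, r_size = r_size,
                 n_valid = sum(both)),
            class = "allelic_kinetics")
}

#' @export
print.allelic_kinetics <- function(x, ...) {
  cat(sprintf("allelic_kinetics: %d genes (%d valid on both alleles)\n",
              nrow(x$table), x$n_valid))
  cat(sprintf("  allelic correlation: burst frequency r = %.3f, burst size r = %.3f\n",
              x$r_frequency$r, x$r_size$r))
  invisible(x)
}

# moment estimates over bootstrap resamples given an n x B index matrix
boot_moments_solve <- function(x, idx) {
  M <- base::matrix(x[idx], nrow(idx), ncol(idx))
  solve_telegraph_moments(colMeans(M),
                          colMeans(M * (M - 1)),
                          colMeans(M * (M - 1) * (M - 2)))
}

# two-sided percentile bootstrap p-value for H0: delta = 0, with add-one
# smoothing so p is never exactly 0
percentile_p <- function(delta) {
  Bn <- length(delta)
  p <- 2 * min((sum(delta <= 0) + 1) / (Bn + 1),
               (sum(delta >= 0) + 1) / (Bn + 1))
  min(p, 1)
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] returning `NA` (not an error)
#' for degenerate input.
#'
#' @param x,y paired numeric vectors.
#' @return list `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
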