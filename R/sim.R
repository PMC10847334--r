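#' Simulation configuration for the coupled two-allele telegraph model
#'
#' Defines the ground-truth conditions of a synthetic allele-specific
#' scRNA-seq experiment. Each gene carries telegraph kinetics (activation
#' rate `kon`, inactivation rate `koff`, transcription rate `s`, all per mean
#' mRNA lifetime, i.e. the decay rate d is the time unit). The coupling
#' parameter `phi` sets the probability that the two alleles of a gene share
#' one promoter ON/OFF state in a given cell; `phi = 1` is perfectly
#' coordinated bursting, `phi = 0` fully independent bursting.
#'
#' @param n_genes,n_cells number of autosomal genes and cells.
#' @param kon_range,koff_range,s_range positive rate ranges; per-gene values
#'   are drawn log-uniformly (rates span orders of magnitude). A degenerate
#'   range `c(x, x)` fixes the value.
#' @param phi allelic coupling probability in `[0, 1]`.
#' @param q_range optional range for the per-allele snapshot OFF probability
#'   q = koff/(kon+koff). When given, q is drawn uniformly, `kon` is drawn
#'   from `kon_range` and `koff` is derived as `kon * q / (1 - q)`,
#'   overriding `koff_range`. Useful for placing genes at controlled
#'   positions on the p0/p2 plane.
#' @param emission `"bernoulli"` (default): a snapshot ON allele emits
#'   Poisson(s) molecules, an OFF allele emits 0. This binary-occupancy
#'   snapshot is the slow-switching limit of the telegraph model and keeps
#'   the p0/p2 geometry analytically exact. `"beta"`: the allele's burst
#'   occupancy tau is drawn from the stationary Beta(kon, koff) law and the
#'   count is Poisson(s * tau) — the full Poisson-Beta telegraph stationary
#'   distribution, used for kinetics-recovery studies.
#' @param depth_mean mean sequencing reads per molecule at a SNP site in
#'   [split_to_snp_reads()]; `Inf` disables sequencing noise.
#' @param n_snps_range integer range for the number of informative SNP sites
#'   per gene.
#' @param dropout_rate probability in `[0, 1)` that a low-count
#'   (gene, cell, allele) entry (total reads `<= dropout_max_reads`) is
#'   zeroed at the SNP-read stage, emulating capture dropout.
#' @param dropout_max_reads read-count ceiling defining "low-count" entries
#'   eligible for dropout.
#' @param n_xlinked number of additional X-linked fixture genes with the
#'   129S1 allele (allele A) silenced in every cell, mimicking the inactive
#'   129S1 X chromosome of the hybrid MEFs.
#' @param diff_frac fraction of genes given allele-specific kinetics, for
#'   testing the allelic-difference bootstrap; allele B of those genes has
#'   `kon * kon_fold` and `s * s_fold`.
#' @param kon_fold,s_fold fold-changes applied to allele B of the
#'   `diff_frac` genes.
#' @param gene_length_range bp range for simulated gene lengths
#'   (log-uniform).
#' @param stage stage label stamped on every simulated cell.
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output. All draws flow from one generator in documented order (see
#'   [simulate_counts()]).
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200, n_cells = 500,
                              kon_range = c(0.3, 3),
                              koff_range = c(1, 10),
                              s_range = c(10, 50),
                              phi = 0.5,
                              q_range = NULL,
                              emission = c("bernoulli", "beta"),
                              depth_mean = 1,
                              n_snps_range = c(2L, 6L),
                              dropout_rate = 0,
                              dropout_max_reads = 5,
                              n_xlinked = 0L,
                              diff_frac = 0,
                              kon_fold = 1,
                              s_fold = 1,
                              gene_length_range = c(1000, 50000),
                              stage = "stage1",
                              seed = 1L) {
  emission <- match.arg(emission)
  if (!is.numeric(n_genes) || n_genes < 1) stop_config("n_genes must be >= 1")
  if (!is.numeric(n_cells) || n_cells < 1) stop_config("n_cells must be >= 1")
  check_positive_range(kon_range, "kon_range")
  check_positive_range(koff_range, "koff_range")
  check_positive_range(s_range, "s_range")
  check_fraction(phi, "phi")
  if (!is.null(q_range)) {
    if (q_range[1] <= 0 || q_range[2] >= 1 || q_range[1] > q_range[2])
      stop_config("q_range must lie strictly inside (0,1) with lower <= upper")
  }
  if (!is.numeric(depth_mean) || depth_mean <= 0)
    stop_config("depth_mean must be positive (possibly Inf)")
  if (n_snps_range[1] < 1 || n_snps_range[1] > n_snps_range[2])
    stop_config("n_snps_range must be a pair of counts >= 1 with lower <= upper")
  check_fraction(dropout_rate, "dropout_rate", open_upper = TRUE)
  check_fraction(diff_frac, "diff_frac")
  if (kon_fold <= 0 || s_fold <= 0) stop_config("fold-changes must be positive")
  check_positive_range(gene_length_range, "gene_length_range")

  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 kon_range = kon_range, koff_range = koff_range,
                 s_range = s_range, phi = phi, q_range = q_range,
                 emission = emission, depth_mean = depth_mean,
                 n_snps_range = as.integer(n_snps_range),
                 dropout_rate = dropout_rate,
                 dropout_max_reads = dropout_max_reads,
                 n_xlinked = as.integer(n_xlinked),
                 diff_frac = diff_frac, kon_fold = kon_fold, s_fold = s_fold,
                 gene_length_range = gene_length_range,
                 stage = stage, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d genes x %d cells, phi = %.2f, ",
                     "emission = %s, seed = %d\n"),
              x$n_genes, x$n_cells, x$phi, x$emission, x$seed))
  invisible(x)
}

# Joint snapshot probabilities for two alleles with OFF probabilities qA, qB
# coupled comonotonically (shared uniform) with probability phi.
# pa/pb are ON probabilities. Emission-zero terms use eA = P(count 0 | ON).
snapshot_expectations <- function(qA, qB, phi, eA, eB) {
  pa <- 1 - qA; pb <- 1 - qB
  p0_state <- phi * pmin(qA, qB) + (1 - phi) * qA * qB
  p2_state <- phi * pmin(pa, pb) + (1 - phi) * pa * pb
  zA <- qA + pa * eA                       # marginal P(observed 0)
  zB <- qB + pb * eB
  p0_sh <- pmin(qA, qB) + pmax(0, pb - pa) * eB + pmax(0, pa - pb) * eA +
    pmin(pa, pb) * eA * eB
  p2_sh <- pmin(pa, pb) * (1 - eA) * (1 - eB)
  list(p0_state = p0_state, p2_state = p2_state,
       p0_obs = phi * p0_sh + (1 - phi) * zA * zB,
       p2_obs = phi * p2_sh + (1 - phi) * (1 - zA) * (1 - zB))
}

#' Simulate allele-specific counts from a coupled two-allele telegraph model
#'
#' Draws per-gene kinetics from the configured ranges, then for every cell
#' realises the two alleles' promoter states: with probability `phi` the
#' alleles share one state draw (coupled bursting), otherwise each allele
#' draws independently. Coupling is comonotone — both alleles consume the
#' same uniform variate — so it degrades gracefully when the alleles'
#' kinetics differ. ON alleles emit `Poisson(s)` molecules under the default
#' Bernoulli-snapshot emission, or `Poisson(s * tau)` with
#' `tau ~ Beta(kon, koff)` under `emission = "beta"`.
#'
#' Draw order under the single seed: (1) per-gene q (if `q_range` set),
#' (2) kon, (3) koff, (4) s, (5) gene lengths, (6) allelic-difference gene
#' subset, (7) X-linked placement, (8) the three gene-x-cell uniform fields
#' (shared / allele A / allele B) plus the coupling indicator, (9) Poisson
#' emission for allele A then allele B.
#'
#' @param config a [simulation_config()].
#' @return A list of class `coburst_sim` with elements `matrix` (an
#'   [allelic_count_matrix()]; X-linked fixture genes carry
#'   `genes$xlinked = TRUE`) and `truth` (a data.frame of per-gene ground
#'   truth: kinetics of both alleles, `phi`, snapshot OFF probability `q`,
#'   and the expected p0/p2 both at promoter-state level and at observation
#'   level, i.e. after Poisson emission zeros; observation-level columns are
#'   `NA` for beta emission where no closed form is stored).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(config) {
  G <- config$n_genes + config$n_xlinked
  N <- config$n_cells
  gene_ids <- sprintf("gene_%04d", seq_len(G))
  cell_ids <- sprintf("cell_%04d", seq_len(N))

  if (!is.null(config$q_range)) {
    q <- stats::runif(G, config$q_range[1], config$q_range[2])
    kon <- runif_log(G, config$kon_range)
    koff <- kon * q / (1 - q)
  } else {
    kon <- runif_log(G, config$kon_range)
    koff <- runif_log(G, config$koff_range)
  }
  s <- runif_log(G, config$s_range)
  gene_length <- round(runif_log(G, config$gene_length_range))

  # allele-specific kinetics for a subset of genes (bootstrap test substrate)
  n_diff <- round(config$diff_frac * config$n_genes)
  diff_genes <- rep(FALSE, G)
  if (n_diff > 0)
    diff_genes[sample.int(config$n_genes, n_diff)] <- TRUE
  kon_B <- ifelse(diff_genes, kon * config$kon_fold, kon)
  s_B <- ifelse(diff_genes, s * config$s_fold, s)
  koff_B <- koff

  xlinked <- c(rep(FALSE, config$n_genes), rep(TRUE, config$n_xlinked))

  qA <- koff / (kon + koff)
  qB <- koff_B / (kon_B + koff_B)
  phi <- config$phi

  share <- matrix(stats::runif(G * N) < phi, G, N)
  u_sh <- matrix(stats::runif(G * N), G, N)
  u_a <- matrix(stats::runif(G * N), G, N)
  u_b <- matrix(stats::runif(G * N), G, N)
  uA <- ifelse(share, u_sh, u_a)
  uB <- ifelse(share, u_sh, u_b)

  if (config$emission == "bernoulli") {
    tauA <- (uA < (1 - qA)) * 1          # recycled down columns: rows = genes
    tauB <- (uB < (1 - qB)) * 1
  } else {
    tauA <- matrix(stats::qbeta(uA, kon, koff), G, N)
    tauB <- matrix(stats::qbeta(uB, kon_B, koff_B), G, N)
  }
  counts_A <- matrix(stats::rpois(G * N, lambda = s * tauA), G, N)
  counts_B <- matrix(stats::rpois(G * N, lambda = s_B * tauB), G, N)
  counts_A[xlinked, ] <- 0

  # synthetic annotation: one chromosome, genes laid out with 10 kb gaps
  gap <- 10000L
  start <- cumsum(c(gap, gene_length[-G] + gap))
  genes <- data.frame(gene_id = gene_ids,
                      gene_length = gene_length,
                      chrom = ifelse(xlinked, "chrX", "chr1"),
                      start = start,
                      end = start + gene_length,
                      strand = rep_len(c("+", "-"), G),
                      xlinked = xlinked,
                      stringsAsFactors = FALSE)
  dimnames(counts_A) <- dimnames(counts_B) <- list(gene_ids, cell_ids)
  cells <- data.frame(cell_id = cell_ids,
                      total_reads = colSums(counts_A) + colSums(counts_B),
                      stage = config$stage,
                      stringsAsFactors = FALSE)

  if (config$emission == "bernoulli") {
    ex <- snapshot_expectations(qA, qB, phi, exp(-s), exp(-s_B))
  } else {
    ex <- snapshot_expectations(qA, qB, phi, NA_real_, NA_real_)
  }
  truth <- data.frame(gene_id = gene_ids,
                      kon_A = kon, koff_A = koff, s_A = s,
                      kon_B = kon_B, koff_B = koff_B, s_B = s_B,
                      phi = phi, q = qA,
                      expected_p0_state = ex$p0_state,
                      expected_p2_state = ex$p2_state,
                      expected_p0 = ex$p0_obs,
                      expected_p2 = ex$p2_obs,
                      allelic_diff = diff_genes,
                      xlinked = xlinked,
                      stringsAsFactors = FALSE)

  structure(list(matrix = allelic_count_matrix(counts_A, counts_B, genes, cells),
                 truth = truth),
            class = "coburst_sim")
}

#' @export
print.coburst_sim <- function(x, ...) {
  cat("coburst_sim\n")
  print(x$matrix)
  cat(sprintf("  ground truth for %d genes (phi = %.2f)\n",
              nrow(x$truth), x$truth$phi[1]))
  invisible(x)
}

#' Sample from the telegraph (Poisson-Beta) stationary distribution
#'
#' Stationary snapshot counts of the two-state promoter model with decay
#' rate d = 1: the burst occupancy is `Beta(kon, koff)` and the count is
#' conditionally `Poisson(s * occupancy)`.
#'
#' @param n number of cells to draw.
#' @param kon,koff,s telegraph rates (per mean mRNA lifetime).
#' @return integer vector of counts.
#' @export
rtelegraph <- function(n, kon, koff, s) {
  if (any(c(kon, koff, s) <= 0) || any(!is.finite(c(kon, koff, s))))
    stop_config("telegraph rates must be positive and finite")
  stats::rpois(n, lambda = s * stats::rbeta(n, kon, koff))
}

#' Split gene-level allelic counts into SNP-level read tables
#'
#' Emulates the SNP counting substrate of allele-specific pipelines: each
#' gene receives `n_snps` informative SNP positions within its body; each
#' cell's per-allele molecule count is partitioned over those positions
#' multinomially (every read covers one SNP site, so SNP reads sum to the
#' gene count); finite `depth_mean` then replaces each SNP read mass `m` by
#' `Poisson(m * depth_mean)` sequencing noise, and `dropout_rate` zeroes a
#' random subset of low-count (gene, cell, allele) entries.
#'
#' @param matrix an [allelic_count_matrix()] from [simulate_counts()].
#' @param config the [simulation_config()]; `n_snps_range`, `depth_mean`,
#'   `dropout_rate` and `dropout_max_reads` are consumed here. Draws use
#'   `seed + 1` so the SNP split is independent of, but reproducible with,
#'   the count simulation.
#' @return data.frame SNP read table with columns `gene_id`, `chrom`, `pos`
#'   (0-based), `cell_id`, `reads_A`, `reads_B`. Rows where both alleles
#'   have zero reads are omitted.
#' @export
split_to_snp_reads <- function(matrix, config) {
  stopifnot(inherits(matrix, "allelic_count_matrix"),
            inherits(config, "simulation_config"))
  if (config$n_snps_range[1] < 1) stop_config("n_snps must be >= 1")
  withr::with_seed(config$seed + 1L, split_to_snp_reads_impl(matrix, config))
}

split_to_snp_reads_impl <- function(matrix, config) {
  G <- nrow(matrix$counts_A)
  N <- ncol(matrix$counts_A)
  gene_ids <- rownames(matrix$counts_A)
  cell_ids <- colnames(matrix$counts_A)
  ann <- matrix$genes

  res <- vector("list", G)
  for (g in seq_len(G)) {
    k <- if (config$n_snps_range[1] == config$n_snps_range[2])
      config$n_snps_range[1]
    else sample(seq(config$n_snps_range[1], config$n_snps_range[2]), 1L)
    glen <- ann$gene_length[g] %||% 1000L
    gstart <- ann$start[g] %||% 0L
    pos <- gstart + sort(sample.int(glen, k))
    cA <- round(matrix$counts_A[g, ])
    cB <- round(matrix$counts_B[g, ])
    splitA <- multinomial_split(cA, k)     # k x N
    splitB <- multinomial_split(cB, k)
    if (is.finite(config$depth_mean)) {
      splitA[] <- stats::rpois(length(splitA), splitA * config$depth_mean)
      splitB[] <- stats::rpois(length(splitB), splitB * config$depth_mean)
    }
    if (config$dropout_rate > 0) {
      totA <- colSums(splitA); totB <- colSums(splitB)
      dropA <- totA > 0 & totA <= config$dropout_max_reads &
        stats::runif(N) < config$dropout_rate
      dropB <- totB > 0 & totB <= config$dropout_max_reads &
        stats::runif(N) < config$dropout_rate
      splitA[, dropA] <- 0
      splitB[, dropB] <- 0
    }
    keep <- splitA + splitB > 0
    if (!any(keep)) next
    idx <- which(keep, arr.ind = TRUE)
    res[[g]] <- data.frame(gene_id = gene_ids[g],
                           chrom = ann$chrom[g] %||% "chr1",
                           pos = pos[idx[, 1]],
                           cell_id = cell_ids[idx[, 2]],
                           reads_A = splitA[keep],
                           reads_B = splitB[keep],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), cell_id = character(0),
                      reads_A = integer(0), reads_B = integer(0))
  rownames(out) <- NULL
  out
}

# distribute each column total over k categories multinomially; returns k x N
multinomial_split <- function(counts, k) {
  N <- length(counts)
  out <- base::matrix(0L, k, N)
  pos <- which(counts > 0)
  for (j in pos)
    out[, j] <- stats::rmultinom(1L, counts[j], rep.int(1 / k, k))
  out
}

#' Simulate per-allele coverage tracks with controlled enrichment
#'
#' Builds bedGraph-style per-allele coverage with mean signal
#' `enrichment_A` (resp. `enrichment_B`) over gene bodies in fixed-width
#' bins, zero background outside, and Gaussian noise truncated at zero —
#' the test substrate for allelic metagene enrichment profiling.
#'
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`); gene bodies plus flanks must not overlap.
#' @param enrichment_A,enrichment_B non-negative mean signal over gene
#'   bodies for the two alleles.
#' @param noise_sd standard deviation of the per-bin Gaussian noise.
#' @param seed integer seed.
#' @param bin_bp bin width of the generated track.
#' @return list with elements `A` and `B`, each a `coverage_track`
#'   data.frame (`chrom`, `start`, `end`, `value`; 0-based half-open).
#' @export
simulate_coverage <- function(genes, enrichment_A, enrichment_B,
                              noise_sd = 0, seed = 1L, bin_bp = 100L) {
  if (enrichment_A < 0 || enrichment_B < 0)
    stop_config("enrichment levels must be non-negative")
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  withr::with_seed(as.integer(seed), {
    one <- function(level) {
      parts <- lapply(seq_len(nrow(genes)), function(i) {
        br <- seq(genes$start[i], genes$end[i], by = bin_bp)
        if (br[length(br)] < genes$end[i]) br <- c(br, genes$end[i])
        nb <- length(br) - 1L
        val <- level + if (noise_sd > 0) stats::rnorm(nb, 0, noise_sd) else 0
        data.frame(chrom = genes$chrom[i], start = br[-length(br)],
                   end = br[-1], value = pmax(0, val),
                   stringsAsFactors = FALSE)
      })
      tr <- do.call(rbind, parts)
      tr <- tr[order(tr$chrom, tr$start), ]
      rownames(tr) <- NULL
      class(tr) <- c("coverage_track", "data.frame")
      tr
    }
    list(A = one(enrichment_A), B = one(enrichment_B))
  })
}
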