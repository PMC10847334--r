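#!/usr/bin/env Rscript
# Build the synthetic two-stage cohort used throughout the analysis:
# an MEF-like stage with strongly coupled allelic bursting and an iPSC-like
# stage with weaker coupling, plus X-linked fixture genes (129S1 allele
# silenced) and per-allele coverage tracks. Everything downstream
# (02..06) consumes the TSV/bedGraph files written here.

suppressPackageStartupMessages(library(coburst))
outdir <- "results/analysis/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# emission = "beta": counts follow the full Poisson-Beta telegraph
# stationary law, so the kinetics stage estimates against realistic data
stages <- list(
  mef  = simulation_config(n_genes = 300, n_cells = 500, phi = 0.85,
                           kon_range = c(0.5, 2), koff_range = c(1, 5),
                           s_range = c(15, 60), emission = "beta",
                           n_snps_range = c(2, 5),
                           depth_mean = 2, n_xlinked = 10,
                           stage = "mef", seed = 2001),
  ipsc = simulation_config(n_genes = 300, n_cells = 500, phi = 0.35,
                           kon_range = c(0.5, 2), koff_range = c(1, 5),
                           s_range = c(15, 60), emission = "beta",
                           n_snps_range = c(2, 5),
                           depth_mean = 2, n_xlinked = 10,
                           stage = "ipsc", seed = 2002))

for (st in names(stages)) {
  sim <- simulate_counts(stages[[st]])
  tab <- split_to_snp_reads(sim$matrix, stages[[st]])
  write_snp_table(tab, file.path(outdir, sprintf("%s.snp_reads.tsv", st)))
  write_allelic_counts(sim$matrix, file.path(outdir, sprintf("%s.counts", st)))
  coburst:::write_tsv_file(sim$truth,
                           file.path(outdir, sprintf("%s.truth.tsv", st)))
  write_gene_annotation(sim$matrix$genes,
                        file.path(outdir, sprintf("%s.genes.bed", st)))
  cat(sprintf("%s: %d genes x %d cells, %d SNP-read rows, phi = %.2f\n",
              st, nrow(sim$matrix$counts_A), ncol(sim$matrix$counts_A),
              nrow(tab), stages[[st]]$phi))
}

cat("wrote cohort under", outdir, "\n")
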