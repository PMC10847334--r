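---
title: "Allelic transcriptional bursting: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic transcriptional bursting: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coburst)
```

# The scientific problem

In an F1 hybrid cell (here the 129S1 × CAST mouse cross), strain-specific
SNPs let single-cell RNA-seq reads be assigned to the maternal or paternal
allele, so transcription can be observed one allele at a time. Most genes
transcribe in bursts: the promoter flips stochastically between an OFF and
an ON state, and mRNA is only made while ON. Because each allele has its own
promoter, the two alleles of a gene may burst in synchrony or independently;
asynchronous bursting is what produces dynamic autosomal random monoallelic
expression (aRME), where a cell transiently detects only one allele of an
autosomal gene.

`coburst` implements the full analysis path from SNP-level allelic read
counts to (i) gene expression classes and bursty/constitutive calls,
(ii) per-allele telegraph-model burst kinetics, (iii) the p0/p2 coordination
statistic that classifies genes as highly coordinated, semi-coordinated or
independent, and (iv) allelic metagene enrichment profiles — together with a
coupled two-allele simulator that provides ground truth for every stage.

# The telegraph model and its time unit

Each allele follows the two-state ("telegraph") model: activation rate
$K_{on}$, inactivation rate $K_{off}$, transcription rate $S$ while active,
mRNA decay rate $d$. Burst frequency is $K_{on}$ (bursts per unit time) and
burst size is $S/K_{off}$ (mean mRNA made per burst). Snapshot counts only
identify the rates up to the decay rate, so throughout the package $d
\equiv 1$: all rates are per mean mRNA lifetime. The stationary snapshot
distribution is Poisson–Beta: the burst occupancy is $\tau \sim
\mathrm{Beta}(K_{on}, K_{off})$ and the count is Poisson$(S\tau)$
(`rtelegraph()` samples it directly).

# The coupled two-allele simulator

`simulate_counts()` draws per-gene kinetics log-uniformly from configured
ranges (rates span orders of magnitude, so a log-uniform prior spreads genes
evenly in log-parameter space) and realises, per cell, the two alleles'
promoter states with a coupling probability $\phi$: with probability $\phi$
both alleles consume a single shared uniform variate (comonotone coupling —
identical states when the alleles share kinetics, graceful degradation when
they do not), otherwise each allele draws independently. $\phi$ is a
simulator abstraction — a single knob that interpolates between fully
independent ($\phi = 0$) and perfectly coordinated ($\phi = 1$) allelic
bursting; it is not a mechanistic parameter of the telegraph model.

Two emission modes are provided:

* **`"bernoulli"` (default).** The snapshot promoter state is binary
  (OFF with probability $q = K_{off}/(K_{on}+K_{off})$) and an ON allele
  emits Poisson$(S)$. This is the slow-switching limit of the telegraph
  model. It keeps the p0/p2 geometry analytically exact, which is what the
  coordination-geometry validations need: at the state level
  $p_0 = \phi q + (1-\phi)q^2$ and $p_2 = \phi(1-q) + (1-\phi)(1-q)^2$
  (verified against a 2×10⁶-draw Monte-Carlo oracle before the formulas
  were frozen into tests), so $p_0 + p_2 = 1 - 2(1-\phi)q(1-q)$ is exactly
  monotone in $\phi$. Ground truth stores both these state-level values and
  the observation-level ones corrected for Poisson emission zeros
  ($P(\text{observed off}) = q + (1-q)e^{-S}$), because detection operates
  on counts, not states.
* **`"beta"`.** The occupancy $\tau$ is drawn from the stationary
  Beta$(K_{on}, K_{off})$ law (shared between alleles under the coupling),
  giving genuine Poisson–Beta counts. A moment estimator applied to
  Bernoulli-emission counts is degenerate — the population moment solution
  drives $K_{on} \to 0$ — so every kinetics-recovery study, and the
  synthetic analysis cohort in `analysis/`, uses this mode.

`split_to_snp_reads()` distributes each gene–cell–allele count over the
gene's informative SNP sites multinomially (each read covers one SNP, so
SNP reads sum exactly to the gene count), then applies Poisson sequencing
noise with mean `depth_mean` reads per molecule, then capture dropout that
zeroes low-count entries (at most `dropout_max_reads` reads) with
probability `dropout_rate`. The capture efficiency of the emulated protocol
is not documented, so `dropout_rate` is an explicit free knob with default
0 rather than a calibrated value.

What the simulator does **not** emulate: continuous-time birth–death
dynamics (snapshot only), UMI/barcode structure, cell-to-cell size factors,
extrinsic noise shared across genes, or cell-cycle effects. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every artefact of real scRNA-seq data.

# Aggregation, normalisation and filters

A SNP site is *informative* for a gene when it reaches
`min_reads_per_snp = 3` total reads in at least one cell, and a gene is
kept only with `min_snps = 2` such sites. The filter is deliberately pooled
per gene rather than applied within every cell: sparse single-cell data
would otherwise lose almost all entries. Gene-level allelic counts are the
arithmetic mean of reads over the gene's qualifying sites, hence
real-valued; every downstream estimator accepts non-integer counts. Because
averaging over $k$ sites divides the read total by $k$, aggregated counts
carry a known $1/k$ scale relative to molecule counts. Allelic ratios,
detection-based statistics (p0/p2, all classifications) and the kinetics
shape parameters $K_{on}, K_{off}$ are invariant to this scale; only $S$
absorbs it (scale equivariance is tested explicitly).

RPKM is computed per allele and for the total layer with one shared
per-cell denominator, so allelic values are comparable within a cell.
Cells with zero total reads are excluded with a warning. The expression
filter keeps genes detected in at least 27% of cells *and* with mean total
RPKM strictly above 10; both bounds are boundary-tested (26% fails, exactly
10 fails, 28%/11 pass) and the filter is idempotent.

# Classification

A cell expresses a gene monoallelically when at least 95% of its allelic
reads come from one allele; the threshold is inclusive (19 vs 1 reads is a
monoallelic call). Gene classes use a deterministic thresholded rule:
silent below 5% detection; monoallelic when ≥ 95% of expressing cells are
monoallelic for the same allele; biallelic otherwise. Biallelic genes are
*bursty* when the set of cells detecting neither allele is non-empty but
proper, and *constitutive* when at least one allele is detected in ≥ 95% of
cells (near-ubiquitous detection, tolerant to dropout; the constitutive
rule takes precedence, and a biallelic gene with no silent window at all is
also constitutive). The published analyses delegate the three-way gene
classification to an Empirical-Bayes tool; this package replaces it with
the deterministic surrogate on purpose — the interface (three classes, then
bursty/constitutive) is what downstream stages consume, every threshold is
an explicit, documented knob, and the rule is fully testable. No claim is
made that the thresholds reconstruct the Bayesian tool's internal
decisions.

aRME categories follow from the per-cell calls of expressing cells:
Cat 1 all monoallelic for the same allele, Cat 2 monoallelic calls from one
allele plus biallelic cells, Cat 3 monoallelic calls from both alleles,
Cat 4 no monoallelic calls.

# Burst kinetics estimation

For the Poisson–Beta law the factorial moments are
$f_k = S^k \prod_{j=0}^{k-1} (K_{on}+j)/(K_{on}+K_{off}+j)$. With
$u_1 = f_1$, $u_2 = f_2/f_1$, $u_3 = f_3/f_2$ the three-moment system
inverts in closed form (implemented in `solve_telegraph_moments()`); tests
verify the solution against an independent damped-Newton root solve of the
forward system to 10⁻⁸. Sample factorial moments plug in directly.

Numerical policy: moment triples with non-positive moments, vanishing
denominators (|den| < 10⁻¹²) or non-positive roots return `valid = FALSE`
with a reason — never clipped values, because silently clipped estimates
would leak into the allelic correlations. Silent genes, constant counts
(the degenerate constitutive regime) and samples below `min_cells = 50` are
refused the same way. An optional likelihood refinement maximises the
Poisson–Beta likelihood by 64-node Gauss–Legendre quadrature in the Beta
quantile domain ($t = F^{-1}_{Beta}(u)$, smooth even for shape parameters
< 1), seeded at the moment solution; counts are rounded to integers for the
likelihood only.

Allelic differences are tested by a cell bootstrap: cells are resampled
with replacement (one index set shared by both alleles, preserving their
within-cell pairing), both alleles re-estimated, and a two-sided percentile
test applied to the bootstrap distribution of $\Delta \log K_{on}$ and
$\Delta \log (S/K_{off})$, with add-one smoothing so p-values are never
exactly zero and Benjamini–Hochberg correction across genes. Replicates
with invalid moment solutions are dropped; a gene needs 50 valid replicates
for a p-value. Validation at the package's study conditions (200 genes,
1 000 cells, B = 500, shared kinetics) shows type-I error ≈ 4–5% at nominal
5%, and ≥ 50% power for a 4-fold allelic $K_{on}$ difference at 1 000
cells with B = 1 000.

# Coordination geometry

Per gene, $p_0$ is the fraction of cells detecting neither allele and
$p_2$ the fraction detecting both, over all cells of the stage (a per-gene
detection floor before computing the fractions is a conceivable
alternative; all-cells is implemented and documented). Perfect coordination
means $p_0 + p_2 = 1$. Independent alleles with shared kinetics and equal
detection probability satisfy $p_0 = q_{obs}^2$, $p_2 = (1-q_{obs})^2$,
giving the independence curve $p_2 = (1-\sqrt{p_0})^2$.

Classification: highly coordinated when $p_0 + p_2 > 0.90$; otherwise
independent when within ±0.05 of the curve; otherwise semi-coordinated when
above the band. Two resolutions were genuinely open and are fixed as
follows. First, near the corners ($p_0 \to 0$ or $p_0 \to 1$) the diagonal
and the curve meet, so the highly-coordinated rule takes precedence over
the band. Second, the low-$p_0$/high-$p_2$ corner ($p_0 < 0.1$,
$p_2 > 0.8$) is flagged within the highly-coordinated class rather than
emitted as a fourth competing category, and points *below* the lower band
(anti-coordination, which the source analyses do not discuss) are labelled
independent with a `negative_deviation` flag so they remain visible without
inventing a class.

# Metagene profiles

Coverage tracks are 0-based half-open interval lists (bedGraph convention;
uncovered positions are zero). Region scores are length-weighted mean
coverage over the gene body ± flank (3 kb for accessibility-style analyses,
2 kb for chromatin-mark-style analyses; mean rather than summed coverage,
so scores are comparable across gene lengths). Metaprofiles bin the flanks
at fixed 10 bp width and rescale the gene body linearly to 100 bins;
minus-strand genes are mirrored so bin 1 is always upstream of the TSS
(TSS = `start` for `+`, `end − 1` for `-`). Genes shorter than the body
bin count are profiled with sub-base bins and flagged. Upstream smoothing
and genome-coverage normalisation belong to track generation and are not
replicated; they change no rank-based conclusion drawn from the scores.
Allelic score distributions are compared with the two-sided Mann–Whitney U
test, with entirely tied inputs reported as p = 1 rather than an error.

# Determinism and problem sizes

Every stochastic operation threads a single integer seed
(`withr::with_seed`, documented draw order), so identical configuration
and seed reproduce bit-identical outputs, including the pipeline's TSV
tree (tested via file hashes). The validation suite runs at deliberately
desk-scale sizes chosen for statistical head-room: coordination geometry at
200–500 genes × 300–1 000 cells, parameter recovery at 40 parameter draws
× 5 000 cells (median relative error ≤ 20% for $K_{on}$ and burst size,
typically ≈ 5–7%), bootstrap calibration at 200 genes × 1 000 cells ×
B = 500. The headline counts of the real study (thousands of bursty genes
per reprogramming stage, allelic correlations 0.64–0.8) depend on the
deposited datasets and are not reproduced here; the package validates the
geometry and estimators those results rest on.

# Known limitations

* The moment estimator needs pronounced zero/low-count structure; genes in
  the near-Poisson regime ($K_{on} \gg 1$) return invalid or unstable
  solutions by design rather than silently wrong ones.
* The deterministic class thresholds (`silent_frac`, `mono_gene_frac`,
  `constitutive_frac`) are explicit knobs, not a reconstruction of any
  Empirical-Bayes tool's internals.
* $\phi$ couples states at the snapshot level; it does not model partial
  temporal overlap of bursts within a cell cycle.
* The simulator's dropout is count-thresholded and independent across
  entries; real capture noise is correlated with expression and cell
  quality.
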