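#' Validate a coverage track
#'
#' A coverage track is a data.frame (`chrom`, `start`, `end`, `value`) of
#' 0-based half-open intervals, sorted and non-overlapping within each
#' chromosome, with finite non-negative values. Positions not covered by
#' any interval have signal zero (bedGraph convention).
#'
#' @param track data.frame to validate.
#' @return the track, classed `coverage_track`, invisibly usable downstream.
#' @export
as_coverage_track <- function(track) {
  req <- c("chrom", "start", "end", "value")
  if (!all(req %in% names(track)))
    stop_config("coverage track needs columns chrom, start, end, value")
  if (any(track$end <= track$start))
    stop_config("coverage track has intervals with end <= start")
  if (any(!is.finite(track$value)) || any(track$value < 0))
    stop_config("coverage track values must be finite and non-negative")
  track <- track[order(track$chrom, track$start), ]
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (ix in by_chrom) {
    if (length(ix) > 1 &&
        any(track$start[ix][-1] < track$end[ix][-length(ix)]))
      stop_config("coverage track has overlapping intervals on %s",
                  track$chrom[ix[1]])
  }
  rownames(track) <- NULL
  class(track) <- c("coverage_track", "data.frame")
  track
}

# Per-chromosome integrator: F(x) = integral of the track from 0 to x,
# vectorised over x. Gaps contribute zero.
track_integrator <- function(track, chrom) {
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0) return(function(x) rep(0, length(x)))
  S <- tr$start; E <- tr$end; V <- tr$value
  cum <- c(0, cumsum(V * (E - S)))
  function(x) {
    j <- findInterval(x, S)
    inside <- j >= 1
    out <- numeric(length(x))
    jj <- j[inside]
    out[inside] <- cum[jj] + V[jj] * pmax(0, pmin(x[inside], E[jj]) - S[jj])
    out
  }
}

# length-weighted mean of the track over [a, b), vectorised over intervals
track_interval_means <- function(Fint, a, b) {
  w <- b - a
  ifelse(w > 0, (Fint(b) - Fint(a)) / w, 0)
}

#' Length-weighted mean coverage over a gene region
#'
#' Mean signal over the gene body extended by `flank_bp` on both sides
#' (`[start - flank, end + flank)`, clipped at position 0). Uncovered
#' positions count as zero signal; a region with no overlapping track
#' interval scores 0 with a warning.
#'
#' @param track a `coverage_track` (see [as_coverage_track()]).
#' @param gene one-row gene annotation (`chrom`, `start`, `end`, `strand`)
#'   or a list with those fields.
#' @param flank_bp flank length in bp on each side (e.g. 3000 for
#'   accessibility, 2000 for chromatin marks).
#' @return numeric score (mean coverage).
#' @export
gene_region_score <- function(track, gene, flank_bp = 3000) {
  track <- as_coverage_track(track)
  a <- max(0, gene$start - flank_bp)
  b <- gene$end + flank_bp
  Fint <- track_integrator(track, gene$chrom)
  total <- Fint(b) - Fint(a)
  if (total == 0) {
    tr <- track[track$chrom == gene$chrom, ]
    if (nrow(tr) == 0 || all(tr$end <= a | tr$start >= b))
      warning("no track interval overlaps the gene region; score 0")
  }
  total / (b - a)
}

#' Per-gene region scores for a gene set
#'
#' @param track a `coverage_track`.
#' @param genes gene annotation data.frame.
#' @param flank_bp flank length in bp.
#' @return named numeric vector of scores (one per gene).
#' @export
gene_region_scores <- function(track, genes, flank_bp = 3000) {
  track <- as_coverage_track(track)
  out <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    ix <- which(genes$chrom == ch)
    Fint <- track_integrator(track, ch)
    a <- pmax(0, genes$start[ix] - flank_bp)
    b <- genes$end[ix] + flank_bp
    out[ix] <- track_interval_means(Fint, a, b)
  }
  stats::setNames(out, genes$gene_id)
}

#' Metagene coverage profile over flanks and scaled gene body
#'
#' Computes the classic metagene profile: mean signal in fixed-width bins
#' across the upstream flank, the gene body linearly rescaled to
#' `n_bins_body` bins, and the downstream flank, averaged over genes.
#' Minus-strand genes are flipped so bin 1 is always `flank_bp` upstream of
#' the TSS (TSS = `start` for `+` genes, `end - 1` for `-` genes; BED
#' conventions, 0-based half-open).
#'
#' @param track a `coverage_track`.
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param flank_bp flank length in bp (default 3000).
#' @param bin_bp flank bin width in bp (default 10).
#' @param n_bins_body bins over the rescaled gene body (default 100).
#' @param label optional gene-set label stored on the result.
#' @return object of class `meta_profile`: data.frame `bins` with `bin`,
#'   `section` (upstream/body/downstream), `position` (bp relative to TSS
#'   for flanks, fraction through the body), `mean`; plus attributes
#'   `n_genes`, `label`. Genes shorter than `n_bins_body` bases are
#'   profiled with sub-base bins and flagged in attribute `short_genes`.
#' @export
metaprofile <- function(track, genes, flank_bp = 3000, bin_bp = 10,
                        n_bins_body = 100, label = NULL) {
  track <- as_coverage_track(track)
  if (nrow(genes) == 0) stop_config("metaprofile needs >= 1 gene")
  if (!all(genes$strand %in% c("+", "-")))
    stop_config("strand must be '+' or '-'")
  n_flank <- as.integer(flank_bp / bin_bp)
  if (n_flank * bin_bp != flank_bp)
    stop_config("flank_bp must be a multiple of bin_bp")
  n_bins <- 2L * n_flank + n_bins_body

  acc <- base::matrix(0, nrow(genes), n_bins)
  for (ch in unique(genes$chrom)) {
    Fint <- track_integrator(track, ch)
    for (i in which(genes$chrom == ch)) {
      g <- genes[i, ]
      up_breaks <- seq(g$start - flank_bp, g$start, by = bin_bp)
      body_breaks <- seq(g$start, g$end, length.out = n_bins_body + 1)
      down_breaks <- seq(g$end, g$end + flank_bp, by = bin_bp)
      breaks <- c(up_breaks, body_breaks[-1],
                  down_breaks[-1])
      a <- pmax(0, breaks[-length(breaks)])
      b <- pmax(0, breaks[-1])
      vals <- pmax(0, track_interval_means(Fint, a, b))  # clip FP cancellation noise
      if (g$strand == "-") vals <- rev(vals)
      acc[i, ] <- vals
    }
  }
  section <- rep(c("upstream", "body", "downstream"),
                 c(n_flank, n_bins_body, n_flank))
  position <- c(seq(-flank_bp + bin_bp / 2, -bin_bp / 2, by = bin_bp),
                (seq_len(n_bins_body) - 0.5) / n_bins_body,
                seq(bin_bp / 2, flank_bp - bin_bp / 2, by = bin_bp))
  bins <- data.frame(bin = seq_len(n_bins), section = section,
                     position = position, mean = colMeans(acc),
                     stringsAsFactors = FALSE)
  structure(list(bins = bins),
            class = "meta_profile",
            n_genes = nrow(genes),
            n_bins = c(upstream = n_flank, body = n_bins_body,
                       downstream = n_flank),
            flank_bp = flank_bp,
            label = label %||% "genes",
            short_genes = genes$gene_id[genes$end - genes$start < n_bins_body])
}

#' @export
print.meta_profile <- function(x, ...) {
  nb <- attr(x, "n_bins")
  cat(sprintf("meta_profile '%s': %d genes, %d + %d + %d bins, flank %d bp\n",
              attr(x, "label"), attr(x, "n_genes"),
              nb[1], nb[2], nb[3], attr(x, "flank_bp")))
  for (s in c("upstream", "body", "downstream"))
    cat(sprintf("  mean over %s bins: %.4g\n", s,
                mean(x$bins$mean[x$bins$section == s])))
  invisible(x)
}

#' Compare allelic enrichment score distributions
#'
#' Two-sided Mann-Whitney U test between the per-gene region scores of the
#' two alleles. Entirely tied inputs return p = 1 with a warning instead
#' of an error.
#'
#' @param scores_A,scores_B per-gene scores for allele A and allele B
#'   (at least 3 each).
#' @return list `U`, `p`, `n_A`, `n_B`.
#' @export
compare_allelic_enrichment <- function(scores_A, scores_B) {
  if (length(scores_A) < 3 || length(scores_B) < 3)
    stop_config("compare_allelic_enrichment needs >= 3 scores per allele")
  if (length(unique(c(scores_A, scores_B))) == 1) {
    warning("all scores tied; p = 1")
    return(list(U = length(scores_A) * length(scores_B) / 2, p = 1,
                n_A = length(scores_A), n_B = length(scores_B)))
  }
  wt <- suppressWarnings(stats::wilcox.test(scores_A, scores_B,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_A = length(scores_A), n_B = length(scores_B))
}
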