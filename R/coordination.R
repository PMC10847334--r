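#' Per-gene p0 and p2 detection fractions
#'
#' For each gene, the fraction of cells detecting neither allele (p0) and
#' the fraction detecting both alleles (p2), computed over all cells of the
#' matrix ("expressing" means count > 0). Perfectly synchronised alleles
#' give p0 + p2 = 1; independently bursting alleles with shared kinetics
#' fall on the curve p2 = (1 - sqrt(p0))^2.
#'
#' @param matrix an [allelic_count_matrix()].
#' @param genes gene ids or indices (default all).
#' @return data.frame `gene_id`, `p0`, `p2`.
#' @export
compute_p0_p2 <- function(matrix, genes = NULL) {
  stopifnot(inherits(matrix, "allelic_count_matrix"))
  if (is.null(genes)) genes <- matrix$genes$gene_id
  if (is.numeric(genes)) genes <- matrix$genes$gene_id[genes]
  idx <- match(genes, matrix$genes$gene_id)
  if (anyNA(idx)) stop_config("unknown gene id(s)")
  A <- matrix$counts_A[idx, , drop = FALSE]
  B <- matrix$counts_B[idx, , drop = FALSE]
  data.frame(gene_id = genes,
             p0 = rowMeans(A == 0 & B == 0),
             p2 = rowMeans(A > 0 & B > 0),
             stringsAsFactors = FALSE)
}

#' Independence curve for allelic detection
#'
#' Expected p2 at a given p0 when the two alleles burst independently with
#' shared kinetics and equal detection probability: each allele is then
#' undetected with probability `sqrt(p0)`, so
#' `p2 = (1 - sqrt(p0))^2`.
#'
#' @param p0 fraction(s) in `[0, 1]`.
#' @return p2 on the independence curve.
#' @export
independence_curve <- function(p0) {
  if (any(p0 < 0 | p0 > 1, na.rm = TRUE)) stop_config("p0 must be in [0,1]")
  (1 - sqrt(p0))^2
}

#' Classify allelic bursting coordination
#'
#' Gene-level three-way classification of the (p0, p2) position:
#' highly coordinated when `p0 + p2 > hc_threshold` (near the perfect
#' coordination diagonal p0 + p2 = 1); independent when within `band` of
#' the shared-kinetics independence curve `p2 = (1 - sqrt(p0))^2`;
#' semi-coordinated when above the curve's upper band but below the
#' diagonal. Precedence: the highly-coordinated rule wins over the
#' independence band (both fire near the p0 -> 0 and p0 -> 1 corners).
#' Genes below the lower band (anti-coordination, p2 < curve - band) are
#' labelled independent with a `negative_deviation` flag; genes in the
#' low-p0/high-p2 corner (p0 < 0.1, p2 > 0.8) carry a `low_p0_high_p2`
#' flag within the highly-coordinated class.
#'
#' @param p0,p2 detection fractions (vectorised), or a data.frame from
#'   [compute_p0_p2()] as first argument.
#' @param hc_threshold highly-coordinated threshold on p0 + p2
#'   (default 0.90, strict `>`).
#' @param band half-width of the independence band around the curve
#'   (default 0.05).
#' @return data.frame `p0`, `p2`, `p2_ind`, `deviation` (= p2 - p2_ind),
#'   `category`, `low_p0_high_p2`, `negative_deviation` (plus `gene_id`
#'   when the input carried one).
#' @export
classify_coordination <- function(p0, p2 = NULL, hc_threshold = 0.90,
                                  band = 0.05) {
  gene_id <- NULL
  if (is.data.frame(p0)) {
    gene_id <- p0$gene_id
    p2 <- p0$p2
    p0 <- p0$p0
  }
  if (any(p0 < 0 | p0 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop_config("p0 and p2 must be fractions in [0,1]")
  if (any(p0 + p2 > 1 + 1e-9, na.rm = TRUE))
    stop_config("p0 + p2 cannot exceed 1")
  p2_ind <- independence_curve(p0)
  deviation <- p2 - p2_ind
  category <- ifelse(p0 + p2 > hc_threshold, "highly_coordinated",
              ifelse(abs(deviation) <= band, "independent",
              ifelse(deviation > band, "semi_coordinated", "independent")))
  out <- data.frame(p0 = p0, p2 = p2, p2_ind = p2_ind, deviation = deviation,
                    category = category,
                    low_p0_high_p2 = category == "highly_coordinated" &
                      p0 < 0.1 & p2 > 0.8,
                    negative_deviation = category == "independent" &
                      deviation < -band,
                    stringsAsFactors = FALSE)
  if (!is.null(gene_id)) out <- cbind(gene_id = gene_id, out)
  out
}

#' Coordination records for a matrix
#'
#' Convenience wrapper: [compute_p0_p2()] followed by
#' [classify_coordination()].
#'
#' @inheritParams compute_p0_p2
#' @inheritParams classify_coordination
#' @return data.frame of per-gene coordination records.
#' @export
coordination_records <- function(matrix, genes = NULL, hc_threshold = 0.90,
                                 band = 0.05) {
  classify_coordination(compute_p0_p2(matrix, genes),
                        hc_threshold = hc_threshold, band = band)
}

#' Compare expression levels between coordination categories
#'
#' Per-gene mean total RPKM compared between coordination categories by
#' pairwise two-sided Mann-Whitney U tests ([stats::wilcox.test()]; exact
#' or normal approximation switched by sample size as in base R).
#' Categories with fewer than `min_genes` genes are skipped with a
#' warning.
#'
#' @param rpkm an `rpkm_matrix` (filtered).
#' @param records coordination records (with `gene_id` and `category`).
#' @param min_genes minimum genes per category (default 3).
#' @return list of class `category_expression`: `gene_means` (per-gene mean
#'   RPKM and category), `tests` (data.frame category pair, U, p, group
#'   sizes), `summary` (median expression per category).
#' @export
expression_by_category <- function(rpkm, records, min_genes = 3) {
  stopifnot(inherits(rpkm, "rpkm_matrix"))
  idx <- match(records$gene_id, rpkm$genes$gene_id)
  if (anyNA(idx)) stop_config("records contain genes absent from the rpkm matrix")
  gm <- data.frame(gene_id = records$gene_id,
                   mean_rpkm = rowMeans(rpkm$total[idx, , drop = FALSE]),
                   category = records$category,
                   stringsAsFactors = FALSE)
  cats <- split(gm$mean_rpkm, gm$category)
  usable <- names(cats)[lengths(cats) >= min_genes]
  skipped <- setdiff(names(cats), usable)
  if (length(skipped) > 0)
    warning(sprintf("category with < %d genes skipped: %s", min_genes,
                    paste(skipped, collapse = ", ")))
  if (length(usable) < 2)
    stop_config("expression_by_category needs >= 2 populated categories")
  pairs <- utils::combn(usable, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    wt <- suppressWarnings(stats::wilcox.test(cats[[a]], cats[[b]],
                                              alternative = "two.sided"))
    data.frame(category1 = a, category2 = b,
               U = unname(wt$statistic), p = wt$p.value,
               n1 = length(cats[[a]]), n2 = length(cats[[b]]),
               stringsAsFactors = FALSE)
  }))
  summary <- data.frame(category = names(cats),
                        n = lengths(cats),
                        median_rpkm = vapply(cats, stats::median, numeric(1)),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(gene_means = gm, tests = tests, summary = summary),
            class = "category_expression")
}

#' @export
print.category_expression <- function(x, ...) {
  cat("expression by coordination category:\n")
  print(x$summary, row.names = FALSE)
  cat("pairwise Mann-Whitney U tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
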