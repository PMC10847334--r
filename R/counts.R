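#' Aggregate SNP-level allelic reads to gene-level counts
#'
#' Applies the informative-SNP filters and across-SNP averaging used for
#' allele-specific expression quantification in F1 hybrids: a SNP site
#' qualifies for its gene if it reaches `min_reads_per_snp` total reads
#' (both alleles) in at least one cell, and a gene is retained only if it
#' has at least `min_snps` qualifying sites. Gene-level allelic counts are
#' the arithmetic mean of per-site reads over the gene's qualifying sites
#' (sites with no reads in a cell contribute zero), so counts are generally
#' non-integer.
#'
#' The per-gene (rather than per-cell) pooling of the SNP filter is
#' deliberate: applying "3 reads per SNP" within every cell would discard
#' nearly all sparse scRNA-seq entries.
#'
#' @param table SNP read table data.frame: `gene_id`, `chrom`, `pos`,
#'   `cell_id`, `reads_A`, `reads_B`. Absent (gene, pos, cell) rows count
#'   as zero reads.
#' @param min_snps minimum qualifying SNP sites per gene (default 2).
#' @param min_reads_per_snp minimum total reads at a site, in some cell,
#'   for the site to be informative (default 3).
#' @param gene_meta optional data.frame of gene metadata (`gene_id`,
#'   `gene_length`, ...) to carry onto the result.
#' @param cell_meta optional data.frame of cell metadata (`cell_id`,
#'   `stage`, optionally `total_reads`). Cells listed here but absent from
#'   `table` appear as all-zero columns. `total_reads`, when provided (e.g.
#'   including reads not assignable to either allele), is used as the RPKM
#'   denominator downstream; otherwise it defaults to the aggregated A+B
#'   sum.
#' @return An [allelic_count_matrix()]. If no gene survives the filters, a
#'   typed empty matrix is returned with a warning.
#' @export
aggregate_snp_to_gene <- function(table, min_snps = 2L, min_reads_per_snp = 3L,
                                  gene_meta = NULL, cell_meta = NULL) {
  if (!all(c("gene_id", "pos", "cell_id", "reads_A", "reads_B") %in% names(table)))
    stop_config("SNP table must have gene_id, pos, cell_id, reads_A, reads_B")
  if (nrow(table) == 0) stop_config("SNP table is empty")
  if (any(table$reads_A < 0) || any(table$reads_B < 0))
    stop_config("reads must be non-negative")

  tot <- table$reads_A + table$reads_B
  site <- paste(table$gene_id, table$pos, sep = "@")
  informative_sites <- unique(site[tot >= min_reads_per_snp])
  n_sites <- table(sub("@.*", "", informative_sites))
  keep_genes <- names(n_sites)[n_sites >= min_snps]

  cell_levels <- if (!is.null(cell_meta)) as.character(cell_meta$cell_id)
                 else sort(unique(table$cell_id))
  if (length(keep_genes) == 0) {
    warning("no gene passed the informative-SNP filters; returning empty matrix")
    return(empty_allelic_count_matrix())
  }
  keep <- table$gene_id %in% keep_genes & site %in% informative_sites
  tb <- table[keep, ]
  gene_f <- factor(tb$gene_id, levels = sort(keep_genes))
  cell_f <- factor(tb$cell_id, levels = cell_levels)
  sums_A <- stats::xtabs(reads_A ~ gene_f + cell_f, data = tb, addNA = FALSE)
  sums_B <- stats::xtabs(reads_B ~ gene_f + cell_f, data = tb, addNA = FALSE)
  k_per_gene <- n_sites[levels(gene_f)]
  counts_A <- unclass(sums_A) / as.numeric(k_per_gene)
  counts_B <- unclass(sums_B) / as.numeric(k_per_gene)
  dimnames(counts_A) <- dimnames(counts_B) <- list(levels(gene_f), cell_levels)

  genes <- data.frame(gene_id = levels(gene_f),
                      n_informative_snps = as.integer(k_per_gene),
                      stringsAsFactors = FALSE)
  if (!is.null(gene_meta))
    genes <- merge(genes, gene_meta, by = "gene_id", all.x = TRUE, sort = FALSE)
  genes <- genes[match(levels(gene_f), genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  cells <- data.frame(cell_id = cell_levels, stringsAsFactors = FALSE)
  if (!is.null(cell_meta))
    cells <- merge(cells, cell_meta, by = "cell_id", all.x = TRUE, sort = FALSE)
  cells <- cells[match(cell_levels, cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  allelic_count_matrix(counts_A, counts_B, genes, cells)
}

#' RPKM-normalise an allelic count matrix
#'
#' Reads per kilobase of gene length per million cell reads, computed per
#' allele and for the total (A + B) layer. All three layers share the same
#' per-cell denominator (`cells$total_reads`), so allelic RPKM values are
#' directly comparable within a cell.
#'
#' @param matrix an [allelic_count_matrix()] with `genes$gene_length` set.
#' @return An object of class `rpkm_matrix`: list with matrices `A`, `B`,
#'   `total`, plus `genes` and `cells` metadata. Cells with zero total
#'   reads are flagged in a warning and excluded.
#' @export
rpkm_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "allelic_count_matrix"))
  len <- matrix$genes$gene_length
  if (is.null(len) || anyNA(len))
    stop_config("rpkm_normalize needs gene_length for every gene")
  tot <- matrix$cells$total_reads
  bad <- !is.finite(tot) | tot <= 0
  if (any(bad)) {
    warning(sprintf("%d cell(s) with zero total reads excluded: %s",
                    sum(bad), paste(matrix$cells$cell_id[bad], collapse = ", ")))
    matrix <- matrix[, !bad]
    tot <- matrix$cells$total_reads
  }
  norm <- function(m) m / (len / 1e3) / rep(tot / 1e6, each = nrow(m))
  structure(list(A = norm(matrix$counts_A),
                 B = norm(matrix$counts_B),
                 total = norm(matrix$counts_A + matrix$counts_B),
                 genes = matrix$genes, cells = matrix$cells),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat(sprintf("rpkm_matrix: %d genes x %d cells\n", nrow(x$total), ncol(x$total)))
  invisible(x)
}

#' Filter to robustly expressed genes
#'
#' Low-expressed genes are dropout prone and give unreliable allelic
#' estimates, so the pipeline keeps only genes detected (total expression
#' > 0) in at least `min_cell_fraction` of cells AND with mean total RPKM
#' strictly above `min_mean_rpkm`. The operation is idempotent.
#'
#' @param rpkm an `rpkm_matrix` from [rpkm_normalize()].
#' @param min_cell_fraction minimum fraction of cells with detection
#'   (default 0.27, applied as `>=`).
#' @param min_mean_rpkm mean total RPKM must strictly exceed this
#'   (default 10).
#' @return the filtered `rpkm_matrix`, with attribute `"removed"` holding
#'   the dropped gene ids.
#' @export
filter_expressed <- function(rpkm, min_cell_fraction = 0.27, min_mean_rpkm = 10) {
  stopifnot(inherits(rpkm, "rpkm_matrix"))
  det_frac <- rowMeans(rpkm$total > 0)
  mean_rpkm <- rowMeans(rpkm$total)
  keep <- det_frac >= min_cell_fraction & mean_rpkm > min_mean_rpkm
  keep[is.na(keep)] <- FALSE
  out <- structure(list(A = rpkm$A[keep, , drop = FALSE],
                        B = rpkm$B[keep, , drop = FALSE],
                        total = rpkm$total[keep, , drop = FALSE],
                        genes = rpkm$genes[keep, , drop = FALSE],
                        cells = rpkm$cells),
                   class = "rpkm_matrix")
  attr(out, "removed") <- rpkm$genes$gene_id[!keep]
  out
}

#' Subset an allelic count matrix to the genes retained by the RPKM filter
#'
#' @param matrix an [allelic_count_matrix()].
#' @param rpkm a filtered `rpkm_matrix`.
#' @return the matching [allelic_count_matrix()] subset.
#' @export
subset_to_filtered <- function(matrix, rpkm) {
  matrix[match(rpkm$genes$gene_id, matrix$genes$gene_id),
         match(rpkm$cells$cell_id, matrix$cells$cell_id)]
}

#' Allelic ratio
#'
#' Fraction of allelic expression from the 129S1 allele (allele A):
#' `counts_A / (counts_A + counts_B)`. Returns `NA` where neither allele
#' has reads.
#'
#' @param matrix an [allelic_count_matrix()], or a numeric vector/matrix of
#'   allele-A counts if `counts_B` is given.
#' @param gene,cell optional gene/cell identifiers or indices to extract a
#'   single value.
#' @param counts_B when `matrix` is raw allele-A counts, the matching
#'   allele-B counts.
#' @return numeric ratio(s) in `[0, 1]`, `NA` where undefined.
#' @export
allelic_ratio <- function(matrix, gene = NULL, cell = NULL, counts_B = NULL) {
  if (inherits(matrix, "allelic_count_matrix")) {
    A <- matrix$counts_A; B <- matrix$counts_B
  } else {
    if (is.null(counts_B)) stop_config("counts_B required for raw counts input")
    A <- matrix; B <- counts_B
  }
  r <- A / (A + B)
  r[(A + B) == 0] <- NA_real_
  if (!is.null(gene) || !is.null(cell)) {
    r <- r[gene %||% seq_len(nrow(r)), cell %||% seq_len(ncol(r))]
  }
  r
}
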