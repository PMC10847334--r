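#' Allelic count matrix
#'
#' The central exchange object of the pipeline: genes x cells read counts for
#' the two parental alleles (allele A = 129S1, allele B = CAST by convention),
#' together with per-gene and per-cell metadata. Counts may be real-valued,
#' because gene-level counts are obtained by averaging reads across
#' informative SNP sites.
#'
#' @param counts_A,counts_B numeric genes x cells matrices, non-negative,
#'   identical dimensions and dimnames.
#' @param genes data.frame of gene metadata with at least `gene_id`;
#'   `gene_length` (bp) is required for RPKM normalisation. Optional
#'   annotation columns (`chrom`, `start`, `end`, `strand`) are carried along.
#' @param cells data.frame of cell metadata with at least `cell_id`;
#'   `total_reads` defaults to the column sums of A + B, `stage` to
#'   `"stage1"`.
#'
#' @return An object of class `allelic_count_matrix`: a list with elements
#'   `counts_A`, `counts_B`, `genes`, `cells`.
#' @export
allelic_count_matrix <- function(counts_A, counts_B, genes = NULL, cells = NULL) {
  counts_A <- as.matrix(counts_A)
  counts_B <- as.matrix(counts_B)
  if (!identical(dim(counts_A), dim(counts_B)))
    stop_config("counts_A and counts_B must have identical dimensions")
  if (anyNA(counts_A) || anyNA(counts_B))
    stop_config("allelic counts must not contain NA")
  if (min(counts_A, 0) < 0 || min(counts_B, 0) < 0)
    stop_config("allelic counts must be non-negative")
  gene_ids <- rownames(counts_A) %||% sprintf("gene_%04d", seq_len(nrow(counts_A)))
  cell_ids <- colnames(counts_A) %||% sprintf("cell_%04d", seq_len(ncol(counts_A)))
  dimnames(counts_A) <- dimnames(counts_B) <- list(gene_ids, cell_ids)

  if (is.null(genes)) genes <- data.frame(gene_id = gene_ids)
  if (is.null(cells)) cells <- data.frame(cell_id = cell_ids)
  if (!"gene_id" %in% names(genes)) stop_config("genes metadata needs a gene_id column")
  if (!"cell_id" %in% names(cells)) stop_config("cells metadata needs a cell_id column")
  if (!identical(as.character(genes$gene_id), gene_ids))
    stop_config("genes metadata does not match count matrix rows")
  if (!identical(as.character(cells$cell_id), cell_ids))
    stop_config("cells metadata does not match count matrix columns")
  if (!is.null(genes$gene_length) && any(genes$gene_length <= 0, na.rm = TRUE))
    stop_config("gene_length must be positive")
  if (is.null(cells$total_reads))
    cells$total_reads <- colSums(counts_A) + colSums(counts_B)
  if (is.null(cells$stage)) cells$stage <- rep("stage1", nrow(cells))

  structure(list(counts_A = counts_A, counts_B = counts_B,
                 genes = genes, cells = cells),
            class = "allelic_count_matrix")
}

#' @export
print.allelic_count_matrix <- function(x, ...) {
  cat(sprintf("allelic_count_matrix: %d genes x %d cells\n",
              nrow(x$counts_A), ncol(x$counts_A)))
  cat(sprintf("  stages: %s\n", paste(unique(x$cells$stage), collapse = ", ")))
  cat(sprintf("  nonzero entries: A %.1f%%, B %.1f%%\n",
              100 * mean(x$counts_A > 0), 100 * mean(x$counts_B > 0)))
  invisible(x)
}

#' @export
dim.allelic_count_matrix <- function(x) dim(x$counts_A)

#' Subset an allelic count matrix
#'
#' @param x allelic_count_matrix.
#' @param i gene index (integer, logical or gene_id character).
#' @param j cell index (integer, logical or cell_id character).
#' @param ... ignored.
#' @export
`[.allelic_count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts_A))
  if (missing(j)) j <- seq_len(ncol(x$counts_A))
  if (is.character(i)) i <- match(i, rownames(x$counts_A))
  if (is.character(j)) j <- match(j, colnames(x$counts_A))
  allelic_count_matrix(x$counts_A[i, j, drop = FALSE],
                       x$counts_B[i, j, drop = FALSE],
                       genes = x$genes[i, , drop = FALSE],
                       cells = x$cells[j, , drop = FALSE])
}

empty_allelic_count_matrix <- function() {
  allelic_count_matrix(matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0),
                       genes = data.frame(gene_id = character(0)),
                       cells = data.frame(cell_id = character(0)))
}
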