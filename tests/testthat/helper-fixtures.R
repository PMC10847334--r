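# shared fixture builders; everything is generated in code at test time

# count matrix with fully controlled entries; gene length 1 kb and cell
# totals 1e6 reads make RPKM equal the raw count
make_acm <- function(A, B, gene_length = 1000, total_reads = 1e6,
                     stage = "stage1") {
  A <- as.matrix(A); B <- as.matrix(B)
  rownames(A) <- rownames(B) <- sprintf("g%02d", seq_len(nrow(A)))
  colnames(A) <- colnames(B) <- sprintf("c%03d", seq_len(ncol(A)))
  allelic_count_matrix(
    A, B,
    genes = data.frame(gene_id = rownames(A),
                       gene_length = rep_len(gene_length, nrow(A))),
    cells = data.frame(cell_id = colnames(A),
                       total_reads = rep_len(total_reads, ncol(A)),
                       stage = stage))
}

# non-overlapping gene annotation on one chromosome with generous gaps
make_genes <- function(n, len = 5000, gap = 15000, strand = NULL) {
  start <- seq(gap, by = len + gap, length.out = n)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chrom = "chr1", start = start, end = start + len,
             strand = strand %||% rep_len(c("+", "-"), n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
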