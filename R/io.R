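#' Read / write a SNP read table
#'
#' TSV schema: `gene_id`, `chrom`, `pos` (0-based), `cell_id`, `reads_A`,
#' `reads_B`. Duplicate (gene, pos, cell) rows or negative reads are
#' rejected with the offending line numbers.
#'
#' @param path TSV file path.
#' @return data.frame SNP read table.
#' @export
read_snp_table <- function(path) {
  tb <- read_tsv_file(path)
  req <- c("gene_id", "chrom", "pos", "cell_id", "reads_A", "reads_B")
  if (!all(req %in% names(tb)))
    stop_config("SNP table %s must have columns: %s", path,
                paste(req, collapse = ", "))
  bad <- which(tb$reads_A < 0 | tb$reads_B < 0)
  if (length(bad) > 0)
    stop_config("negative reads in %s at data line(s) %s", path,
                paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(tb$gene_id, tb$pos, tb$cell_id)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop_config("duplicate (gene, pos, cell) in %s at data line(s) %s", path,
                paste(utils::head(dup, 5), collapse = ", "))
  tb
}

#' @rdname read_snp_table
#' @param table SNP read table data.frame.
#' @export
write_snp_table <- function(table, path) {
  write_tsv_file(table, path)
}

#' Write / read an allelic count matrix as TSV files
#'
#' Writes `<prefix>.alleleA.tsv` and `<prefix>.alleleB.tsv` (gene x cell
#' matrices with a leading `gene_id` column) plus `<prefix>.genes.tsv` and
#' `<prefix>.cells.tsv` metadata. `read_allelic_counts()` round-trips them.
#'
#' @param matrix an [allelic_count_matrix()].
#' @param prefix output path prefix.
#' @return `write_allelic_counts()` the prefix, invisibly;
#'   `read_allelic_counts()` the matrix.
#' @export
write_allelic_counts <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "allelic_count_matrix"))
  wr <- function(m, suffix) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_file(df, paste0(prefix, suffix))
  }
  wr(matrix$counts_A, ".alleleA.tsv")
  wr(matrix$counts_B, ".alleleB.tsv")
  write_tsv_file(matrix$genes, paste0(prefix, ".genes.tsv"))
  write_tsv_file(matrix$cells, paste0(prefix, ".cells.tsv"))
  invisible(prefix)
}

#' @rdname write_allelic_counts
#' @export
read_allelic_counts <- function(prefix) {
  rd <- function(suffix) {
    df <- read_tsv_file(paste0(prefix, suffix), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    m
  }
  A <- rd(".alleleA.tsv")
  B <- rd(".alleleB.tsv")
  genes <- read_tsv_file(paste0(prefix, ".genes.tsv"))
  cells <- read_tsv_file(paste0(prefix, ".cells.tsv"))
  allelic_count_matrix(A, B, genes, cells)
}

#' Read / write bedGraph coverage tracks
#'
#' bedGraph: four whitespace-separated columns chrom, start, end, value;
#' 0-based half-open. `track` and comment lines are skipped. Malformed
#' coordinates and overlapping intervals are reported with their line
#' number.
#'
#' @param path bedGraph file path.
#' @return a `coverage_track` data.frame.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  ln <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4))
    stop_config("%s line %d: expected 4 bedGraph fields, found %d",
                path, ln[which(nf != 4)[1]], nf[nf != 4][1])
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad) > 0)
    stop_config("%s line %d: non-numeric coordinates or value", path, ln[bad[1]])
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop_config("%s line %d: end <= start", path, ln[bad[1]])
  tr <- data.frame(chrom = m[, 1], start = start, end = end, value = value,
                   stringsAsFactors = FALSE)
  ord <- order(tr$chrom, tr$start)
  for (ch in unique(tr$chrom)) {
    ix <- ord[tr$chrom[ord] == ch]
    if (length(ix) > 1) {
      ov <- which(tr$start[ix][-1] < tr$end[ix][-length(ix)])
      if (length(ov) > 0)
        stop_config("%s line %d: interval overlaps the previous one on %s",
                    path, ln[ix[ov[1] + 1]], ch)
    }
  }
  as_coverage_track(tr)
}

#' @rdname read_bedgraph
#' @param track a `coverage_track`.
#' @export
write_bedgraph <- function(track, path) {
  track <- as_coverage_track(track)
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotations from BED6 or GTF
#'
#' BED6 files are parsed directly (with line-numbered diagnostics for
#' coordinate or strand violations); GTF/GFF files are imported through
#' rtracklayer and reduced to `gene` features (falling back to transcript
#' features if no gene rows exist).
#'
#' @param path annotation file (`.bed`, `.gtf` or `.gff`).
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) return(read_bed6(path))
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
    return(read_gtf_genes(path))
  stop_config("unsupported annotation format: %s", path)
}

read_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  ln <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\t")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop_config("%s line %d: expected >= 6 BED fields", path, ln[which(nf < 6)[1]])
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0)
    stop_config("%s line %d: invalid coordinates (need numeric, end > start)",
                path, ln[bad[1]])
  bad <- which(!m[, 6] %in% c("+", "-"))
  if (length(bad) > 0)
    stop_config("%s line %d: unknown strand '%s'", path, ln[bad[1]], m[bad[1], 6])
  data.frame(gene_id = m[, 4], chrom = m[, 1], start = start, end = end,
             strand = m[, 6], stringsAsFactors = FALSE)
}

read_gtf_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_config("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if ("type" %in% names(md) && any(md$type == "gene"))
    md <- md[md$type == "gene", ]
  ids <- md$gene_id %||% md$ID %||% md$Name
  if (is.null(ids)) stop_config("no gene_id attribute found in %s", path)
  st <- as.character(md$strand)
  if (any(!st %in% c("+", "-")))
    stop_config("unknown strand in %s", path)
  data.frame(gene_id = as.character(ids), chrom = as.character(md$seqnames),
             start = md$start - 1L,      # GTF is 1-based closed; emit 0-based
             end = md$end, strand = st, stringsAsFactors = FALSE)
}

#' @rdname read_gene_annotation
#' @param genes gene annotation data.frame.
#' @export
write_gene_annotation <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
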