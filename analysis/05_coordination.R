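#!/usr/bin/env Rscript
# Allelic bursting coordination: per-gene p0/p2 against the independence
# curve p2 = (1 - sqrt(p0))^2, three-way classification, the cross-stage
# category trajectory, and the expression comparison between categories.

suppressPackageStartupMessages(library(coburst))
countdir <- "results/analysis/counts"
classdir <- "results/analysis/classify"
outdir <- "results/analysis/coordination"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

records <- list()
for (st in c("mef", "ipsc")) {
  acm <- read_allelic_counts(file.path(countdir, sprintf("%s.filtered", st)))
  cl <- coburst:::read_tsv_file(file.path(classdir,
                                          sprintf("%s.classes.tsv", st)))
  bursty <- cl$gene_id[cl$burst_class == "bursty"]
  rec <- coordination_records(acm, bursty)
  coburst:::write_tsv_file(rec, file.path(outdir,
                                          sprintf("%s.coordination.tsv", st)))
  records[[st]] <- rec
  tab <- table(rec$category)
  cat(sprintf("%s (%d bursty genes): %s\n", st, nrow(rec),
              paste(sprintf("%s %d (%.0f%%)", names(tab), tab,
                            100 * tab / sum(tab)), collapse = ", ")))

  rpkm <- rpkm_normalize(acm)
  res <- tryCatch(expression_by_category(rpkm,
                                         rec[, c("gene_id", "category")]),
                  error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(res)) {
    coburst:::write_tsv_file(res$tests,
                             file.path(outdir, sprintf("%s.expr_tests.tsv", st)))
    cat("  expression by category (median RPKM):",
        paste(sprintf("%s %.1f", res$summary$category,
                      res$summary$median_rpkm), collapse = ", "), "\n")
  }
}

ct <- crosstab_classes(lapply(records, function(r)
  data.frame(gene_id = r$gene_id, category = r$category)), "category")
coburst:::write_tsv_file(ct$trajectories,
                         file.path(outdir, "category_crosstab.tsv"))
cat("top coordination trajectories (mef -> ipsc):\n")
print(head(ct$trajectories, 5), row.names = FALSE)
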