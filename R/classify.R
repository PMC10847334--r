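#' Per-cell allelic expression call
#'
#' A gene is monoallelic within a cell when at least `mono_threshold`
#' (default 95%) of its allelic expression originates from one allele.
#' The threshold is inclusive: an allelic ratio of exactly 0.95 is a
#' monoallelic call.
#'
#' @param counts_A,counts_B non-negative counts (vectorised).
#' @param mono_threshold monoallelic ratio threshold (default 0.95).
#' @return character vector: `"silent"` (both zero), `"mono_A"`,
#'   `"mono_B"`, or `"biallelic"`.
#' @export
call_cell_state <- function(counts_A, counts_B, mono_threshold = 0.95) {
  if (any(counts_A < 0, na.rm = TRUE) || any(counts_B < 0, na.rm = TRUE))
    stop_config("counts must be non-negative")
  tot <- counts_A + counts_B
  ratio <- counts_A / tot
  out <- rep("biallelic", length(tot))
  out[tot == 0] <- "silent"
  out[tot > 0 & ratio >= mono_threshold] <- "mono_A"
  out[tot > 0 & ratio <= 1 - mono_threshold] <- "mono_B"
  out
}

#' Per-cell allelic calls for a whole matrix
#'
#' @param matrix an [allelic_count_matrix()].
#' @param mono_threshold see [call_cell_state()].
#' @return character genes x cells matrix of calls.
#' @export
cell_state_matrix <- function(matrix, mono_threshold = 0.95) {
  stopifnot(inherits(matrix, "allelic_count_matrix"))
  out <- call_cell_state(matrix$counts_A, matrix$counts_B, mono_threshold)
  base::matrix(out, nrow(matrix$counts_A), ncol(matrix$counts_A),
               dimnames = dimnames(matrix$counts_A))
}

#' Gene-level expression class and bursty/constitutive classification
#'
#' Deterministic three-way gene classification (silent / monoallelic /
#' biallelic) followed by the bursty/constitutive split of biallelic genes.
#' A gene is silent when detected (total count > 0) in fewer than
#' `silent_frac` of cells; monoallelic when, among expressing cells, at
#' least `mono_gene_frac` are monoallelic for the same allele; biallelic
#' otherwise. A biallelic gene is constitutive when at least one allele is
#' detected in at least `constitutive_frac` of cells (near-ubiquitous
#' detection, tolerant to dropout), and bursty when the set of cells with
#' zero expression of both alleles is non-empty but not all cells.
#' Biallelic genes with no both-zero cell that miss the per-allele
#' constitutive bar are still constitutive (there is no silent window).
#'
#' @param matrix an [allelic_count_matrix()], normally already filtered.
#' @param silent_frac detection fraction below which a gene is silent
#'   (default 0.05).
#' @param mono_gene_frac fraction of expressing cells that must be
#'   monoallelic for one allele to call the gene monoallelic
#'   (default 0.95).
#' @param constitutive_frac per-allele detection fraction defining
#'   constitutive expression (default 0.95).
#' @param mono_threshold per-cell monoallelic ratio threshold
#'   (default 0.95).
#' @return data.frame per gene: `gene_id`, `expr_class`
#'   (silent/monoallelic/biallelic), `burst_class`
#'   (bursty/constitutive/not_applicable). `burst_class` is
#'   `not_applicable` exactly for non-biallelic genes.
#' @export
classify_gene_expression <- function(matrix, silent_frac = 0.05,
                                     mono_gene_frac = 0.95,
                                     constitutive_frac = 0.95,
                                     mono_threshold = 0.95) {
  stopifnot(inherits(matrix, "allelic_count_matrix"))
  A <- matrix$counts_A; B <- matrix$counts_B
  states <- cell_state_matrix(matrix, mono_threshold)
  expressing <- A + B > 0
  det_frac <- rowMeans(expressing)
  n_expr <- rowSums(expressing)
  frac_monoA <- rowSums(states == "mono_A") / pmax(n_expr, 1)
  frac_monoB <- rowSums(states == "mono_B") / pmax(n_expr, 1)

  expr_class <- rep("biallelic", nrow(A))
  expr_class[n_expr > 0 &
               (frac_monoA >= mono_gene_frac | frac_monoB >= mono_gene_frac)] <-
    "monoallelic"
  expr_class[det_frac < silent_frac] <- "silent"

  burst_class <- rep("not_applicable", nrow(A))
  bi <- expr_class == "biallelic"
  burst_class[bi] <- classify_bursty_rows(A[bi, , drop = FALSE],
                                          B[bi, , drop = FALSE],
                                          constitutive_frac)
  data.frame(gene_id = matrix$genes$gene_id,
             expr_class = expr_class,
             burst_class = burst_class,
             stringsAsFactors = FALSE)
}

classify_bursty_rows <- function(A, B, constitutive_frac = 0.95) {
  both_zero <- rowSums(A == 0 & B == 0)
  n <- ncol(A)
  constitutive <- rowMeans(A > 0) >= constitutive_frac |
    rowMeans(B > 0) >= constitutive_frac
  bursty <- !constitutive & both_zero > 0 & both_zero < n
  ifelse(bursty, "bursty", "constitutive")
}

#' Bursty/constitutive call for one biallelic gene
#'
#' @param matrix an [allelic_count_matrix()].
#' @param gene gene id or row index.
#' @param constitutive_frac see [classify_gene_expression()].
#' @return `"bursty"` or `"constitutive"`.
#' @export
classify_bursty <- function(matrix, gene, constitutive_frac = 0.95) {
  stopifnot(inherits(matrix, "allelic_count_matrix"))
  if (is.character(gene)) gene <- match(gene, matrix$genes$gene_id)
  classify_bursty_rows(matrix$counts_A[gene, , drop = FALSE],
                       matrix$counts_B[gene, , drop = FALSE],
                       constitutive_frac)
}

arme_levels <- c("Cat1_nonrandom_mono", "Cat2_rme_one_allele",
                 "Cat3_rme_either_allele", "Cat4_biallelic")

#' Random monoallelic expression (aRME) category of a gene
#'
#' Classifies a gene by the allelic calls of its expressing cells:
#' Cat 1 (nonrandom monoallelic) — every expressing cell is monoallelic for
#' the same allele; Cat 2 (RME with one allele) — monoallelic calls exist,
#' all from one allele, alongside biallelic cells; Cat 3 (RME with either
#' allele) — monoallelic calls from both alleles; Cat 4 (biallelic) — no
#' monoallelic call.
#'
#' @param calls character vector of per-cell calls for one gene
#'   (from [call_cell_state()]); `"silent"` cells are ignored.
#' @return one of `"Cat1_nonrandom_mono"`, `"Cat2_rme_one_allele"`,
#'   `"Cat3_rme_either_allele"`, `"Cat4_biallelic"`.
#' @export
classify_arme <- function(calls) {
  calls <- calls[calls != "silent"]
  if (length(calls) == 0) stop_config("classify_arme needs >= 1 expressing cell")
  has_a <- any(calls == "mono_A")
  has_b <- any(calls == "mono_B")
  has_bi <- any(calls == "biallelic")
  if (has_a && has_b) return(arme_levels[3])
  if ((has_a || has_b) && !has_bi) return(arme_levels[1])
  if (has_a || has_b) return(arme_levels[2])
  arme_levels[4]
}

#' aRME categories for every gene of a matrix
#'
#' @param matrix an [allelic_count_matrix()].
#' @param mono_threshold per-cell monoallelic ratio threshold.
#' @return data.frame `gene_id`, `category`; genes with no expressing cell
#'   are omitted.
#' @export
classify_arme_matrix <- function(matrix, mono_threshold = 0.95) {
  states <- cell_state_matrix(matrix, mono_threshold)
  expressed <- rowSums(states != "silent") > 0
  cats <- apply(states[expressed, , drop = FALSE], 1, classify_arme)
  data.frame(gene_id = matrix$genes$gene_id[expressed],
             category = unname(cats), stringsAsFactors = FALSE)
}

#' Cross-stage class trajectory table
#'
#' Tabulates how per-gene classes travel across stages (e.g. bursty in all
#' stages, constitutive only in the last), restricted to genes classified
#' in every stage.
#'
#' @param per_stage_classes named list (one element per stage, in order) of
#'   data.frames with `gene_id` and the class column.
#' @param class_col name of the class column (default `"burst_class"`).
#' @return list of class `class_crosstab`: `trajectories` (data.frame of
#'   trajectory string and gene count), `genes` (per-gene wide table), and
#'   for exactly two stages `table` (a contingency table stage1 x stage2).
#'   No shared genes gives an empty table with a warning.
#' @export
crosstab_classes <- function(per_stage_classes, class_col = "burst_class") {
  if (length(per_stage_classes) < 2)
    stop_config("crosstab_classes needs >= 2 stages")
  stages <- names(per_stage_classes) %||%
    paste0("stage", seq_along(per_stage_classes))
  shared <- Reduce(intersect, lapply(per_stage_classes, `[[`, "gene_id"))
  if (length(shared) == 0) {
    warning("no genes shared across all stages")
    return(structure(list(trajectories = data.frame(trajectory = character(0),
                                                    n = integer(0)),
                          genes = data.frame(gene_id = character(0))),
                     class = "class_crosstab"))
  }
  wide <- data.frame(gene_id = shared, stringsAsFactors = FALSE)
  for (i in seq_along(per_stage_classes)) {
    df <- per_stage_classes[[i]]
    wide[[stages[i]]] <- df[[class_col]][match(shared, df$gene_id)]
  }
  traj <- apply(wide[stages], 1, paste, collapse = " -> ")
  tab <- sort(table(traj), decreasing = TRUE)
  out <- list(trajectories = data.frame(trajectory = names(tab),
                                        n = as.integer(tab),
                                        stringsAsFactors = FALSE),
              genes = wide)
  if (length(stages) == 2)
    out$table <- table(wide[[stages[1]]], wide[[stages[2]]],
                       dnn = stages[1:2])
  structure(out, class = "class_crosstab")
}

#' @export
print.class_crosstab <- function(x, ...) {
  cat("class trajectories across stages:\n")
  print(x$trajectories, row.names = FALSE)
  invisible(x)
}
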