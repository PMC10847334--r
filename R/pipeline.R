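#' Pipeline configuration
#'
#' Collects every stage threshold of the analysis in one validated object.
#' Values can come from a YAML file ([read_pipeline_config()]); arguments
#' given here override file values.
#'
#' @param min_snps,min_reads_per_snp informative-SNP filters
#'   (see [aggregate_snp_to_gene()]).
#' @param min_cell_fraction,min_mean_rpkm expression filters
#'   (see [filter_expressed()]).
#' @param mono_threshold per-cell monoallelic ratio threshold.
#' @param silent_frac,mono_gene_frac,constitutive_frac gene classification
#'   thresholds (see [classify_gene_expression()]).
#' @param hc_threshold,band coordination thresholds
#'   (see [classify_coordination()]).
#' @param kinetics_min_cells,bootstrap_B kinetics settings; `bootstrap_B = 0`
#'   skips the allelic-difference bootstrap.
#' @param flank_bp metaprofile flank length in bp.
#' @param seed integer seed for all stochastic steps.
#' @param outdir output directory for [run_pipeline()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_snps = 2L, min_reads_per_snp = 3L,
                            min_cell_fraction = 0.27, min_mean_rpkm = 10,
                            mono_threshold = 0.95,
                            silent_frac = 0.05, mono_gene_frac = 0.95,
                            constitutive_frac = 0.95,
                            hc_threshold = 0.90, band = 0.05,
                            kinetics_min_cells = 50L, bootstrap_B = 0L,
                            flank_bp = 3000L,
                            seed = 1L, outdir = "coburst_out") {
  cfg <- list(min_snps = as.integer(min_snps),
              min_reads_per_snp = as.integer(min_reads_per_snp),
              min_cell_fraction = min_cell_fraction,
              min_mean_rpkm = min_mean_rpkm,
              mono_threshold = mono_threshold,
              silent_frac = silent_frac,
              mono_gene_frac = mono_gene_frac,
              constitutive_frac = constitutive_frac,
              hc_threshold = hc_threshold,
              band = band,
              kinetics_min_cells = as.integer(kinetics_min_cells),
              bootstrap_B = as.integer(bootstrap_B),
              flank_bp = as.integer(flank_bp),
              seed = as.integer(seed),
              outdir = outdir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  check_fraction(cfg$min_cell_fraction, "min_cell_fraction")
  check_fraction(cfg$mono_threshold, "mono_threshold")
  check_fraction(cfg$silent_frac, "silent_frac")
  check_fraction(cfg$mono_gene_frac, "mono_gene_frac")
  check_fraction(cfg$constitutive_frac, "constitutive_frac")
  check_fraction(cfg$hc_threshold, "hc_threshold")
  check_fraction(cfg$band, "band")
  if (cfg$min_snps < 1 || cfg$min_reads_per_snp < 0)
    stop_config("SNP filters out of range")
  if (cfg$min_mean_rpkm < 0) stop_config("min_mean_rpkm must be >= 0")
  if (cfg$bootstrap_B < 0) stop_config("bootstrap_B must be >= 0")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take the
#' documented defaults, unknown keys are an error.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  vals[names(list(...))] <- list(...)
  do.call(pipeline_config, vals)
}

#' Run the full per-stage analysis pipeline
#'
#' For every stage (taken from the cell metadata `stage` column):
#' RPKM-normalise, filter expressed genes, classify genes
#' (silent/monoallelic/biallelic, bursty/constitutive, aRME categories),
#' estimate allelic burst kinetics for the bursty genes, compute p0/p2
#' coordination records, and compare expression between coordination
#' categories. With more than one stage, cross-stage trajectory tables are
#' produced for the burst class and the coordination category. All tables
#' are written as TSV under `config$outdir` together with a manifest
#' recording the configuration, its hash and the output file hashes;
#' identical input + config + seed reproduce byte-identical outputs.
#'
#' @param input an [allelic_count_matrix()] (cells of all stages), or a SNP
#'   read table data.frame (aggregated first with the configured filters).
#' @param config a `pipeline_config`.
#' @param gene_meta,cell_meta metadata passed to [aggregate_snp_to_gene()]
#'   when `input` is a SNP table.
#' @return list of class `pipeline_result`: per-stage results
#'   (`stages`), cross-stage tables (`crosstabs`), and the manifest.
#'   Stages ending with zero retained genes are skipped with a message;
#'   only all stages empty is an error.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         gene_meta = NULL, cell_meta = NULL) {
  validate_pipeline_config(config)
  if (is.data.frame(input)) {
    input <- aggregate_snp_to_gene(input, config$min_snps,
                                   config$min_reads_per_snp,
                                   gene_meta = gene_meta,
                                   cell_meta = cell_meta)
  }
  stopifnot(inherits(input, "allelic_count_matrix"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- unique(input$cells$stage)
  results <- list()
  for (st in stages) {
    res <- run_stage(input[, input$cells$stage == st], st, config)
    if (!is.null(res)) results[[st]] <- res
  }
  if (length(results) == 0)
    stop_config("all stages ended with zero retained genes")

  crosstabs <- list()
  if (length(results) >= 2) {
    classes <- lapply(results, `[[`, "classes")
    crosstabs$burst_class <- crosstab_classes(classes, "burst_class")
    coords <- lapply(results, function(r)
      data.frame(gene_id = r$coordination$gene_id,
                 category = r$coordination$category))
    coords <- Filter(function(d) nrow(d) > 0, coords)
    if (length(coords) >= 2)
      crosstabs$coordination <- crosstab_classes(coords, "category")
    for (nm in names(crosstabs))
      write_tsv_file(crosstabs[[nm]]$trajectories,
                     file.path(config$outdir,
                               sprintf("crosstab_%s.tsv", nm)))
  }

  manifest <- write_manifest(config, results)
  structure(list(stages = results, crosstabs = crosstabs,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}

run_stage <- function(acm, stage, config) {
  message(sprintf("[coburst] stage %s: %d genes x %d cells", stage,
                  nrow(acm$counts_A), ncol(acm$counts_A)))
  rpkm <- withCallingHandlers(
    rpkm_normalize(acm),
    warning = function(w) {
      message(sprintf("[coburst] stage %s: %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  if (ncol(rpkm$total) == 0) {
    message(sprintf("[coburst] stage %s skipped: no cell with reads", stage))
    return(NULL)
  }
  rpkm_f <- filter_expressed(rpkm, config$min_cell_fraction,
                             config$min_mean_rpkm)
  if (nrow(rpkm_f$total) == 0) {
    message(sprintf("[coburst] stage %s skipped: no gene passed the expression filters",
                    stage))
    return(NULL)
  }
  acm_f <- subset_to_filtered(acm, rpkm_f)
  classes <- classify_gene_expression(acm_f, config$silent_frac,
                                      config$mono_gene_frac,
                                      config$constitutive_frac,
                                      config$mono_threshold)
  arme <- classify_arme_matrix(acm_f, config$mono_threshold)
  bursty <- classes$gene_id[classes$burst_class == "bursty"]

  kinetics <- NULL
  if (length(bursty) > 0)
    kinetics <- allelic_kinetics(acm_f, bursty, B = config$bootstrap_B,
                                 min_cells = config$kinetics_min_cells,
                                 seed = config$seed)
  coordination <- if (length(bursty) > 0)
    coordination_records(acm_f, bursty, config$hc_threshold, config$band)
  else data.frame()

  expression <- NULL
  if (nrow(coordination) > 0 &&
      length(unique(coordination$category)) >= 2) {
    expression <- withCallingHandlers(
      tryCatch(
        expression_by_category(rpkm_f,
                               coordination[, c("gene_id", "category")]),
        error = function(e) NULL),
      warning = function(w) {
        message(sprintf("[coburst] stage %s: %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  sd <- file.path(config$outdir, stage)
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(classes, file.path(sd, "gene_classes.tsv"))
  write_tsv_file(arme, file.path(sd, "arme_categories.tsv"))
  if (!is.null(kinetics))
    write_tsv_file(kinetics$table, file.path(sd, "allelic_kinetics.tsv"))
  if (nrow(coordination) > 0)
    write_tsv_file(coordination, file.path(sd, "coordination.tsv"))
  if (!is.null(expression)) {
    write_tsv_file(expression$tests, file.path(sd, "expression_tests.tsv"))
    write_tsv_file(expression$summary, file.path(sd, "expression_summary.tsv"))
  }
  list(stage = stage, n_genes = nrow(rpkm_f$total),
       classes = classes, arme = arme, kinetics = kinetics,
       coordination = coordination, expression = expression)
}

write_manifest <- function(config, results) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE,
                      pattern = "\\.tsv$")
  manifest <- list(
    package = "coburst",
    version = as.character(utils::packageVersion("coburst")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    config_md5 = cfg_hash,
    stages = names(results),
    outputs = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d stage(s): %s\n", length(x$stages),
              paste(names(x$stages), collapse = ", ")))
  for (r in x$stages) {
    n_bursty <- sum(r$classes$burst_class == "bursty")
    cat(sprintf("  %s: %d genes retained, %d bursty", r$stage, r$n_genes,
                n_bursty))
    if (nrow(r$coordination) > 0)
      cat(sprintf(", coordination: %s",
                  paste(sprintf("%s=%d", names(table(r$coordination$category)),
                                table(r$coordination$category)),
                        collapse = " ")))
    cat("\n")
  }
  invisible(x)
}
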