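#' Pipeline configuration
#'
#' Single flat list of every stage parameter, with the printed operating
#' points of the analysis as defaults: QC at 500 genes / 1,000 UMIs /
#' 20% mitochondrial, dropout threshold 0.5, deconvolution size factors,
#' k = 2 metabolic clusters, 10 PCs and resolution 0.1 for
#' re-clustering, min.pct 0.25 and log2FC 0.25 for markers, signature
#' size 8, minprop 0.1 for the survival cutpoint. Unknown keys are
#' rejected by [validate_pipeline_config()].
#'
#' @param ... overrides of the defaults (see
#'   [validate_pipeline_config()] for the full key list).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(default_pipeline_config(), list(...))
  errs <- config_errors(cfg)
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "))
  class(cfg) <- "PipelineConfig"
  cfg
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    # synthetic input
    n_genes = 1000L, n_cells = 800L, n_cell_types = 4L, n_samples = 2L,
    n_pathways = 25L, genes_per_pathway = 8L, planted_fraction = 0.5,
    planted_boost = 3,
    # QC
    min_genes = 500L, min_umis = 1000L, max_mito = 0.20,
    # imputation
    impute = TRUE, drop_thre = 0.5,
    # normalization
    normalization = "deconvolution",
    # pathway activity
    n_perm = 200L, q_max = 0.05, outlier_rule = "iqr",
    # clustering
    k = 2L, n_pcs = 10L, resolution = 0.1,
    # markers / signature
    min_pct = 0.25, logfc_threshold = 0.25, signature_n = 8L,
    # survival
    bulk_n = 375L, bulk_hr = 2, bulk_censor = 0.3, minprop = 0.1,
    cutpoint_perm = 0L)
}

config_errors <- function(cfg) {
  defaults <- default_pipeline_config()
  errs <- character(0)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", "),
                           " (known: ", paste(names(defaults), collapse = ", "),
                           ")"))
  missing <- setdiff(names(defaults), names(cfg))
  if (length(missing))
    errs <- c(errs, paste0("missing key(s): ", paste(missing, collapse = ", ")))
  chk <- function(key, ok, msg)
    if (key %in% names(cfg) && !isTRUE(ok)) errs <<- c(errs, paste0(key, " ", msg))
  num1 <- function(key) key %in% names(cfg) &&
    is.numeric(cfg[[key]]) && length(cfg[[key]]) == 1L && is.finite(cfg[[key]])
  if (!num1("seed")) errs <- c(errs, "seed must be a single number")
  for (key in c("n_genes", "n_cells", "n_cell_types", "n_samples",
                "n_pathways", "genes_per_pathway", "min_genes", "min_umis",
                "n_perm", "k", "n_pcs", "signature_n", "bulk_n",
                "cutpoint_perm"))
    chk(key, num1(key) && cfg[[key]] >= 0 && cfg[[key]] == round(cfg[[key]]),
        "must be a non-negative integer")
  for (key in c("max_mito", "drop_thre", "planted_fraction", "q_max",
                "minprop", "bulk_censor"))
    chk(key, num1(key) && cfg[[key]] >= 0 && cfg[[key]] <= 1,
        "must be a fraction in [0,1]")
  for (key in c("planted_boost", "bulk_hr", "resolution"))
    chk(key, num1(key) && cfg[[key]] > 0, "must be positive")
  chk("normalization",
      cfg$normalization %in% c("deconvolution", "RLE", "TMM", "upperquartile"),
      "must be one of deconvolution/RLE/TMM/upperquartile")
  chk("outlier_rule", cfg$outlier_rule %in% c("iqr", "none"),
      "must be 'iqr' or 'none'")
  chk("impute", is.logical(cfg$impute) && length(cfg$impute) == 1L,
      "must be TRUE/FALSE")
  errs
}

#' Validate a pipeline configuration file (or list)
#'
#' Checks every parameter's type and range against the defaults and
#' rejects unknown keys; all problems are reported at once.
#'
#' @param config a YAML file path or a named list.
#' @return `TRUE` invisibly on success; otherwise an error listing every
#'   problem.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  cfg <- cfg[names(cfg) %in% union(names(default_pipeline_config()),
                                   names(config))]
  extra <- setdiff(names(config), names(default_pipeline_config()))
  errs <- config_errors(c(cfg, config[extra]))
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on a simulated dataset
#'
#' Executes simulate -> QC -> TPM -> (impute) -> size factors +
#' normalize -> cell-type pathway activity with permutation test ->
#' per-cell enrichment of malignant cells -> hierarchical high/low split
#' -> markers and signature -> bulk survival (cutpoint, KM/log-rank,
#' Cox), writing TSV outputs and a JSON manifest of content hashes to
#' `out_dir`. Every stage draws its randomness from `config$seed`, so a
#' re-run with the same config reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return the run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = unclass(config), stages = list(),
                   warnings = character(0))
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      outputs = files,
      md5 = as.list(tools::md5sum(files)))
  }

  sim <- simulate_counts(simulation_config(
    n_genes = config$n_genes, n_cells = config$n_cells,
    n_cell_types = config$n_cell_types, n_samples = config$n_samples,
    n_pathways = config$n_pathways,
    genes_per_pathway = config$genes_per_pathway,
    planted_split = list(fraction = config$planted_fraction,
                         boost = config$planted_boost),
    seed = config$seed))
  sim <- plant_metabolic_split(sim)
  sim_dir <- file.path(out_dir, "simulated")
  write_simulation(sim, sim_dir)
  note("simulate", file.path(sim_dir, c("matrix.mtx", "genes.tsv",
                                        "barcodes.tsv", "cell_metadata.tsv",
                                        "pathways.gmt", "gene_lengths.tsv")))

  qc <- qc_filter_cells(sim$counts,
                        qc_thresholds(config$min_genes, config$min_umis,
                                      config$max_mito))
  rep <- attr(qc, "qc_report")
  qc_file <- write_tsv(data.frame(metric = c("n_input", "n_kept",
                                             "removed_low_genes",
                                             "removed_low_umis",
                                             "removed_high_mito"),
                                  value = c(rep$n_input, rep$n_kept,
                                            rep$removed_low_genes,
                                            rep$removed_low_umis,
                                            rep$removed_high_mito)),
                       file.path(out_dir, "qc_report.tsv"))
  note("qc", qc_file)

  tpm <- counts_to_tpm(qc, sim$gene_lengths)
  expr <- tpm
  if (isTRUE(config$impute)) {
    model <- fit_dropout_model(tpm, tpm$annotation$sample)
    expr <- impute_dropouts(tpm, model, drop_thre = config$drop_thre)
  }
  sf <- size_factors(qc, method = config$normalization)
  norm <- normalize_counts(expr, sf)
  write_tsv(data.frame(cell_id = names(sf), size_factor = as.numeric(sf)),
            file.path(out_dir, "size_factors.tsv"))
  note("normalize", file.path(out_dir, "size_factors.tsv"))

  means <- celltype_means(norm)
  rel <- relative_expression(means)
  act <- pathway_scores(rel, sim$pathways, outlier_rule = config$outlier_rule)
  act <- permutation_test(norm, sim$pathways, act, n_perm = config$n_perm,
                          seed = config$seed)
  heat <- activity_heat_table(act, q_max = config$q_max)
  write_tsv(heat, file.path(out_dir, "pathway_activity.tsv"))
  note("score-pathways", file.path(out_dir, "pathway_activity.tsv"))

  mal <- which(norm$annotation$cell_type == "malignant")
  mal_log <- ExpressionMatrix(log1p(as.matrix(norm$values[, mal])),
                              norm$annotation[mal, , drop = FALSE],
                              units = "lognorm")
  sc <- gsva_scores(mal_log, sim$pathways)
  split <- label_high_low(hierarchical_split(sc, k = config$k), sc)
  write_tsv(data.frame(cell_id = names(split$labels),
                       metabolic_group = unname(split$labels)),
            file.path(out_dir, "metabolic_split.tsv"))
  note("cluster", file.path(out_dir, "metabolic_split.tsv"))

  de <- find_markers(mal_log, split$labels,
                     min_pct = config$min_pct,
                     logfc_threshold = config$logfc_threshold,
                     contrast = c("high", "low"))
  write_tsv(as.data.frame(de), file.path(out_dir, "markers.tsv"))
  sig <- top_n_signature(de, n = config$signature_n, direction = "up")
  write_gmt(stats::setNames(list(sig$genes), "high_metabolic_signature"),
            file.path(out_dir, "signature.gmt"))
  note("signature", file.path(out_dir, c("markers.tsv", "signature.gmt")))

  bulk <- simulate_bulk_survival(n_samples = config$bulk_n,
                                 signature = sig$genes,
                                 hazard_ratio = config$bulk_hr,
                                 censor_rate = config$bulk_censor,
                                 seed = config$seed)
  score <- score_bulk(bulk$expression, sig)
  cohort <- survival_cohort(score, bulk$cohort$time, bulk$cohort$event,
                            bulk$cohort[, c("age", "sex")])
  cp <- optimal_cutpoint(cohort, minprop = config$minprop,
                         n_perm_adjust = config$cutpoint_perm,
                         seed = config$seed)
  km <- km_logrank(cohort, cutpoint = cp$cutpoint)
  cox <- cox_multivariate(cohort, covariates = c("age", "sex"),
                          score_as = "group", cutpoint = cp$cutpoint)
  write_tsv(data.frame(sample_id = cohort$sample_id, score = cohort$score,
                       time = cohort$time, event = cohort$event,
                       group = ifelse(cohort$score > cp$cutpoint,
                                      "high", "low")),
            file.path(out_dir, "survival_cohort.tsv"))
  surv_summary <- data.frame(
    quantity = c("cutpoint", "logrank_chisq", "logrank_p",
                 "cox_group_hr", "cox_group_p"),
    value = c(cp$cutpoint, km$chisq, km$p,
              cox$hr[cox$term == "score_grouphigh"],
              cox$p[cox$term == "score_grouphigh"]))
  write_tsv(surv_summary, file.path(out_dir, "survival_summary.tsv"))
  note("survival", file.path(out_dir, c("survival_cohort.tsv",
                                        "survival_summary.tsv")))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
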