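#' Simulation configuration for the synthetic single-cell dataset
#'
#' Collects every knob of the droplet-count generator. Defaults describe
#' the scenario the rest of the package is validated on: 2,000 genes x
#' 2,000 cells across 4 samples; 4 cell types of which half the cells are
#' malignant; 50 metabolic pathways of 8 genes each with 25% of each
#' pathway's membership drawn from a shared pool (so 1/multiplicity
#' weights are exercised); log-normal library sizes; logistic dropout on
#' the latent mean; and a planted high/low metabolic split in the
#' malignant compartment (half the malignant cells, 3-fold boost).
#'
#' @param n_genes,n_cells,n_cell_types,n_samples,n_pathways,genes_per_pathway
#'   positive integer dimensions.
#' @param pathway_overlap_fraction fraction in `[0,1]` of each pathway's
#'   genes drawn from a pool shared across pathways.
#' @param activity_multipliers numeric `n_pathways x n_cell_types` matrix
#'   of positive fold factors applied to a pathway's genes in a cell
#'   type; default all 1 (no planted cell-type activity).
#' @param malignant_fraction fraction of cells of the malignant type
#'   (cell type 1); remaining cells are split evenly across the other
#'   types.
#' @param library_size_lognorm `c(mu, sigma)` of the log library size.
#' @param dropout_midpoint latent mean at which dropout probability is
#'   0.5.
#' @param dropout_slope positive slope of the logistic dropout curve.
#' @param dispersion_lognorm `c(mu, sigma)` of log gene-level NB
#'   dispersion.
#' @param planted_split list `(fraction, boost)`: fraction of malignant
#'   cells assigned to the high-metabolic program and the fold boost
#'   applied to metabolic-pathway genes in those cells.
#' @param mito_genes number of genes labelled with the mitochondrial
#'   prefix `MT-` (their expression is ordinary; the label exercises QC).
#' @param seed integer seed; identical config + seed reproduces the
#'   dataset bit-for-bit.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000L, n_cells = 2000L,
                              n_cell_types = 4L, n_samples = 4L,
                              n_pathways = 50L, genes_per_pathway = 8L,
                              pathway_overlap_fraction = 0.25,
                              activity_multipliers = NULL,
                              malignant_fraction = 0.5,
                              library_size_lognorm = c(mu = log(5000), sigma = 0.35),
                              dropout_midpoint = 0.7, dropout_slope = 1.5,
                              dispersion_lognorm = c(mu = log(0.2), sigma = 0.4),
                              planted_split = list(fraction = 0.5, boost = 3),
                              mito_genes = 20L, seed = 1L) {
  dims <- c(n_genes = n_genes, n_cells = n_cells, n_cell_types = n_cell_types,
            n_samples = n_samples, n_pathways = n_pathways,
            genes_per_pathway = genes_per_pathway)
  if (any(dims < 1L) || any(dims != round(dims)))
    stop("invalid config: all dimensions must be positive integers")
  if (pathway_overlap_fraction < 0 || pathway_overlap_fraction > 1)
    stop("invalid config: pathway_overlap_fraction must be in [0,1]")
  if (is.null(activity_multipliers))
    activity_multipliers <- matrix(1, n_pathways, n_cell_types)
  activity_multipliers <- as.matrix(activity_multipliers)
  if (!all(dim(activity_multipliers) == c(n_pathways, n_cell_types)))
    stop("invalid config: activity_multipliers must be n_pathways x n_cell_types")
  if (any(activity_multipliers <= 0))
    stop("invalid config: all fold factors must be > 0")
  if (malignant_fraction <= 0 || malignant_fraction >= 1)
    stop("invalid config: malignant_fraction must be in (0,1)")
  if (dropout_slope <= 0 || dropout_midpoint <= 0)
    stop("invalid config: dropout curve parameters must be positive")
  if (!is.list(planted_split) ||
      is.null(planted_split$fraction) || is.null(planted_split$boost))
    stop("invalid config: planted_split needs fields 'fraction' and 'boost'")
  if (planted_split$fraction < 0 || planted_split$fraction > 1)
    stop("invalid config: planted_split$fraction must be in [0,1]")
  if (planted_split$boost <= 0)
    stop("invalid config: planted_split$boost must be > 0")
  if (n_pathways * genes_per_pathway > n_genes)
    stop("invalid config: pathway genes exceed n_genes")
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              n_cell_types = as.integer(n_cell_types),
              n_samples = as.integer(n_samples),
              n_pathways = as.integer(n_pathways),
              genes_per_pathway = as.integer(genes_per_pathway),
              pathway_overlap_fraction = pathway_overlap_fraction,
              activity_multipliers = activity_multipliers,
              malignant_fraction = malignant_fraction,
              library_size_lognorm = unname(library_size_lognorm),
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope,
              dispersion_lognorm = unname(dispersion_lognorm),
              planted_split = planted_split,
              mito_genes = as.integer(mito_genes),
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# pathway membership with controlled overlap: each pathway takes
# round(f * gpp) genes from a shared pool, the rest are exclusive
build_pathways <- function(cfg, gene_ids) {
  gpp <- cfg$genes_per_pathway
  n_shared <- round(cfg$pathway_overlap_fraction * gpp)
  pool_size <- max(n_shared, ceiling(n_shared * cfg$n_pathways / 3))
  pool_size <- min(pool_size, length(gene_ids))
  shared_pool <- gene_ids[seq_len(pool_size)]
  cursor <- pool_size
  sets <- vector("list", cfg$n_pathways)
  classes <- kegg_metabolic_classes()
  for (p in seq_len(cfg$n_pathways)) {
    n_excl <- gpp - n_shared
    excl <- gene_ids[cursor + seq_len(n_excl)]
    cursor <- cursor + n_excl
    sh <- if (n_shared > 0) sample(shared_pool, n_shared) else character(0)
    sets[[p]] <- c(sh, excl)
  }
  names(sets) <- sprintf("pathway%02d", seq_len(cfg$n_pathways))
  category <- classes[((seq_len(cfg$n_pathways) - 1L) %% length(classes)) + 1L]
  names(category) <- names(sets)
  list(collection = PathwayCollection(sets, category),
       n_pathway_genes = cursor)
}

logistic_dropout_prob <- function(mu, midpoint, slope) {
  1 / (1 + (pmax(mu, 1e-12) / midpoint)^slope)
}

#' Simulate a droplet scRNA-seq count matrix with known ground truth
#'
#' Draws UMI-like counts per gene and cell from a negative binomial with
#' mean = base expression x pathway-activity multiplier of the cell's
#' type x cell size factor, gene-level dispersions sampled log-normal.
#' Entries are then zeroed with a logistic dropout probability that
#' decreases in the latent mean (probability 0.5 at
#' `dropout_midpoint`). The full latent state is returned as ground
#' truth so downstream recovery can be scored.
#'
#' @param config a [simulation_config()].
#' @return list with elements:
#'   * `counts`: [ExpressionMatrix()] of observed counts with annotation
#'     columns `sample`, `condition`, `cell_type`;
#'   * `pathways`: the planted [PathwayCollection()];
#'   * `gene_lengths`: named vector of synthetic gene lengths (bases);
#'   * `truth`: list with `cell_type`, `sample`, `metabolic_group`
#'     (NA until [plant_metabolic_split()]), `pathway_activity`,
#'     `size_factor`, `latent_mean`, `latent_counts`, `dropout_mask`;
#'   * `config`: the config used.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  if (cfg$mito_genes > 0) {
    idx <- (cfg$n_genes - cfg$mito_genes + 1L):cfg$n_genes
    gene_ids[idx] <- sprintf("MT-gene%03d", seq_along(idx))
  }
  cell_ids <- sprintf("cell%05d", seq_len(cfg$n_cells))

  pw <- build_pathways(cfg, gene_ids)
  pc <- pw$collection

  # cell-type labels: type 1 is the malignant compartment
  type_names <- c("malignant",
                  sprintf("stromal%d", seq_len(max(0L, cfg$n_cell_types - 1L))))
  n_mal <- round(cfg$malignant_fraction * cfg$n_cells)
  n_rest <- cfg$n_cells - n_mal
  rest_types <- if (cfg$n_cell_types > 1L)
    rep(type_names[-1L], length.out = n_rest) else character(0)
  cell_type <- sample(c(rep("malignant", n_mal), rest_types))
  sample_lab <- sample(sprintf("S%02d", seq_len(cfg$n_samples)),
                       cfg$n_cells, replace = TRUE)

  # gene-level baseline relative abundance and NB dispersion
  base <- exp(stats::rnorm(cfg$n_genes, mean = 0, sd = 1.2))
  base <- base / sum(base)
  names(base) <- gene_ids
  disp <- exp(stats::rnorm(cfg$n_genes, cfg$dispersion_lognorm[1L],
                           cfg$dispersion_lognorm[2L]))

  # per-(gene, type) activity factor: product over pathways carrying the gene
  type_factor <- matrix(1, cfg$n_genes, cfg$n_cell_types,
                        dimnames = list(gene_ids, type_names))
  for (p in seq_len(cfg$n_pathways)) {
    g <- pc$pathways[[p]]
    for (t in seq_len(cfg$n_cell_types))
      type_factor[g, t] <- type_factor[g, t] * cfg$activity_multipliers[p, t]
  }

  lib <- exp(stats::rnorm(cfg$n_cells, cfg$library_size_lognorm[1L],
                          cfg$library_size_lognorm[2L]))
  size_factor <- lib / exp(mean(log(lib)))
  names(size_factor) <- cell_ids

  type_idx <- match(cell_type, type_names)
  latent_mean <- (base * type_factor[, type_idx, drop = FALSE]) *
    rep(lib, each = cfg$n_genes)
  dimnames(latent_mean) <- list(gene_ids, cell_ids)

  latent_counts <- matrix(
    stats::rnbinom(length(latent_mean), mu = latent_mean,
                   size = rep(1 / disp, times = cfg$n_cells)),
    cfg$n_genes, cfg$n_cells, dimnames = dimnames(latent_mean))

  pdrop <- logistic_dropout_prob(latent_mean, cfg$dropout_midpoint,
                                 cfg$dropout_slope)
  mask <- matrix(stats::runif(length(pdrop)) < pdrop, cfg$n_genes, cfg$n_cells) &
    latent_counts > 0L
  observed <- latent_counts
  observed[mask] <- 0L

  ann <- data.frame(sample = sample_lab, condition = "tumor",
                    cell_type = cell_type, row.names = cell_ids,
                    stringsAsFactors = FALSE)
  gene_lengths <- round(exp(stats::rnorm(cfg$n_genes, log(2000), 0.6))) + 200
  names(gene_lengths) <- gene_ids

  truth <- list(cell_type = stats::setNames(cell_type, cell_ids),
                sample = stats::setNames(sample_lab, cell_ids),
                metabolic_group = stats::setNames(rep(NA_character_, cfg$n_cells),
                                                  cell_ids),
                pathway_activity = cfg$activity_multipliers,
                size_factor = size_factor,
                latent_mean = latent_mean,
                latent_counts = latent_counts,
                dropout_mask = Matrix::Matrix(mask, sparse = TRUE),
                base_expression = base,
                dispersion = stats::setNames(disp, gene_ids))
  list(counts = ExpressionMatrix(observed, ann, units = "counts"),
       pathways = pc, gene_lengths = gene_lengths, truth = truth,
       config = cfg)
}

#' Plant a high/low metabolic split in the malignant compartment
#'
#' Multiplies the latent means of all metabolic-pathway genes by
#' `boost` in a randomly chosen fraction of malignant cells, redraws the
#' affected counts (same dispersions, dropout re-applied at the boosted
#' mean), and records the planted labels in
#' `truth$metabolic_group` ("high"/"low" for malignant cells).
#'
#' With `fraction = 0` every malignant cell is labelled "low" and the
#' matrix is returned unchanged; with `boost = 1` the groups are
#' statistically indistinguishable by construction.
#'
#' @param sim output of [simulate_counts()].
#' @param fraction,boost override the config's `planted_split`.
#' @return `sim` with updated `counts` and `truth`.
#' @export
plant_metabolic_split <- function(sim, fraction = NULL, boost = NULL) {
  cfg <- sim$config
  if (is.null(fraction)) fraction <- cfg$planted_split$fraction
  if (is.null(boost)) boost <- cfg$planted_split$boost
  if (boost <= 0) stop("invalid config: boost must be > 0")
  if (fraction < 0 || fraction > 1)
    stop("invalid config: fraction must be in [0,1]")
  set.seed(cfg$seed + 104729L)  # dedicated substream for the split

  mal <- names(sim$truth$cell_type)[sim$truth$cell_type == "malignant"]
  if (!length(mal)) stop("no malignant cells designated in the dataset")
  grp <- stats::setNames(rep("low", length(mal)), mal)
  n_high <- round(fraction * length(mal))
  high <- if (n_high > 0) sample(mal, n_high) else character(0)
  grp[high] <- "high"
  sim$truth$metabolic_group[mal] <- grp

  if (length(high) && boost != 1) {
    genes <- sim$pathways$universe
    lm <- sim$truth$latent_mean
    lm[genes, high] <- lm[genes, high] * boost
    sim$truth$latent_mean <- lm
    # redraw the boosted block with the gene dispersions of the base draw
    disp_all <- sim$truth$dispersion
    block_mu <- lm[genes, high, drop = FALSE]
    block <- matrix(stats::rnbinom(length(block_mu), mu = block_mu,
                                   size = rep(1 / disp_all[genes],
                                              times = length(high))),
                    nrow = length(genes),
                    dimnames = dimnames(block_mu))
    pdrop <- logistic_dropout_prob(block_mu, cfg$dropout_midpoint,
                                   cfg$dropout_slope)
    bmask <- matrix(stats::runif(length(pdrop)) < pdrop, nrow(block_mu)) &
      block > 0L
    lc <- sim$truth$latent_counts
    lc[genes, high] <- block
    sim$truth$latent_counts <- lc
    dm <- as.matrix(sim$truth$dropout_mask)
    dm[genes, high] <- bmask
    sim$truth$dropout_mask <- Matrix::Matrix(dm, sparse = TRUE)
    block[bmask] <- 0L
    v <- as.matrix(sim$counts$values)
    v[genes, high] <- block
    sim$counts <- ExpressionMatrix(v, sim$counts$annotation, units = "counts")
  }
  sim$truth$planted_split <- list(fraction = fraction, boost = boost)
  sim
}

#' Simulate a bulk expression cohort with threshold-dependent survival
#'
#' Each sample carries a latent signature activity `s ~ N(0,1)`;
#' signature genes track `s` (log-scale shift), background genes are
#' independent noise. Event times are exponential with hazard
#' `h0 * HR^{1[s > cutpoint]} * exp(beta . covariates)`; censoring times
#' are independent exponentials calibrated to the requested censoring
#' fraction (none when `censor_rate = 0`).
#'
#' The default cohort size mirrors a typical public gastric-cancer bulk
#' cohort (375 tumour samples).
#'
#' @param n_samples cohort size.
#' @param signature character vector of signature gene ids (must be
#'   non-empty); background genes are added up to `n_genes`.
#' @param n_genes total genes in the bulk matrix.
#' @param cutpoint threshold on the latent score above which the hazard
#'   is multiplied by `hazard_ratio`.
#' @param hazard_ratio positive fold change in hazard for the high group.
#' @param censor_rate target fraction censored, in `[0, 1)`.
#' @param covariate_effects named numeric vector of log-hazard effects
#'   for covariates `age` (per year, centred at 65) and `sexM`
#'   (male vs female); `NULL` for no covariates.
#' @param baseline_hazard events per day in the reference group.
#' @param seed integer seed.
#' @return list with `cohort` (data.frame: sample_id, time, event, age,
#'   sex, true_score, true_group), `expression` ([ExpressionMatrix()],
#'   log-scale intensities), and `truth` (cutpoint, hazard_ratio,
#'   covariate_effects).
#' @export
simulate_bulk_survival <- function(n_samples = 375L, signature,
                                   n_genes = 1000L, cutpoint = 0,
                                   hazard_ratio = 2, censor_rate = 0.3,
                                   covariate_effects = NULL,
                                   baseline_hazard = log(2) / 730,
                                   seed = 1L) {
  if (missing(signature) || !length(signature))
    stop("invalid config: signature must be a non-empty gene list")
  if (hazard_ratio <= 0) stop("invalid config: hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("invalid config: censor_rate must be in [0, 1)")
  set.seed(seed)
  signature <- unique(as.character(signature))
  n_bg <- max(0L, n_genes - length(signature))
  genes <- c(signature, sprintf("bulkgene%05d", seq_len(n_bg)))
  samples <- sprintf("T%04d", seq_len(n_samples))

  s <- stats::rnorm(n_samples)
  expr <- matrix(stats::rnorm(length(genes) * n_samples, mean = 5, sd = 1),
                 length(genes), n_samples, dimnames = list(genes, samples))
  expr[signature, ] <- expr[signature, ] +
    matrix(s, length(signature), n_samples, byrow = TRUE) * 1.5

  age <- round(stats::rnorm(n_samples, 65, 10))
  sex <- sample(c("F", "M"), n_samples, replace = TRUE)
  lp <- 0
  if (!is.null(covariate_effects)) {
    if (!is.null(covariate_effects["age"]) && !is.na(covariate_effects["age"]))
      lp <- lp + covariate_effects[["age"]] * (age - 65)
    if (!is.null(covariate_effects["sexM"]) && !is.na(covariate_effects["sexM"]))
      lp <- lp + covariate_effects[["sexM"]] * (sex == "M")
  }
  high <- s > cutpoint
  hazard <- baseline_hazard * ifelse(high, hazard_ratio, 1) * exp(lp)
  t_event <- stats::rexp(n_samples, rate = hazard)
  if (censor_rate > 0) {
    cens_rate <- mean(hazard) * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n_samples, rate = cens_rate)
  } else {
    t_cens <- rep(Inf, n_samples)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  cohort <- data.frame(sample_id = samples, time = time, event = event,
                       age = age, sex = sex, true_score = s,
                       true_group = ifelse(high, "high", "low"),
                       stringsAsFactors = FALSE)
  ann <- data.frame(sample = samples, condition = "tumor",
                    cell_type = "bulk", row.names = samples,
                    stringsAsFactors = FALSE)
  list(cohort = cohort,
       expression = ExpressionMatrix(expr - min(expr), ann, units = "normalized"),
       truth = list(cutpoint = cutpoint, hazard_ratio = hazard_ratio,
                    covariate_effects = covariate_effects))
}

#' Write a simulated dataset to disk in standard formats
#'
#' MTX + sidecars + cell metadata for the counts, GMT for the planted
#' pathways, TSV for gene lengths.
#'
#' @param sim output of [simulate_counts()] / [plant_metabolic_split()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$counts, dir, format = "mtx")
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  utils::write.table(
    data.frame(gene_id = names(sim$gene_lengths), length = sim$gene_lengths),
    file.path(dir, "gene_lengths.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
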