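# a tiny matrix with controllable QC properties
qc_toy <- function() {
  set.seed(21)
  n_genes <- 600
  genes <- c(sprintf("gene%03d", 1:(n_genes - 5)), sprintf("MT-g%d", 1:5))
  v <- matrix(rpois(n_genes * 6, 3), n_genes, 6,
              dimnames = list(genes, sprintf("c%d", 1:6)))
  v[, 1][v[, 1] > 0][1:50] <- 0                    # will trim below
  ExpressionMatrix(v)
}

test_that("QC keeps cells at the inclusive boundaries and removes below them", {
  genes <- c(sprintf("gene%03d", 1:600), "MT-g1")
  base <- rep(0L, 601); names(base) <- genes

  mk <- function(n_detected, umis, mito) {
    x <- base
    per <- umis - mito
    picked <- seq_len(n_detected - 1L)
    x[picked] <- c(per - (n_detected - 2L), rep(1L, n_detected - 2L))
    x["MT-g1"] <- mito
    x
  }
  # boundary cell: exactly 500 detected (incl mito gene), 1000 UMIs, 20% mito
  at <- mk(500, 1000, 200)
  low_genes <- mk(499, 1000, 200)
  high_mito <- mk(500, 1000, 250)
  low_umis <- mk(500, 999, 199)
  v <- cbind(at = at, low_genes = low_genes, high_mito = high_mito,
             low_umis = low_umis)
  kept <- qc_filter_cells(ExpressionMatrix(v))
  expect_identical(colnames(kept$values), "at")
  rep <- attr(kept, "qc_report")
  expect_equal(rep$removed_low_genes, 1)
  expect_equal(rep$removed_high_mito, 1)
  expect_equal(rep$removed_low_umis, 1)
})

test_that("QC is idempotent and errors when nothing survives", {
  sim <- simulate_counts(simulation_config(n_genes = 800, n_cells = 100,
                                           n_cell_types = 2, n_samples = 1,
                                           n_pathways = 5,
                                           genes_per_pathway = 5, seed = 2))
  once <- qc_filter_cells(sim$counts)
  twice <- qc_filter_cells(once)
  expect_identical(colnames(once$values), colnames(twice$values))
  expect_equal(attr(twice, "qc_report")$n_kept,
               attr(twice, "qc_report")$n_input)
  expect_error(qc_filter_cells(sim$counts,
                               qc_thresholds(min_umis = 10^9)),
               "every cell")
})

test_that("dropout model: constant positive gene gets d ~ 0, all-zero gene d = 1", {
  n <- 40
  set.seed(3)
  v <- rbind(flat = rep(50, n),
             dead = rep(0, n),
             bimodal = c(rep(0, 22), rpois(18, 60)))  # zero rate > 1/2: candidate
  colnames(v) <- sprintf("c%02d", 1:n)
  rownames(v) <- c("flat", "dead", "bimodal")
  x <- ExpressionMatrix(v, units = "TPM")
  m <- fit_dropout_model(x, rep("s1", n), min_cells = 10)
  expect_true(all(m$d["flat", ] == 0))        # zero rate 0: not a candidate
  expect_true(all(m$d["dead", ] == 1))
  expect_true("dead" %in% m$per_group$s1$unimputable)
  expect_true(all(m$d["bimodal", v["bimodal", ] == 0] > 0.5))
  expect_true(all(m$d["bimodal", v["bimodal", ] > 0] < 0.5))
})

test_that("estimated dropout rate recovers a planted logistic dropout", {
  # tight dispersions + high dropout midpoint: zeros among candidate genes
  # are dominated by dropout, not negative-binomial sampling zeros, so the
  # mixture's dropout calls are comparable to the planted mask
  cfg <- simulation_config(n_genes = 300, n_cells = 200, n_cell_types = 2,
                           n_samples = 1, n_pathways = 5,
                           genes_per_pathway = 5,
                           library_size_lognorm = c(log(20000), 0.2),
                           dispersion_lognorm = c(log(0.1), 0.2),
                           dropout_midpoint = 20, dropout_slope = 2,
                           seed = 31)
  sim <- simulate_counts(cfg)
  tpm <- counts_to_tpm(sim$counts, sim$gene_lengths)
  m <- fit_dropout_model(tpm, sim$truth$sample)
  mask <- as.matrix(sim$truth$dropout_mask)
  cand <- m$per_group$S01$candidates
  cand <- setdiff(cand, m$per_group$S01$unimputable)
  skip_if(length(cand) < 20, "too few candidate genes in this draw")
  true_rate <- mean(mask[cand, ])
  est_rate <- mean(m$d[cand, ] > 0.5)
  expect_lt(abs(est_rate - true_rate), 0.10)
})

test_that("imputation never alters reliable entries and only fills dropouts", {
  cfg <- simulation_config(n_genes = 400, n_cells = 120, n_cell_types = 2,
                           n_samples = 1, n_pathways = 5,
                           genes_per_pathway = 5, dropout_midpoint = 2,
                           seed = 13)
  sim <- simulate_counts(cfg)
  tpm <- counts_to_tpm(sim$counts, sim$gene_lengths)
  m <- fit_dropout_model(tpm, sim$truth$sample)
  imp <- impute_dropouts(tpm, m, drop_thre = 0.5)
  untouched <- m$d <= 0.5
  expect_identical(as.matrix(imp$values)[untouched],
                   as.matrix(tpm$values)[untouched])
  expect_true(all(imp$values >= 0))
})

test_that("imputed values beat raw zeros on masked entries", {
  cfg <- simulation_config(n_genes = 400, n_cells = 150, n_cell_types = 2,
                           n_samples = 1, n_pathways = 5,
                           genes_per_pathway = 5,
                           dropout_midpoint = 4, dropout_slope = 2,
                           seed = 17)
  sim <- simulate_counts(cfg)
  tpm <- counts_to_tpm(sim$counts, sim$gene_lengths)
  m <- fit_dropout_model(tpm, sim$truth$sample)
  imp <- impute_dropouts(tpm, m, drop_thre = 0.5)
  # latent truth on the TPM scale
  lat_tpm <- counts_to_tpm(ExpressionMatrix(sim$truth$latent_counts,
                                            sim$counts$annotation),
                           sim$gene_lengths)
  mask <- as.matrix(sim$truth$dropout_mask) & m$d > 0.5
  skip_if(sum(mask) < 50, "too few imputable masked entries in this draw")
  truth_vals <- log1p(as.matrix(lat_tpm$values)[mask])
  imp_vals <- log1p(as.matrix(imp$values)[mask])
  raw_vals <- log1p(as.matrix(tpm$values)[mask])
  rmse_imp <- sqrt(mean((imp_vals - truth_vals)^2))
  rmse_raw <- sqrt(mean((raw_vals - truth_vals)^2))
  expect_lt(rmse_imp, rmse_raw)
  expect_gt(suppressWarnings(cor(imp_vals, truth_vals)), 0)
})

test_that("dropout-free data yields almost no high dropout posteriors", {
  # dropout-free droplet data corresponds to deep sequencing; a deep
  # library keeps sampling zeros (which no per-entry mixture can tell
  # apart from dropouts) out of the way so the test isolates the
  # mixture's false-positive behaviour
  cfg <- simulation_config(n_genes = 600, n_cells = 150, n_cell_types = 2,
                           n_samples = 1, n_pathways = 5,
                           genes_per_pathway = 5,
                           library_size_lognorm = c(log(20000), 0.3),
                           dropout_midpoint = 1e-6, seed = 23)
  sim <- simulate_counts(cfg)  # midpoint ~ 0: logistic dropout never fires
  expect_equal(sum(sim$truth$dropout_mask), 0)
  tpm <- counts_to_tpm(sim$counts, sim$gene_lengths)
  m <- fit_dropout_model(tpm, sim$truth$sample)
  # all-zero genes are a flagged degenerate case (d = 1 by convention);
  # the type-I property concerns the fitted mixture on measurable genes
  measurable <- setdiff(rownames(tpm$values), m$per_group$S01$unimputable)
  expect_lt(mean(m$d[measurable, ] > 0.5), 0.02)
})

test_that("all size-factor methods return 1 for identical cells", {
  v <- matrix(rep(rpois(80, 10), 30), 80, 30,
              dimnames = list(rand_gene_names(80), sprintf("c%d", 1:30)))
  x <- ExpressionMatrix(v)
  for (meth in c("RLE", "upperquartile", "TMM", "deconvolution")) {
    f <- suppressWarnings(size_factors(x, meth))
    expect_equal(unname(as.numeric(f)), rep(1, 30), tolerance = 1e-6,
                 label = meth)
  }
})

test_that("RLE recovers a 3x scaled cell exactly; scaling is equivariant", {
  set.seed(5)
  base <- rpois(100, 20) + 1
  v <- cbind(c1 = base, c2 = base, c3 = base * 3, c4 = base)
  rownames(v) <- rand_gene_names(100)
  f <- size_factors(ExpressionMatrix(v), "RLE")
  expect_equal(unname(f["c3"] / f["c1"]), 3, tolerance = 1e-12)
  fu <- size_factors(ExpressionMatrix(v), "upperquartile")
  expect_equal(unname(fu["c3"] / fu["c1"]), 3, tolerance = 1e-12)
  # equivariance: scaling c2 by 5 scales its factor by 5
  v2 <- v; v2[, "c2"] <- v2[, "c2"] * 5
  f2 <- size_factors(ExpressionMatrix(v2), "RLE")
  expect_equal(unname(f2["c2"] / f2["c1"] / (f["c2"] / f["c1"])), 5,
               tolerance = 1e-12)
})

test_that("RLE agrees with the DESeq2 median-ratio reference", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  v <- matrix(rpois(200 * 20, 15) + 1, 200, 20,
              dimnames = list(rand_gene_names(200), sprintf("c%d", 1:20)))
  ours <- size_factors(ExpressionMatrix(v), "RLE")
  ref <- DESeq2::estimateSizeFactorsForMatrix(v)
  ref <- ref / exp(mean(log(ref)))
  # DESeq2 medians the log ratios (even-count averaging differs in the
  # 6th decimal from the median of plain ratios)
  expect_equal(unname(as.numeric(ours)), unname(ref), tolerance = 1e-4)
})

test_that("deconvolution recovers log-normal true factors without DE genes", {
  set.seed(8)
  n <- 500; G <- 600
  base <- rexp(G, 1 / 5)
  sf_true <- exp(rnorm(n, 0, 0.4))
  mu <- outer(base, sf_true)
  v <- matrix(rpois(G * n, mu), G, n,
              dimnames = list(rand_gene_names(G), sprintf("c%04d", 1:n)))
  f <- size_factors(ExpressionMatrix(v), "deconvolution")
  sf_norm <- sf_true / exp(mean(log(sf_true)))
  expect_gt(cor(as.numeric(f), sf_norm), 0.95)
  expect_lt(stats::median(abs(as.numeric(f) - sf_norm) / sf_norm), 0.05)
})

test_that("normalization divides by factors and log-transforms cleanly", {
  v <- matrix(c(2, 4, 3, 9), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  x <- ExpressionMatrix(v)
  f <- structure(c(2, 3), names = colnames(v), method = "manual",
                 class = c("SizeFactors", "numeric"))
  out <- normalize_counts(x, f)
  expect_equal(as.numeric(out$values), c(1, 2, 1, 3))
  expect_identical(normalize_counts(x, c(1, 1))$values, x$values)
  lg <- normalize_counts(x, c(1, 1), log_transform = TRUE)
  expect_equal(as.matrix(lg$values), log1p(v), ignore_attr = TRUE)
  zero <- ExpressionMatrix(matrix(0, 2, 2,
                                  dimnames = list(c("g1", "g2"),
                                                  c("c1", "c2"))))
  expect_true(all(normalize_counts(zero, c(1, 1),
                                   log_transform = TRUE)$values == 0))
  expect_error(normalize_counts(x, c(0, 1)), "positive")
})
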