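small_cfg <- function(...) {
  simulation_config(n_genes = 300L, n_cells = 200L, n_cell_types = 3L,
                    n_samples = 2L, n_pathways = 8L, genes_per_pathway = 6L,
                    seed = 42L, ...)
}

test_that("identical config and seed reproduce the dataset bit-for-bit", {
  a <- simulate_counts(small_cfg())
  b <- simulate_counts(small_cfg())
  expect_identical(as.matrix(a$counts$values), as.matrix(b$counts$values))
  expect_identical(a$truth$size_factor, b$truth$size_factor)
  expect_identical(a$pathways$pathways, b$pathways$pathways)
  pa <- plant_metabolic_split(a)
  pb <- plant_metabolic_split(b)
  expect_identical(as.matrix(pa$counts$values), as.matrix(pb$counts$values))
  expect_identical(pa$truth$metabolic_group, pb$truth$metabolic_group)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 0), "invalid config")
  expect_error(simulation_config(pathway_overlap_fraction = 1.2),
               "invalid config")
  expect_error(small_cfg(activity_multipliers =
                           matrix(-1, 8, 3)), "fold factors")
  expect_error(small_cfg(planted_split = list(fraction = 0.5, boost = 0)),
               "boost")
})

test_that("a planted activity multiplier shows up in latent group means", {
  mult <- matrix(1, 8, 3)
  mult[3, 1] <- 4  # pathway 3 boosted in the malignant type
  sim <- simulate_counts(small_cfg(activity_multipliers = mult))
  shared <- unique(unlist(sim$pathways$pathways[-3]))
  excl <- setdiff(sim$pathways$pathways[[3]], shared)
  mal <- sim$truth$cell_type == "malignant"
  lat <- sim$truth$latent_mean
  # compare per-cell mean of exclusive genes, scaled by size factor
  m_mal <- mean(lat[excl, mal] / rep(sim$truth$size_factor[mal],
                                     each = length(excl)))
  m_oth <- mean(lat[excl, !mal] / rep(sim$truth$size_factor[!mal],
                                      each = length(excl)))
  expect_equal(m_mal / m_oth, 4, tolerance = 1e-9)
})

test_that("null multipliers give pathway scores near parity downstream", {
  sim <- simulate_counts(small_cfg())
  norm <- normalize_counts(sim$counts, size_factors(sim$counts, "RLE"))
  act <- pathway_scores(relative_expression(celltype_means(norm)),
                        sim$pathways, outlier_rule = "none")
  expect_true(all(abs(act$score - 1) < 0.35, na.rm = TRUE))
  expect_lt(abs(mean(act$score, na.rm = TRUE) - 1), 0.1)
})

test_that("plant_metabolic_split boosts latent metabolic means by the stated fold", {
  sim <- simulate_counts(small_cfg())
  planted <- plant_metabolic_split(sim, fraction = 0.5, boost = 3)
  grp <- planted$truth$metabolic_group
  hi <- names(grp)[grp %in% "high"]; lo <- names(grp)[grp %in% "low"]
  genes <- planted$pathways$universe
  lat <- planted$truth$latent_mean
  sf <- planted$truth$size_factor
  ratio <- mean(sweep(lat[genes, hi], 2, sf[hi], "/")) /
    mean(sweep(lat[genes, lo], 2, sf[lo], "/"))
  expect_equal(ratio, 3, tolerance = 0.15)
})

test_that("fraction 0 labels every malignant cell low and changes nothing", {
  sim <- simulate_counts(small_cfg())
  planted <- plant_metabolic_split(sim, fraction = 0)
  grp <- planted$truth$metabolic_group
  mal <- planted$truth$cell_type == "malignant"
  expect_true(all(grp[mal] == "low"))
  expect_true(all(is.na(grp[!mal])))
  expect_identical(as.matrix(planted$counts$values),
                   as.matrix(sim$counts$values))
})

test_that("dropout mask only covers entries with positive pre-dropout counts", {
  sim <- simulate_counts(small_cfg())
  mask <- as.matrix(sim$truth$dropout_mask)
  expect_true(all(sim$truth$latent_counts[mask] > 0))
  obs <- as.matrix(sim$counts$values)
  expect_true(all(obs[mask] == 0))
  expect_identical(obs[!mask], sim$truth$latent_counts[!mask])
})

test_that("empirical dropout frequency decreases with latent mean (binned)", {
  sim <- simulate_counts(small_cfg())
  mask <- as.matrix(sim$truth$dropout_mask)
  mu <- sim$truth$latent_mean
  pos <- sim$truth$latent_counts > 0
  bins <- cut(log(mu[pos]), breaks = 8)
  rate <- tapply(mask[pos], bins, mean)
  rate <- rate[!is.na(rate)]
  inversions <- sum(diff(rate) > 0)
  expect_lte(inversions, 1)
})

test_that("expected library size tracks size factor times base total", {
  cfg <- simulation_config(n_genes = 2000L, n_cells = 300L,
                           n_cell_types = 3L, n_samples = 2L,
                           n_pathways = 10L, genes_per_pathway = 8L,
                           seed = 9L)
  sim <- simulate_counts(cfg)
  lat_lib <- colSums(sim$truth$latent_mean)
  pred <- sim$truth$size_factor * exp(cfg$library_size_lognorm[1])
  expect_lt(stats::median(abs(lat_lib - pred) / pred), 0.05)
})

test_that("bulk survival generator honours censoring and effect contracts", {
  sig <- sprintf("s%02d", 1:8)
  b0 <- simulate_bulk_survival(150, sig, censor_rate = 0, seed = 3)
  expect_true(all(b0$cohort$event == 1))
  expect_error(simulate_bulk_survival(100, character(0)), "signature")
  expect_error(simulate_bulk_survival(100, sig, hazard_ratio = 0),
               "hazard_ratio")
  expect_error(simulate_bulk_survival(100, sig, censor_rate = 1),
               "censor_rate")
  b <- simulate_bulk_survival(400, sig, censor_rate = 0.3, seed = 4)
  expect_gt(mean(b$cohort$event == 0), 0.15)
  expect_lt(mean(b$cohort$event == 0), 0.45)
  # signature genes track the latent score, background genes do not
  cors <- cor(t(as.matrix(b$expression$values[sig, ])), b$cohort$true_score)
  expect_true(all(cors > 0.5))
})

test_that("null hazard ratio keeps log-rank rejection near nominal", {
  reps <- 200
  pvals <- numeric(reps)
  sig <- sprintf("s%02d", 1:5)
  for (r in seq_len(reps)) {
    b <- simulate_bulk_survival(60, sig, n_genes = 5, hazard_ratio = 1,
                                censor_rate = 0.2, seed = 1000 + r)
    coh <- survival_cohort(b$cohort$true_score, b$cohort$time,
                           b$cohort$event)
    km <- km_logrank(coh, group = b$cohort$true_group)
    pvals[r] <- km$p
  }
  rej <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("write_simulation emits the standard file set", {
  d <- withr::local_tempdir()
  sim <- simulate_counts(small_cfg())
  write_simulation(sim, d)
  expect_true(all(file.exists(file.path(d,
    c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cell_metadata.tsv",
      "pathways.gmt", "gene_lengths.tsv")))))
  back <- read_expression(file.path(d, "matrix.mtx"), "mtx",
                          file.path(d, "cell_metadata.tsv"))
  expect_equal(as.matrix(back$values), as.matrix(sim$counts$values),
               tolerance = 1e-9, ignore_attr = TRUE)
})
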