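test_that("identical expression columns get identical per-cell scores", {
  set.seed(2)
  v <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(rand_gene_names(20), sprintf("c%d", 1:4)))
  v[, 3] <- v[, 1]
  pc <- PathwayCollection(list(S1 = rownames(v)[1:5],
                               S2 = rownames(v)[8:15]))
  sc <- gsva_scores(make_expr(v), pc)
  expect_equal(sc$scores[, 1], sc$scores[, 3], ignore_attr = TRUE)
})

test_that("a set of a cell's top-ranked genes scores strictly positive", {
  set.seed(3)
  v <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(rand_gene_names(10), sprintf("c%d", 1:6)))
  v[1:3, 1] <- v[1:3, 1] + 10   # top genes for cell 1
  pc <- PathwayCollection(list(top = rownames(v)[1:3]))
  sc <- gsva_scores(make_expr(v), pc)
  expect_gt(sc$scores["top", "c1"], 0)
})

test_that("per-cell scores match the brute-force kernel-CDF walk oracle", {
  set.seed(41)
  for (i in 1:100) {
    G <- sample(8:20, 1); n <- sample(3:5, 1)
    v <- matrix(rnorm(G * n, sd = runif(1, 0.5, 2)), G, n,
                dimnames = list(rand_gene_names(G), sprintf("c%d", 1:n)))
    n_sets <- sample(1:3, 1)
    sets <- lapply(seq_len(n_sets), function(s)
      sample(rownames(v), sample(3:(G - 1), 1)))
    names(sets) <- sprintf("S%d", seq_len(n_sets))
    got <- gsva_scores(make_expr(v), PathwayCollection(sets))$scores
    want <- oracle_gsva(v, sets)
    expect_equal(got, want[rownames(got), , drop = FALSE], tolerance = 1e-9,
                 label = sprintf("instance %d", i))
  }
})

test_that("scores are invariant to strictly monotone per-gene transforms", {
  set.seed(6)
  v <- matrix(rexp(15 * 8), 15, 8,
              dimnames = list(rand_gene_names(15), sprintf("c%d", 1:8)))
  pc <- PathwayCollection(list(S = rownames(v)[c(2, 5, 9, 12)]))
  a <- gsva_scores(make_expr(v), pc)$scores
  # same monotone map applied uniformly across cells preserves per-cell
  # rank order of the kernel statistics gene-by-gene? it preserves the
  # cross-cell ordering each z_ij is built from, hence the walks when the
  # map is affine; nonlinear maps change kernel overlaps, so test affine
  b <- gsva_scores(make_expr(3 * v + 2), pc)$scores
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("AUC ranking covers separation, ties and exhaustive enumeration", {
  v <- rbind(sep = c(3, 4, 1, 2),
             inter = c(1, 3, 2, 4),
             tie = c(1, 1, 1, 1))
  colnames(v) <- sprintf("c%d", 1:4)
  x <- make_expr(v)
  rk <- rank_genes_auc(x, c("c1", "c2"), c("c3", "c4"))
  expect_equal(rk$auc[rk$gene == "sep"], 1.0)
  expect_equal(rk$auc[rk$gene == "inter"], 0.25)
  expect_equal(rk$auc[rk$gene == "tie"], 0.5)
  # swapped groups: AUC -> 1 - AUC
  rk2 <- rank_genes_auc(x, c("c3", "c4"), c("c1", "c2"))
  expect_equal(rk$auc[order(rk$gene)] + rk2$auc[order(rk2$gene)],
               rep(1, 3))
})

test_that("AUC equals the exhaustive pair enumeration on random draws", {
  set.seed(13)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    v <- matrix(sample(0:5, 4 * (na + nb), replace = TRUE), 4,
                dimnames = list(rand_gene_names(4),
                                sprintf("c%d", 1:(na + nb))))
    rk <- rank_genes_auc(make_expr(v), seq_len(na), na + seq_len(nb))
    for (g in rownames(v))
      expect_equal(rk$auc[rk$gene == g],
                   oracle_auc(v[g, seq_len(na)], v[g, na + seq_len(nb)]),
                   tolerance = 1e-12)
  }
})

test_that("preranked GSEA matches the brute-force walk and the fgsea statistic", {
  set.seed(17)
  for (i in 1:25) {
    G <- sample(10:30, 1)
    ranked <- data.frame(gene = rand_gene_names(G),
                         stat = sort(rnorm(G), decreasing = TRUE))
    m <- sample(3:(G - 2), 1)
    set_genes <- sample(ranked$gene, m)
    pc <- PathwayCollection(list(S = set_genes))
    res <- preranked_gsea(ranked, pc, n_perm = 100, seed = 1)
    want <- oracle_gsea_es(ranked$stat, ranked$gene %in% set_genes)
    expect_equal(res$es, want, tolerance = 1e-12)
  }
  skip_if_not_installed("fgsea")
  set.seed(19)
  G <- 40
  ranked <- data.frame(gene = rand_gene_names(G),
                       stat = sort(rnorm(G), decreasing = TRUE))
  set_genes <- sample(ranked$gene, 8)
  res <- preranked_gsea(ranked, PathwayCollection(list(S = set_genes)),
                        n_perm = 100, seed = 1)
  stats_vec <- stats::setNames(ranked$stat, ranked$gene)
  ref <- fgsea::calcGseaStat(stats_vec,
                             selectedStats = match(set_genes, ranked$gene),
                             gseaParam = 1, scoreType = "std")
  expect_equal(res$es, unname(ref), tolerance = 1e-9)
})

test_that("GSEA edge cases: degenerate sets and ranking reversal", {
  ranked <- data.frame(gene = rand_gene_names(12),
                       stat = seq(2, -2, length.out = 12))
  all_genes <- PathwayCollection(list(S = ranked$gene))
  res <- preranked_gsea(ranked, all_genes, n_perm = 100, seed = 1)
  expect_true(is.na(res$es))  # every gene in the set: walk degenerate
  pc <- PathwayCollection(list(S = ranked$gene[1:4]))
  fwd <- preranked_gsea(ranked, pc, n_perm = 100, seed = 1)
  rev_ranked <- data.frame(gene = rev(ranked$gene), stat = rev(-ranked$stat))
  bwd <- preranked_gsea(rev_ranked, pc, n_perm = 100, seed = 1)
  expect_equal(fwd$es, -bwd$es, tolerance = 1e-12)
  expect_error(preranked_gsea(ranked,
                              PathwayCollection(list(S = c("zz1", "zz2",
                                                           "zz3"))),
                              n_perm = 100),
               "no set overlaps")
})

test_that("variance-inflated Wilcoxon flags a planted set and stays calibrated", {
  set.seed(23)
  G <- 300; n <- 500
  v <- matrix(rnorm(G * n), G, n,
              dimnames = list(rand_gene_names(G), sprintf("c%04d", 1:n)))
  clusters <- sample(rep(c("k1", "k2"), each = n / 2))
  planted <- rownames(v)[1:10]
  # a moderate shift: log2FCs separate completely at n = 500 while the planted
  # genes' inter-gene correlation (and hence the variance inflation
  # penalty) stays low
  v[planted, clusters == "k1"] <- v[planted, clusters == "k1"] + 1
  x <- make_expr(v - min(v))
  sets <- c(list(planted = planted),
            lapply(1:20, function(s) sample(rownames(v)[11:G], 10)))
  names(sets) <- c("planted", sprintf("null%02d", 1:20))
  res <- vi_wilcoxon_gene_set_test(x, clusters, PathwayCollection(sets))
  hit <- res[res$cluster == "k1" & res$pathway == "planted", ]
  expect_gt(hit$statistic, 0)
  expect_lt(hit$q, 0.05)
  null_p <- res$p[res$pathway != "planted"]
  expect_lte(mean(null_p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / length(null_p)))
})

test_that("identical clusters give zero log2FC and zero statistic", {
  v <- matrix(rep(rexp(50), 40), 50, 40,
              dimnames = list(rand_gene_names(50), sprintf("c%d", 1:40)))
  x <- make_expr(v)
  res <- vi_wilcoxon_gene_set_test(x, rep(c("a", "b"), 20),
                                   PathwayCollection(list(S = rownames(v)[1:6])))
  expect_equal(res$mean_logfc, rep(0, nrow(res)))
})
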