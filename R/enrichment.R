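# Row-wise Wilcoxon rank-sum with normal approximation + tie correction.
# Returns per row: AUC, U statistic, two-sided p.
row_wilcoxon <- function(v, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  res <- t(apply(v[, c(idx_a, idx_b), drop = FALSE], 1L, function(x) {
    r <- rank(x)
    ra <- sum(r[seq_len(na)])
    u <- ra - na * (na + 1) / 2
    auc <- u / (na * nb)
    n <- na + nb
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(c(auc, u, 1))
    zstat <- (u - na * nb / 2) / sqrt(sigma2)
    c(auc, u, 2 * stats::pnorm(-abs(zstat)))
  }))
  colnames(res) <- c("auc", "U", "p")
  res
}

#' Rank genes by AUC between two cell groups
#'
#' For each gene, `AUC = P(a > b) + 0.5 P(a = b)` for a random a-cell
#' and b-cell value, computed by rank sums. The ranking statistic is the
#' signed `AUC - 0.5`, sorted descending, ties broken by gene id
#' (lexicographic), so the order is strictly deterministic.
#'
#' @param expr an [ExpressionMatrix()].
#' @param group_a,group_b column ids or indices of the two groups.
#' @return object of class `RankedGeneList`: data.frame (gene, auc,
#'   stat) sorted descending by `stat`.
#' @export
rank_genes_auc <- function(expr, group_a, group_b) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- as.matrix(expr$values)
  ia <- if (is.character(group_a)) match(group_a, colnames(v)) else group_a
  ib <- if (is.character(group_b)) match(group_b, colnames(v)) else group_b
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  res <- row_wilcoxon(v, ia, ib)
  df <- data.frame(gene = rownames(v), auc = res[, "auc"],
                   stat = res[, "auc"] - 0.5, stringsAsFactors = FALSE)
  df <- df[order(-df$stat, df$gene), ]
  rownames(df) <- NULL
  class(df) <- c("RankedGeneList", "data.frame")
  df
}

# classic weighted running-sum enrichment score over a ranking:
# hit steps proportional to |stat|^p, miss steps uniform; ES is the
# walk value of largest magnitude
gsea_es <- function(stat_sorted, in_set, gsea_param = 1) {
  m <- sum(in_set)
  G <- length(stat_sorted)
  if (m == 0L || m == G) return(NA_real_)
  w <- abs(stat_sorted)^gsea_param
  denom <- sum(w[in_set])
  if (denom == 0) return(NA_real_)
  step <- ifelse(in_set, w / denom, -1 / (G - m))
  walk <- cumsum(step)
  walk[which.max(abs(walk))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum enrichment: walking down the ranked
#' list, genes in the set step the sum up in proportion to
#' `|stat|^gsea_param`, others step it down uniformly; the enrichment
#' score (ES) is the extreme of the walk. The null is built from random
#' gene-label permutations of set membership; positive and negative ES
#' are normalized separately (NES = ES / mean |null ES| of the same
#' sign) and BH adjustment is applied within each sign. Sets whose ES is
#' degenerate (every ranked gene in the set) are flagged undefined.
#'
#' @param ranked a [rank_genes_auc()] result, or a data.frame with
#'   columns `gene` and `stat` sorted descending.
#' @param sets a [PathwayCollection()].
#' @param n_perm gene-permutation count for the null.
#' @param gsea_param weight exponent on the ranking statistic.
#' @param min_genes minimum overlap between a set and the ranking.
#' @param seed integer seed.
#' @return data.frame of class `GseaResult`: pathway, size, es, nes,
#'   p, q, leading_edge (comma-separated gene list).
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000L, gsea_param = 1,
                           min_genes = 3L, seed = 1L) {
  stopifnot(inherits(sets, "PathwayCollection"))
  stat <- ranked$stat
  genes <- ranked$gene
  G <- length(genes)
  set.seed(seed)
  sizes <- integer(0); rows <- list()
  null_cache <- list()  # per set size, n_perm null ES values
  for (nm in names(sets$pathways)) {
    hit <- genes %in% sets$pathways[[nm]]
    m <- sum(hit)
    if (m < min_genes) next
    es <- gsea_es(stat, hit, gsea_param)
    if (is.na(es)) {
      rows[[nm]] <- data.frame(pathway = nm, size = m, es = NA_real_,
                               nes = NA_real_, p = NA_real_, q = NA_real_,
                               leading_edge = "", stringsAsFactors = FALSE)
      next
    }
    key <- as.character(m)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- vapply(seq_len(n_perm), function(b) {
        hb <- logical(G); hb[sample.int(G, m)] <- TRUE
        gsea_es(stat, hb, gsea_param)
      }, 0)
    }
    null_es <- null_cache[[key]]
    same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    # leading edge: set genes at or before the walk extreme
    w <- abs(stat)^gsea_param
    stepv <- ifelse(hit, w / sum(w[hit]), -1 / (G - m))
    walk <- cumsum(stepv)
    peak <- which.max(abs(walk))
    le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]] else
      genes[peak:G][hit[peak:G]]
    rows[[nm]] <- data.frame(pathway = nm, size = m, es = es, nes = nes,
                             p = p, q = NA_real_,
                             leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set overlaps the ranking by >= ", min_genes)
  rownames(out) <- NULL
  pos <- !is.na(out$es) & out$es >= 0
  neg <- !is.na(out$es) & out$es < 0
  out$q[pos] <- stats::p.adjust(out$p[pos], "BH")
  out$q[neg] <- stats::p.adjust(out$p[neg], "BH")
  class(out) <- c("GseaResult", "data.frame")
  out
}

#' Variance-inflated Wilcoxon gene-set test per cluster
#'
#' For each cluster, the per-gene statistic is the log2 fold change of
#' mean expression between the cluster and all other cells (pseudo-count
#' 1 on the de-logged normalized scale). Each gene set is then tested by
#' a Wilcoxon rank-sum of its member genes' log2FC against all
#' non-member genes, with the rank-sum variance inflated by
#' `1 + (m - 1) * rho`, where `rho` is the mean pairwise correlation of
#' the member genes' expression — the standard correction for
#' inter-gene correlation in competitive gene-set tests. BH adjustment
#' is applied across sets within each cluster.
#'
#' @param log_expr an [ExpressionMatrix()] of log-normalized expression.
#' @param clusters per-cell cluster labels.
#' @param sets a [PathwayCollection()].
#' @param min_genes minimum measured genes per set.
#' @return data.frame: cluster, pathway, size, statistic (z), mean_logfc,
#'   rho, p, q.
#' @export
vi_wilcoxon_gene_set_test <- function(log_expr, clusters, sets,
                                      min_genes = 3L) {
  stopifnot(inherits(log_expr, "ExpressionMatrix"),
            inherits(sets, "PathwayCollection"))
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2L) stop("at least 2 clusters required")
  v <- as.matrix(log_expr$values)
  rows <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    mu_in <- rowMeans(expm1(v[, in_cl, drop = FALSE]))
    mu_out <- rowMeans(expm1(v[, !in_cl, drop = FALSE]))
    lfc <- log2(mu_in + 1) - log2(mu_out + 1)
    r_lfc <- rank(lfc)
    for (nm in names(sets$pathways)) {
      g <- intersect(sets$pathways[[nm]], rownames(v))
      if (length(g) < min_genes) next
      m <- length(g)
      n_tot <- length(lfc)
      member <- rownames(v) %in% g
      rs <- sum(r_lfc[member])
      mu_rs <- m * (n_tot + 1) / 2
      var_rs <- m * (n_tot - m) * (n_tot + 1) / 12
      cm <- suppressWarnings(stats::cor(t(v[g, , drop = FALSE])))
      rho <- mean(cm[upper.tri(cm)], na.rm = TRUE)
      if (!is.finite(rho)) rho <- 0
      rho <- max(rho, 0)
      vif <- 1 + (m - 1) * rho
      zstat <- (rs - mu_rs) / sqrt(vif * var_rs)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, pathway = nm, size = m, statistic = zstat,
        mean_logfc = mean(lfc[member]), rho = rho,
        p = 2 * stats::pnorm(-abs(zstat)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable gene set")
  out$q <- NA_real_
  for (cl in unique(out$cluster))
    out$q[out$cluster == cl] <- stats::p.adjust(out$p[out$cluster == cl], "BH")
  rownames(out) <- NULL
  out
}
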