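# Independent brute-force oracles, written as plain loops straight from the
# definitions. They deliberately share no code with the package internals.

# weighted-mean pathway activity: w_g = 1/#sets containing g
oracle_pathway_score <- function(rel, sets, pathway, type) {
  mult <- function(g) sum(vapply(sets, function(s) g %in% s, TRUE))
  genes <- intersect(sets[[pathway]], rownames(rel))
  num <- 0; den <- 0
  for (g in genes) {
    if (!all(is.finite(rel[g, ]))) next
    w <- 1 / mult(g)
    num <- num + w * rel[g, type]
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}

# gaussian kernel CDF + symmetric-rank-weight KS walk, straight loops
oracle_gsva <- function(v, sets, tau = 1) {
  keep <- apply(v, 1L, stats::sd) > 0
  v <- v[keep, , drop = FALSE]
  G <- nrow(v); n <- ncol(v)
  z <- matrix(0, G, n, dimnames = dimnames(v))
  for (i in seq_len(G)) {
    h <- stats::sd(v[i, ]) / 4
    for (j in seq_len(n))
      z[i, j] <- mean(stats::pnorm((v[i, j] - v[i, ]) / h))
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    for (s in seq_along(sets)) {
      hit_genes <- intersect(sets[[s]], rownames(v))
      hit <- rownames(v)[ord] %in% hit_genes
      m <- sum(hit)
      if (m == 0 || m == G) next
      w <- abs(G / 2 - seq_len(G) + 0.5)^tau
      walk <- 0; maxpos <- 0; minneg <- 0
      wsum <- sum(w[hit])
      for (k in seq_len(G)) {
        walk <- walk + if (hit[k]) w[k] / wsum else -1 / (G - m)
        maxpos <- max(maxpos, walk)
        minneg <- min(minneg, walk)
      }
      out[s, j] <- maxpos + minneg
    }
  }
  out
}

# classic GSEA running sum; returns the walk value of largest magnitude
oracle_gsea_es <- function(stat, hit, p = 1) {
  G <- length(stat); m <- sum(hit)
  if (m == 0 || m == G) return(NA_real_)
  w <- abs(stat)^p
  walk <- 0; extreme <- 0
  for (k in seq_len(G)) {
    walk <- walk + if (hit[k]) w[k] / sum(w[hit]) else -1 / (G - m)
    if (abs(walk) > abs(extreme)) extreme <- walk
  }
  extreme
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exhaustive-pair AUC: P(a > b) + 0.5 P(a == b)
oracle_auc <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(b))
}

make_expr <- function(v, units = "lognorm", ...) {
  ExpressionMatrix(v, units = units, ...)
}

rand_gene_names <- function(n) sprintf("g%03d", seq_len(n))
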