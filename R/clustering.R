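#' Hierarchical split of cells on per-cell pathway scores
#'
#' Euclidean distances between cells on the pathway-score columns,
#' agglomerative clustering with complete linkage, tree cut into `k`
#' groups. Scores are standardized per pathway (z-score across cells)
#' before the distance so no single high-variance pathway dominates;
#' set `standardize = FALSE` for raw-score distances.
#'
#' @param scores a [gsva_scores()] `PerCellScoreMatrix` (or a
#'   pathway x cell matrix).
#' @param k number of clusters (default 2: the high/low metabolic
#'   split).
#' @param standardize z-score each pathway across cells first.
#' @return object of class `ClusterAssignment`: list with `labels`
#'   (named integer per cell), `method`, `parameters`.
#' @export
hierarchical_split <- function(scores, k = 2L, standardize = TRUE) {
  m <- if (inherits(scores, "PerCellScoreMatrix")) scores$scores else
    as.matrix(scores)
  if (ncol(m) < k) stop("k exceeds the number of cells")
  if (any(!is.finite(m))) stop("scores must be complete (no NA/Inf)")
  x <- t(m)  # cells x pathways
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    x <- scale(x[, sds > 0, drop = FALSE])
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "complete")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, method = "hclust-complete",
                 parameters = list(k = k, standardize = standardize)),
            class = "ClusterAssignment")
}

#' @exportS3Method base::print
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment [%s]: %d cells, %d clusters\n",
              x$method, length(x$labels), length(unique(x$labels))))
  print(table(x$labels))
  invisible(x)
}

#' Name the two metabolic clusters "high" and "low"
#'
#' The cluster with the greater mean of per-cell mean pathway score is
#' labelled "high", the other "low" — the naming is derived from the
#' data, never from cluster ids. An exact tie is broken toward the
#' first cluster with a warning.
#'
#' @param assign a 2-cluster [hierarchical_split()] result.
#' @param scores the `PerCellScoreMatrix` the split was computed on.
#' @return the `ClusterAssignment` with labels in `{"high", "low"}`.
#' @export
label_high_low <- function(assign, scores) {
  stopifnot(inherits(assign, "ClusterAssignment"))
  m <- if (inherits(scores, "PerCellScoreMatrix")) scores$scores else
    as.matrix(scores)
  ids <- sort(unique(assign$labels))
  if (length(ids) != 2L) stop("exactly 2 clusters required")
  cell_mean <- colMeans(m)
  g1 <- mean(cell_mean[assign$labels == ids[1L]])
  g2 <- mean(cell_mean[assign$labels == ids[2L]])
  if (g1 == g2) {
    warning("tied cluster means; 'high' assigned to the first cluster")
    high_id <- ids[1L]
  } else high_id <- if (g1 > g2) ids[1L] else ids[2L]
  out <- ifelse(assign$labels == high_id, "high", "low")
  names(out) <- names(assign$labels)
  assign$labels <- out
  assign$parameters$high_cluster <- high_id
  assign
}

#' PCA on per-cell pathway scores
#'
#' Centered PCA with a deterministic sign convention: each component is
#' flipped so its largest-magnitude loading is positive.
#'
#' @param scores a `PerCellScoreMatrix` or pathway x cell matrix.
#' @param n_components number of components to keep.
#' @return list: `coords` (cell x component), `loadings`
#'   (pathway x component), `variance_explained` (fractions).
#' @export
pca_on_scores <- function(scores, n_components = 2L) {
  m <- if (inherits(scores, "PerCellScoreMatrix")) scores$scores else
    as.matrix(scores)
  x <- t(m)
  if (all(apply(x, 2L, stats::sd) == 0)) stop("constant score matrix")
  n_components <- min(n_components, ncol(x), nrow(x) - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  coords <- pc$x[, k, drop = FALSE]
  for (j in k) {  # sign convention
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords, loadings = rot, variance_explained = ve[k])
}

#' Graph-based re-clustering of a cell subset
#'
#' Log-normalized highly variable genes, PCA to `n_pcs` components, a
#' shared-nearest-neighbour graph (Jaccard weights on `k_nn`-nearest
#' neighbour sets), and modularity community detection at the given
#' resolution. Labels are `lmCluster0..m` by decreasing size; the seed
#' makes the partition reproducible.
#'
#' @param expr an [ExpressionMatrix()] of counts or normalized values
#'   for the subset (>= 50 cells).
#' @param n_pcs number of principal components (default 10).
#' @param resolution modularity resolution (default 0.1; larger gives
#'   more communities).
#' @param n_hvg number of highly variable genes.
#' @param k_nn neighbourhood size of the SNN graph.
#' @param seed integer seed.
#' @return a `ClusterAssignment` with labels `lmCluster0..`.
#' @export
subcluster_cells <- function(expr, n_pcs = 10L, resolution = 0.1,
                             n_hvg = 1000L, k_nn = 20L, seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- as.matrix(expr$values)
  if (ncol(v) < 50L) stop("at least 50 cells required for re-clustering")
  lv <- if (expr$units == "lognorm") v else
    log1p(sweep(v, 2L, pmax(colSums(v), 1), "/") * 1e4)
  vars <- apply(lv, 1L, stats::var)
  hvg <- order(vars, decreasing = TRUE)[seq_len(min(n_hvg, sum(vars > 0)))]
  x <- t(lv[hvg, , drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                          drop = FALSE]
  d <- as.matrix(stats::dist(pc))
  n <- nrow(d)
  k_nn <- min(k_nn, n - 1L)
  nb <- apply(d, 1L, function(row) order(row)[2:(k_nn + 1L)])  # k_nn x n
  nb_sets <- lapply(seq_len(n), function(i) c(i, nb[, i]))
  # SNN edges: Jaccard overlap of neighbour sets over kNN pairs
  ii <- rep(seq_len(n), each = k_nn)
  jj <- as.integer(nb)
  pairs <- unique(cbind(pmin(ii, jj), pmax(ii, jj)))
  wts <- apply(pairs, 1L, function(p) {
    a <- nb_sets[[p[1L]]]; b <- nb_sets[[p[2L]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  ok <- wts > 1 / 15  # prune weak edges, the usual SNN convention
  g <- igraph::graph_from_edgelist(pairs[ok, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = wts[ok])
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
  memb <- igraph::membership(comm)
  # isolated cells: attach to the community of the nearest labelled cell
  iso <- which(igraph::degree(g) == 0)
  if (length(iso)) {
    warning(length(iso), " isolated cell(s) assigned to nearest community")
    for (i in iso) {
      nn <- order(d[i, ])[-1L]
      nn <- nn[!(nn %in% iso)]
      if (length(nn)) memb[i] <- memb[nn[1L]]
    }
  }
  sz <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sz) - 1L, names(sz))
  labels <- sprintf("lmCluster%d", relabel[as.character(memb)])
  names(labels) <- colnames(v)
  structure(list(labels = labels, method = "snn-leiden",
                 parameters = list(n_pcs = n_pcs, resolution = resolution,
                                   n_hvg = n_hvg, k_nn = k_nn, seed = seed)),
            class = "ClusterAssignment")
}

#' Pairwise chi-square tests of subcluster proportions across strata
#'
#' For each pair of strata (e.g. histological subtypes), a 2x2 table of
#' high/low membership is tested by Pearson chi-square without
#' continuity correction; when any expected count is below 5 an exact
#' test is used instead (flagged). BH adjustment across pairs.
#'
#' @param assign a [ClusterAssignment()] with two label values, or a
#'   per-cell character vector.
#' @param stratum per-cell stratum labels (>= 2 strata).
#' @return data.frame: stratum_a, stratum_b, statistic, p, q, exact.
#' @export
proportion_test <- function(assign, stratum) {
  labels <- if (inherits(assign, "ClusterAssignment")) assign$labels else
    as.character(assign)
  stratum <- as.character(stratum)
  if (length(labels) != length(stratum))
    stop("assign and stratum must align")
  strata <- sort(unique(stratum))
  if (length(strata) < 2L) stop("at least 2 strata required")
  rows <- list()
  for (i in seq_len(length(strata) - 1L)) for (j in (i + 1L):length(strata)) {
    sel <- stratum %in% strata[c(i, j)]
    tab <- table(labels[sel], stratum[sel])
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    exact <- any(expected < 5)
    if (exact) {
      p <- stats::fisher.test(tab)$p.value
      statv <- NA_real_
      warning("expected count < 5 for ", strata[i], " vs ", strata[j],
              "; exact test used")
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      statv <- unname(ct$statistic)
      p <- ct$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      stratum_a = strata[i], stratum_b = strata[j],
      statistic = statv, p = p, exact = exact, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out[, c("stratum_a", "stratum_b", "statistic", "p", "q", "exact")]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 = identical partitions, ~0 = random.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must align")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(0)
  (sum_ij - expected) / (mx - expected)
}
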