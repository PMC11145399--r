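#' Mean expression per gene per cell type
#'
#' @param expr an [ExpressionMatrix()] (imputed, normalized upstream).
#' @param cell_type per-cell labels; defaults to the `cell_type`
#'   annotation column.
#' @return genes x cell-type matrix of arithmetic means. Cell types with
#'   zero cells are excluded with a warning.
#' @export
celltype_means <- function(expr, cell_type = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(cell_type)) cell_type <- expr$annotation$cell_type
  if (is.null(cell_type)) stop("no cell_type labels supplied or annotated")
  cell_type <- as.character(cell_type)
  if (length(cell_type) != ncol(expr$values))
    stop("cell_type must have one label per column")
  v <- as.matrix(expr$values)
  if (!nrow(v) || !ncol(v)) stop("empty expression matrix")
  f <- factor(cell_type)
  counts <- table(f)
  if (any(counts == 0)) {
    warning("cell types with zero cells excluded: ",
            paste(names(counts)[counts == 0], collapse = ", "))
    f <- droplevels(f)
  }
  sums <- t(rowsum(t(v), f))       # genes x types
  sweep(sums, 2L, as.numeric(table(f)), "/")
}

#' Relative expression across cell types
#'
#' `r_gt = mean_gt / mean over cell types of mean_g.` (unweighted), so
#' the row average of `r` over types is 1 for every defined gene. Genes
#' whose cross-type average is 0 are undefined (`NA`).
#'
#' @param means genes x cell-type matrix from [celltype_means()].
#' @return genes x cell-type matrix of relative expression.
#' @export
relative_expression <- function(means) {
  means <- as.matrix(means)
  if (ncol(means) < 2L)
    stop("relative expression requires at least 2 cell types")
  avg <- rowMeans(means)
  r <- sweep(means, 1L, avg, "/")
  r[avg == 0, ] <- NA_real_
  r
}

#' Weighted pathway activity scores per cell type
#'
#' `score(t, p)` is the weighted mean of the pathway's gene-level
#' relative expressions in cell type `t`, with weight
#' `w_g = 1 / multiplicity(g)` (the reciprocal of the number of pathways
#' containing the gene). A score of 1 means parity with the cross-type
#' average. Pathway genes absent from the matrix are dropped; outlier
#' genes are excluded by `outlier_rule`; entries with fewer than
#' `min_genes` usable genes are undefined (`NA`).
#'
#' The default outlier rule removes a gene from a pathway when any of
#' its relative expressions exceeds `Q3 + 3 IQR` of the pooled `r`
#' values of that pathway's genes; it is deterministic and can be
#' switched off.
#'
#' @param rel genes x cell-type matrix from [relative_expression()].
#' @param pathways a [PathwayCollection()].
#' @param outlier_rule `"iqr"` or `"none"`.
#' @param min_genes minimum usable genes per (pathway, type) entry.
#' @return object of class `ActivityTable`: list with `score`
#'   (pathway x cell-type matrix), `n_genes_used`, `p_value`, `q_value`
#'   (NA until [permutation_test()]), `genes_used` (per-pathway list).
#' @export
pathway_scores <- function(rel, pathways, outlier_rule = c("iqr", "none"),
                           min_genes = 3L) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(inherits(pathways, "PathwayCollection"))
  rel <- as.matrix(rel)
  types <- colnames(rel)
  w_all <- 1 / gene_multiplicity(pathways)
  np <- length(pathways$pathways)
  score <- matrix(NA_real_, np, ncol(rel),
                  dimnames = list(names(pathways$pathways), types))
  n_used <- matrix(0L, np, ncol(rel), dimnames = dimnames(score))
  genes_used <- vector("list", np)
  names(genes_used) <- names(pathways$pathways)
  for (p in seq_len(np)) {
    g <- intersect(pathways$pathways[[p]], rownames(rel))
    if (!length(g)) next
    rp <- rel[g, , drop = FALSE]
    ok_gene <- rowSums(!is.finite(rp)) == 0
    g <- g[ok_gene]
    if (!length(g)) next
    rp <- rel[g, , drop = FALSE]
    if (outlier_rule == "iqr" && length(g) >= min_genes) {
      pool <- as.numeric(rp)
      thr <- stats::quantile(pool, 0.75, names = FALSE) +
        3 * stats::IQR(pool)
      keep <- apply(rp, 1L, function(x) all(x <= thr))
      if (sum(keep) >= min_genes) {
        g <- g[keep]
        rp <- rel[g, , drop = FALSE]
      }
    }
    if (length(g) < min_genes) next
    w <- w_all[g]
    score[p, ] <- colSums(rp * w) / sum(w)
    n_used[p, ] <- length(g)
    genes_used[[p]] <- g
  }
  structure(list(score = score, n_genes_used = n_used,
                 p_value = matrix(NA_real_, np, ncol(rel),
                                  dimnames = dimnames(score)),
                 q_value = matrix(NA_real_, np, ncol(rel),
                                  dimnames = dimnames(score)),
                 genes_used = genes_used,
                 category = pathways$category,
                 outlier_rule = outlier_rule, min_genes = min_genes),
            class = "ActivityTable")
}

#' @exportS3Method base::print
print.ActivityTable <- function(x, ...) {
  cat(sprintf("ActivityTable: %d pathways x %d cell types (%d defined)\n",
              nrow(x$score), ncol(x$score), sum(is.finite(x$score))))
  if (any(is.finite(x$p_value)))
    cat(sprintf("permutation p-values present (n_perm = %s)\n",
                attr(x, "n_perm")))
  invisible(x)
}

# one pass of the scoring pipeline given labels; used by the observed
# score and by every permutation
score_pipeline_once <- function(v, labels, pathways, outlier_rule, min_genes) {
  f <- factor(labels)
  sums <- t(rowsum(t(v), f))
  means <- sweep(sums, 2L, as.numeric(table(f)), "/")
  rel <- relative_expression(means)
  pathway_scores(rel, pathways, outlier_rule = outlier_rule,
                 min_genes = min_genes)$score
}

#' Permutation test for pathway activity
#'
#' Shuffles cell-type labels across cells (within condition), recomputes
#' the full scoring pipeline per permutation, and reports for each
#' (pathway, cell type) entry
#' `p = (1 + #\{|score_perm - 1| >= |score_obs - 1|\}) / (1 + n_perm)`
#' (two-sided deviation from parity, never 0 by the +1 correction).
#' q-values are Benjamini-Hochberg across all defined entries of the
#' table (one condition per table).
#'
#' @param expr the [ExpressionMatrix()] the observed table was computed
#'   on.
#' @param pathways the same [PathwayCollection()].
#' @param observed an [pathway_scores()] `ActivityTable`.
#' @param cell_type per-cell labels (default: annotation column).
#' @param condition optional per-cell condition labels; permutations are
#'   confined within each condition.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return the `ActivityTable` with `p_value` and `q_value` filled.
#' @export
permutation_test <- function(expr, pathways, observed, cell_type = NULL,
                             condition = NULL, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(observed, "ActivityTable"))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (is.null(cell_type)) cell_type <- expr$annotation$cell_type
  cell_type <- as.character(cell_type)
  if (is.null(condition)) condition <- expr$annotation$condition
  if (is.null(condition)) condition <- rep("all", length(cell_type))
  condition <- as.character(condition)
  v <- as.matrix(expr$values)
  obs_dev <- abs(observed$score - 1)
  exceed <- matrix(0L, nrow(obs_dev), ncol(obs_dev),
                   dimnames = dimnames(obs_dev))
  set.seed(seed)
  cond_idx <- split(seq_along(cell_type), condition)
  for (b in seq_len(n_perm)) {
    perm <- cell_type
    for (ci in cond_idx) perm[ci] <- cell_type[sample(ci)]
    s <- score_pipeline_once(v, perm, pathways,
                             observed$outlier_rule, observed$min_genes)
    dev <- abs(s - 1)
    hit <- !is.na(dev) & !is.na(obs_dev) & dev >= obs_dev
    exceed <- exceed + hit
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[!is.finite(observed$score)] <- NA_real_
  q <- p
  defined <- is.finite(p)
  q[defined] <- stats::p.adjust(p[defined], method = "BH")
  observed$p_value <- p
  observed$q_value <- q
  attr(observed, "n_perm") <- n_perm
  observed
}

#' Long-format activity table for export and plotting
#'
#' Joins tumor and normal activity tables, masks entries with
#' `q > q_max` (scores set to `NA`, the convention for blank heatmap
#' cells), and sorts by category then pathway.
#'
#' @param tumor,normal `ActivityTable`s on the same pathway universe
#'   (`normal` may be `NULL`).
#' @param q_max masking threshold on the BH-adjusted q-value.
#' @return data.frame: condition, cell_type, pathway, category, score,
#'   n_genes, p, q, masked.
#' @export
activity_heat_table <- function(tumor, normal = NULL, q_max = 0.05) {
  one <- function(tab, cond) {
    stopifnot(inherits(tab, "ActivityTable"))
    df <- expand.grid(pathway = rownames(tab$score),
                      cell_type = colnames(tab$score),
                      stringsAsFactors = FALSE)
    df$condition <- cond
    df$category <- unname(tab$category[df$pathway])
    df$score <- as.numeric(tab$score)
    df$n_genes <- as.integer(tab$n_genes_used)
    df$p <- as.numeric(tab$p_value)
    df$q <- as.numeric(tab$q_value)
    df$masked <- !is.na(df$q) & df$q > q_max
    df$score[df$masked] <- NA_real_
    df
  }
  out <- one(tumor, "tumor")
  if (!is.null(normal)) out <- rbind(out, one(normal, "normal"))
  out <- out[order(out$condition, out$category, out$pathway, out$cell_type), ]
  rownames(out) <- NULL
  out[, c("condition", "cell_type", "pathway", "category", "score",
          "n_genes", "p", "q", "masked")]
}
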