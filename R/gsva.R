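#' Per-cell gene-set enrichment scores (kernel-CDF random walk)
#'
#' For each gene, expression is converted to a smoothed empirical
#' cumulative-density statistic across cells (Gaussian kernel on the
#' supplied — typically log — expression, bandwidth = per-gene SD / 4;
#' a Poisson kernel is available for raw counts). Within each cell the
#' statistics are rank-transformed and given the symmetric rank weight
#' `|G/2 - rank + 1/2|`, which emphasises genes at either extreme of the
#' cell's profile. For each gene set a weighted Kolmogorov-Smirnov
#' random walk is run down the cell's ranking: hits step up
#' proportionally to `weight^tau`, misses step down uniformly. The
#' score is the magnitude-difference statistic (maximum positive
#' deviation plus minimum negative deviation), or the single largest
#' deviation when `stat = "maxdev"`.
#'
#' Constant gene rows carry no ranking information and are dropped with
#' a warning; sets with fewer than `min_genes` measured genes are
#' skipped.
#'
#' @param expr an [ExpressionMatrix()]; log-scale values recommended
#'   with the Gaussian kernel.
#' @param pathways a [PathwayCollection()].
#' @param tau weight exponent on the rank statistic (default 1).
#' @param kernel `"gaussian"` or `"poisson"`.
#' @param stat `"magnitude_difference"` (default) or `"maxdev"`.
#' @param min_genes minimum measured genes per set.
#' @return object of class `PerCellScoreMatrix`: list with `scores`
#'   (pathway x cell), `method`, `parameters`.
#' @export
gsva_scores <- function(expr, pathways, tau = 1,
                        kernel = c("gaussian", "poisson"),
                        stat = c("magnitude_difference", "maxdev"),
                        min_genes = 3L) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(pathways, "PathwayCollection"))
  kernel <- match.arg(kernel)
  stat <- match.arg(stat)
  v <- as.matrix(expr$values)
  if (ncol(v) < 2L) stop("at least 2 cells are required")
  sds <- apply(v, 1L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant gene row(s) dropped")
    v <- v[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  if (!nrow(v)) stop("no informative genes remain")
  z <- if (kernel == "gaussian") kcdf_gaussian(v, sds / 4) else
    kcdf_poisson(v, 0.5)
  dimnames(z) <- dimnames(v)
  scores <- walk_scores(z, pathways, tau = tau, stat = stat,
                        min_genes = min_genes)
  structure(list(scores = scores, method = "kcdf-ks-walk",
                 parameters = list(tau = tau, kernel = kernel, stat = stat)),
            class = "PerCellScoreMatrix")
}

# rank the kernel-CDF statistics per cell and run the weighted KS walk
# per set (compiled)
walk_scores <- function(z, pathways, tau, stat, min_genes) {
  G <- nrow(z); n <- ncol(z)
  sets <- lapply(pathways$pathways, function(g) {
    idx <- match(intersect(g, rownames(z)), rownames(z))
    if (length(idx) < min_genes) NULL else idx
  })
  keep <- !vapply(sets, is.null, TRUE)
  sets <- sets[keep]
  if (!length(sets)) stop("no pathway has >= ", min_genes, " measured genes")
  member <- matrix(0L, G, length(sets))
  for (s in seq_along(sets)) member[sets[[s]], s] <- 1L
  out <- ks_walk_scores(z, member, tau, stat == "magnitude_difference")
  dimnames(out) <- list(names(sets), colnames(z))
  out
}

#' @exportS3Method base::print
print.PerCellScoreMatrix <- function(x, ...) {
  cat(sprintf("PerCellScoreMatrix [%s]: %d pathways x %d cells\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
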