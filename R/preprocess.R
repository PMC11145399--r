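#' Quality-control thresholds for cell filtering
#'
#' Defaults follow standard droplet QC practice: at least 500 detected
#' genes, at least 1,000 UMIs, and at most 20% mitochondrial counts.
#' All boundaries are inclusive (>=, >=, <=).
#'
#' @param min_genes minimum number of detected genes per cell.
#' @param min_umis minimum total UMI count per cell.
#' @param max_mito_fraction maximum mitochondrial fraction, in `[0,1]`.
#' @param mito_gene_prefix prefix identifying mitochondrial genes.
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes = 500L, min_umis = 1000L,
                          max_mito_fraction = 0.20,
                          mito_gene_prefix = "MT-") {
  if (min_genes < 0 || min_umis < 0)
    stop("min_genes and min_umis must be non-negative")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0,1]")
  structure(list(min_genes = min_genes, min_umis = min_umis,
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_prefix = mito_gene_prefix),
            class = "QCThresholds")
}

#' Filter low-quality cells
#'
#' Keeps cells passing all three criteria: detected genes >= `min_genes`,
#' UMIs >= `min_umis`, mitochondrial fraction <= `max_mito_fraction`.
#'
#' @param counts an [ExpressionMatrix()] of raw counts.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `ExpressionMatrix` with attribute `"qc_report"`:
#'   a list of counts removed per criterion and the kept cell ids.
#' @export
qc_filter_cells <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "ExpressionMatrix"),
            inherits(thresholds, "QCThresholds"))
  v <- counts$values
  n_detected <- Matrix::colSums(v > 0)
  n_umis <- Matrix::colSums(v)
  mito <- grepl(paste0("^", thresholds$mito_gene_prefix), rownames(v))
  mito_frac <- if (any(mito))
    Matrix::colSums(v[mito, , drop = FALSE]) / pmax(n_umis, 1) else
    rep(0, ncol(v))
  pass_genes <- n_detected >= thresholds$min_genes
  pass_umis <- n_umis >= thresholds$min_umis
  pass_mito <- mito_frac <= thresholds$max_mito_fraction
  keep <- pass_genes & pass_umis & pass_mito
  if (!any(keep))
    stop("QC removed every cell; pipeline cannot proceed")
  report <- list(n_input = ncol(v), n_kept = sum(keep),
                 removed_low_genes = sum(!pass_genes),
                 removed_low_umis = sum(!pass_umis),
                 removed_high_mito = sum(!pass_mito),
                 kept_cells = colnames(v)[keep])
  out <- subset_expr(counts, cells = which(keep))
  attr(out, "qc_report") <- report
  out
}

# two-component normal mixture EM on a vector (dropout low mode vs
# expression mode), means constrained ordered; returns lambda (weight of
# the low mode) and per-observation posterior of the low mode
mixture_em <- function(x, max_iter = 100L, tol = 1e-6) {
  n <- length(x)
  q <- stats::quantile(x, c(0.25, 0.75))
  mu <- c(min(x), max(q[2L], min(x) + 0.1))
  sd0 <- max(stats::sd(x), 0.1)
  sg <- c(sd0 / 2, sd0 / 2)
  lambda <- mean(x <= q[1L])
  lambda <- min(max(lambda, 0.05), 0.95)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- lambda * stats::dnorm(x, mu[1L], sg[1L])
    d2 <- (1 - lambda) * stats::dnorm(x, mu[2L], sg[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    post <- d1 / tot
    ll <- sum(log(tot))
    lambda <- min(max(mean(post), 1e-4), 1 - 1e-4)
    w1 <- sum(post); w2 <- n - w1
    mu[1L] <- sum(post * x) / w1
    mu[2L] <- sum((1 - post) * x) / w2
    sg[1L] <- sqrt(sum(post * (x - mu[1L])^2) / w1)
    sg[2L] <- sqrt(sum((1 - post) * (x - mu[2L])^2) / w2)
    sg <- pmax(sg, 0.05)
    if (mu[1L] > mu[2L]) {  # keep the low mode first
      mu <- rev(mu); sg <- rev(sg); lambda <- 1 - lambda; post <- 1 - post
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(lambda = lambda, mu = mu, sigma = sg, posterior = post)
}

#' Fit a per-gene dropout mixture model within cell groups
#'
#' Within each group (one group per sample in the intended use), each
#' candidate gene's `log(TPM + 1)` values are modelled as a two-component
#' mixture — a low/dropout mode and a normal expression mode — fitted by
#' EM. The dropout probability `d_gc` of entry (gene, cell) is the
#' posterior of the low mode. Only genes whose zero rate within the
#' group exceeds `candidate_zero_rate` are modelled (the gene-level gate
#' before the per-entry posterior gate used at imputation); other genes
#' get `d_gc = 0`. Genes that are zero in every cell of a group get
#' `d_gc = 1` and are flagged unimputable.
#'
#' @param tpm an [ExpressionMatrix()] (TPM or normalized scale).
#' @param groups factor/character per cell, e.g. the sample label;
#'   groups with fewer than `min_cells` cells are skipped with a flag.
#' @param candidate_zero_rate gene-level zero-rate gate (default 0.5:
#'   only genes not expressed in more than half of the cells are
#'   modelled).
#' @param min_cells minimum group size for fitting.
#' @return object of class `DropoutModel`: per-group list with `d` (gene
#'   x cell posterior dropout matrix), `lambda`, `candidates`,
#'   `unimputable`, plus `groups` and the global `d` assembled gene x
#'   cell.
#' @export
fit_dropout_model <- function(tpm, groups, candidate_zero_rate = 0.5,
                              min_cells = 10L) {
  stopifnot(inherits(tpm, "ExpressionMatrix"))
  v <- as.matrix(tpm$values)
  groups <- as.character(groups)
  if (length(groups) != ncol(v)) stop("groups must have one label per cell")
  d_all <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  per_group <- list()
  skipped <- character(0)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < min_cells) {
      skipped <- c(skipped, g)
      next
    }
    sub <- v[, idx, drop = FALSE]
    zero_rate <- rowMeans(sub == 0)
    all_zero <- zero_rate == 1
    candidates <- which(zero_rate > candidate_zero_rate & !all_zero)
    lam <- rep(NA_real_, nrow(v)); names(lam) <- rownames(v)
    for (gi in candidates) {
      x <- log1p(sub[gi, ])
      if (stats::sd(x) < 1e-8) next
      fit <- mixture_em(x)
      lam[gi] <- fit$lambda
      d_all[gi, idx] <- fit$posterior
    }
    d_all[all_zero, idx] <- 1
    per_group[[g]] <- list(cells = colnames(sub),
                           candidates = rownames(v)[candidates],
                           unimputable = rownames(v)[all_zero],
                           lambda = lam)
  }
  structure(list(d = d_all, groups = groups, per_group = per_group,
                 skipped_groups = skipped,
                 candidate_zero_rate = candidate_zero_rate),
            class = "DropoutModel")
}

#' Impute likely dropout entries from similar cells
#'
#' For each cell, entries with posterior dropout probability
#' `d_gc > drop_thre` are re-estimated by non-negative least-squares
#' regression of the cell's reliable genes (`d <= drop_thre`) on the
#' same genes of its most similar cells within the same group
#' (Pearson correlation, top `k = min(20, group size - 1)` neighbours);
#' the fitted combination of the neighbours then predicts the dropout
#' entries. Reliable entries are never altered. Cells with fewer than 3
#' usable neighbours are left unimputed and logged.
#'
#' @param tpm an [ExpressionMatrix()] on the scale the model was fitted
#'   on.
#' @param model a [fit_dropout_model()] result for the same matrix.
#' @param drop_thre posterior threshold above which an entry is treated
#'   as a dropout (default 0.5).
#' @return an [ExpressionMatrix()] with imputed values (>= 0); attribute
#'   `"impute_log"` lists cells skipped for lack of neighbours.
#' @export
impute_dropouts <- function(tpm, model, drop_thre = 0.5) {
  stopifnot(inherits(tpm, "ExpressionMatrix"), inherits(model, "DropoutModel"))
  v <- as.matrix(tpm$values)
  if (!identical(dim(v), dim(model$d)))
    stop("model was fitted on a matrix of different dimensions")
  out <- v
  skipped_cells <- character(0)
  for (g in names(model$per_group)) {
    info <- model$per_group[[g]]
    idx <- match(info$cells, colnames(v))
    if (length(idx) < 4L) next
    dg <- model$d[, idx, drop = FALSE]
    sub <- v[, idx, drop = FALSE]
    need <- dg > drop_thre
    if (!any(need)) next
    # genes reliable across the whole group anchor the similarity metric
    reliable_gene <- rowMeans(dg) <= drop_thre
    if (sum(reliable_gene) < 10L) {
      skipped_cells <- c(skipped_cells, info$cells)
      next
    }
    lsub <- log1p(sub[reliable_gene, , drop = FALSE])
    cc <- suppressWarnings(stats::cor(lsub))
    cc[is.na(cc)] <- 0
    k <- min(20L, length(idx) - 1L)
    for (j in seq_along(idx)) {
      to_fill <- which(need[, j])
      if (!length(to_fill)) next
      nb <- order(cc[, j], decreasing = TRUE)
      nb <- setdiff(nb, j)[seq_len(k)]
      if (length(nb) < 3L) {
        skipped_cells <- c(skipped_cells, info$cells[j])
        next
      }
      rel_j <- which(dg[, j] <= drop_thre)
      if (length(rel_j) < length(nb) + 2L) {
        skipped_cells <- c(skipped_cells, info$cells[j])
        next
      }
      X <- sub[rel_j, nb, drop = FALSE]
      y <- sub[rel_j, j]
      coef <- tryCatch(pracma::lsqnonneg(X, y)$x,
                       error = function(e) NULL)
      if (is.null(coef)) {
        skipped_cells <- c(skipped_cells, info$cells[j])
        next
      }
      pred <- as.numeric(sub[to_fill, nb, drop = FALSE] %*% coef)
      out[to_fill, idx[j]] <- pmax(pred, 0)
    }
  }
  res <- ExpressionMatrix(out, tpm$annotation, units = tpm$units)
  attr(res, "impute_log") <- list(skipped_cells = unique(skipped_cells))
  res
}

#' Per-cell size factors
#'
#' Four estimators, all rescaled to geometric mean 1:
#' * `deconvolution`: pooled deconvolution across cells (pools over a
#'   library-size-ordered ring solved by least squares), the default for
#'   droplet data;
#' * `RLE`: per-cell median ratio to the geometric-mean reference over
#'   genes positive in the reference;
#' * `TMM`: trimmed mean of M-values against a reference column (30% M
#'   trim, 5% A trim), converted to size factors via library sizes;
#' * `upperquartile`: per-cell 75th percentile of nonzero counts.
#'
#' @param counts an [ExpressionMatrix()] of non-negative counts.
#' @param method one of `"deconvolution"`, `"RLE"`, `"TMM"`,
#'   `"upperquartile"`.
#' @return object of class `SizeFactors`: numeric vector (names = cell
#'   ids) with attribute `method`.
#' @export
size_factors <- function(counts,
                         method = c("deconvolution", "RLE", "TMM",
                                    "upperquartile")) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  method <- match.arg(method)
  v <- as.matrix(counts$values)
  if (min(v) < 0) stop("counts must be non-negative")
  f <- switch(method,
    RLE = {
      logv <- log(v)
      ref <- exp(rowMeans(logv))  # geometric mean; 0 where any zero
      use <- is.finite(ref) & ref > 0
      if (!any(use)) stop("no gene is positive in every cell; RLE undefined")
      apply(v[use, , drop = FALSE], 2L, function(col)
        stats::median(col / ref[use]))
    },
    upperquartile = apply(v, 2L, function(col) {
      nz <- col[col > 0]
      if (!length(nz)) stop("all-zero cell; upper-quartile factor undefined")
      stats::quantile(nz, 0.75, names = FALSE)
    }),
    TMM = {
      nf <- edgeR::calcNormFactors(v, method = "TMM",
                                   logratioTrim = 0.3, sumTrim = 0.05)
      colSums(v) * nf
    },
    deconvolution = {
      n <- ncol(v)
      sizes <- unique(pmin(seq(21L, 101L, by = 20L), max(2L, n - 1L)))
      est <- suppressWarnings(
        scran::calculateSumFactors(v, sizes = sizes, min.mean = 0.1))
      if (any(est <= 0)) {
        warning("non-positive deconvolution factors clipped to the ",
                "smallest positive estimate")
        est[est <= 0] <- min(est[est > 0])
      }
      est
    })
  if (any(f <= 0)) stop("non-positive size factor produced by ", method)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(v)
  structure(f, method = method, class = c("SizeFactors", "numeric"))
}

#' Normalize an expression matrix by size factors
#'
#' Divides each column by its factor; optionally applies `log(x + 1)`.
#'
#' @param x an [ExpressionMatrix()].
#' @param factors a [size_factors()] vector aligned to the columns.
#' @param log_transform apply `log1p` after scaling.
#' @return an [ExpressionMatrix()] with units `"normalized"` or
#'   `"lognorm"`.
#' @export
normalize_counts <- function(x, factors, log_transform = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  f <- as.numeric(factors)
  if (length(f) != ncol(x$values)) stop("factors must align to columns")
  if (any(f <= 0)) stop("size factors must be positive")
  v <- sweep(as.matrix(x$values), 2L, f, "/")
  if (log_transform) v <- log1p(v)
  ExpressionMatrix(v, x$annotation,
                   units = if (log_transform) "lognorm" else "normalized")
}
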