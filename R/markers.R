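#' Marker / differential-expression detection between cell groups
#'
#' One-vs-rest (or pairwise, via `contrast`) marker detection in the
#' style of standard single-cell toolkits: genes are pre-filtered to
#' those detected in at least `min_pct` of either group and with
#' `|log2FC| >= logfc_threshold`; surviving genes get a Wilcoxon
#' rank-sum p on the log-normalized values and BH adjustment across
#' tested genes per contrast. log2FC is computed as
#' `log2(mean(expm1(x)) + 1)` ratios on the log-normalized scale
#' (pseudo-count 1).
#'
#' @param log_expr an [ExpressionMatrix()] of log-normalized expression.
#' @param labels per-cell group labels.
#' @param min_pct detection-fraction filter (default 0.25).
#' @param logfc_threshold absolute log2FC filter (default 0.25).
#' @param contrast `NULL` for one-vs-rest over every label, or
#'   `c(group, reference)` for a single pairwise contrast.
#' @return data.frame of class `DEResult`: contrast, gene, log2fc, auc,
#'   pct1, pct2, p, q — sorted by contrast then descending log2fc (ties
#'   by gene id). Groups with fewer than 3 cells are skipped.
#' @export
find_markers <- function(log_expr, labels, min_pct = 0.25,
                         logfc_threshold = 0.25, contrast = NULL) {
  stopifnot(inherits(log_expr, "ExpressionMatrix"))
  labels <- as.character(labels)
  v <- as.matrix(log_expr$values)
  if (length(labels) != ncol(v)) stop("labels must align to columns")
  if (length(unique(labels)) < 2L) stop("at least 2 groups required")
  contrasts <- if (is.null(contrast))
    lapply(sort(unique(labels)), function(g) c(g, ".rest")) else
    list(contrast)
  rows <- list()
  for (ct in contrasts) {
    ia <- which(labels == ct[1L])
    ib <- if (ct[2L] == ".rest") which(labels != ct[1L]) else
      which(labels == ct[2L])
    if (length(ia) < 3L || length(ib) < 3L) {
      warning("contrast ", ct[1L], " vs ", ct[2L], " skipped (< 3 cells)")
      next
    }
    pct1 <- rowMeans(v[, ia, drop = FALSE] > 0)
    pct2 <- rowMeans(v[, ib, drop = FALSE] > 0)
    mu1 <- rowMeans(expm1(v[, ia, drop = FALSE]))
    mu2 <- rowMeans(expm1(v[, ib, drop = FALSE]))
    lfc <- log2(mu1 + 1) - log2(mu2 + 1)
    test <- (pmax(pct1, pct2) >= min_pct) & (abs(lfc) >= logfc_threshold)
    if (!any(test)) next
    wt <- row_wilcoxon(v[test, , drop = FALSE], ia, ib)
    df <- data.frame(contrast = paste0(ct[1L], "_vs_",
                                       sub("^\\.", "", ct[2L])),
                     gene = rownames(v)[test],
                     log2fc = lfc[test], auc = wt[, "auc"],
                     pct1 = pct1[test], pct2 = pct2[test],
                     p = wt[, "p"], stringsAsFactors = FALSE)
    df$q <- stats::p.adjust(df$p, "BH")
    df <- df[order(-df$log2fc, df$gene), ]
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contrast = character(0), gene = character(0),
                      log2fc = numeric(0), auc = numeric(0),
                      pct1 = numeric(0), pct2 = numeric(0),
                      p = numeric(0), q = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Extract a top-N signature from a DE result
#'
#' Significant genes (`q < q_max`) of the requested direction are ranked
#' by log2 fold change (or by p-value with `rank_by = "p"`); ties are
#' broken lexicographically by gene id. The first `n` genes form the
#' signature; when fewer are significant a shorter signature is returned
#' with a warning.
#'
#' @param de a [find_markers()] result.
#' @param n signature size.
#' @param direction `"up"` or `"down"`.
#' @param contrast restrict to one contrast when `de` holds several.
#' @param q_max significance threshold (default 0.05).
#' @param rank_by `"log2fc"` (default) or `"p"`.
#' @param name signature name (defaults to the contrast).
#' @return object of class `Signature`: list with `name`, `genes`
#'   (ordered), `provenance`.
#' @export
top_n_signature <- function(de, n, direction = c("up", "down"),
                            contrast = NULL, q_max = 0.05,
                            rank_by = c("log2fc", "p"), name = NULL) {
  direction <- match.arg(direction)
  rank_by <- match.arg(rank_by)
  if (n < 1L) stop("n must be >= 1")
  df <- as.data.frame(de)
  if (!is.null(contrast)) df <- df[df$contrast == contrast, ]
  if (!nrow(df)) stop("no DE rows for the requested contrast")
  sig <- df[!is.na(df$q) & df$q < q_max, ]
  sig <- if (direction == "up") sig[sig$log2fc > 0, ] else
    sig[sig$log2fc < 0, ]
  ord <- if (rank_by == "log2fc") {
    if (direction == "up") order(-sig$log2fc, sig$gene) else
      order(sig$log2fc, sig$gene)
  } else order(sig$p, sig$gene)
  sig <- sig[ord, ]
  genes <- unique(sig$gene)
  if (length(genes) < n) {
    warning("only ", length(genes), " significant genes available; ",
            "signature shorter than n = ", n)
    n <- length(genes)
  }
  if (!n) stop("no significant genes; cannot build a signature")
  structure(list(name = name %||% unique(df$contrast)[1L],
                 genes = genes[seq_len(n)],
                 provenance = list(contrast = unique(sig$contrast),
                                   n = n, direction = direction,
                                   q_max = q_max, rank_by = rank_by)),
            class = "Signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.Signature <- function(x, ...) {
  cat(sprintf("Signature '%s' (%d genes, %s): %s\n", x$name,
              length(x$genes), x$provenance$direction,
              paste(x$genes, collapse = ", ")))
  invisible(x)
}
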