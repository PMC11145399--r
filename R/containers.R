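#' Expression matrix container
#'
#' Lightweight container used throughout the pipeline: a genes x columns
#' numeric matrix (dense or sparse `dgCMatrix`), a per-column annotation
#' table, and a units tag recording what the values are.
#'
#' Genes are rows, cells (or bulk samples) are columns, everywhere in the
#' package. Gene and column identifiers must be unique; the annotation is
#' keyed by column id and must cover exactly the columns of the matrix.
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, genes x columns,
#'   with rownames (gene ids) and colnames (cell/sample ids).
#' @param annotation data.frame with one row per column of `values`.
#'   Rownames (or a `cell_id` column) must match the colnames of `values`.
#'   Typical columns: `sample`, `condition` ("tumor"/"normal"),
#'   `cell_type`, cluster labels.
#' @param units one of `"counts"`, `"TPM"`, `"normalized"`, `"lognorm"`.
#'
#' @return an object of class `ExpressionMatrix` with fields `values`,
#'   `annotation`, `units`.
#' @export
ExpressionMatrix <- function(values, annotation = NULL, units = "counts") {
  if (is.null(dim(values)) || any(dim(values) < 1L))
    stop("'values' must be a non-empty genes x columns matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%04d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate column identifiers")
  units <- match.arg(units, c("counts", "TPM", "normalized", "lognorm"))
  if (units %in% c("counts", "TPM") && min_value(values) < 0)
    stop("negative values are not allowed for units '", units, "'")
  if (is.null(annotation)) {
    annotation <- data.frame(row.names = colnames(values))
  } else {
    annotation <- as.data.frame(annotation)
    if (!is.null(annotation$cell_id) && is.null(rownames(annotation)))
      rownames(annotation) <- annotation$cell_id
    missing <- setdiff(colnames(values), rownames(annotation))
    if (length(missing))
      stop("annotation missing for columns: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ...")
    annotation <- annotation[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, annotation = annotation, units = units),
            class = "ExpressionMatrix")
}

min_value <- function(x) {
  if (methods::is(x, "sparseMatrix")) min(0, min(x@x, Inf)) else min(x)
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d columns [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  if (ncol(x$annotation))
    cat("annotation:", paste(colnames(x$annotation), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by genes and/or columns
#'
#' @param x an [ExpressionMatrix()].
#' @param genes,cells character, integer or logical index.
#' @return a new `ExpressionMatrix` carrying the matching annotation rows.
#' @export
subset_expr <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  ExpressionMatrix(v, x$annotation[colnames(v), , drop = FALSE], units = x$units)
}

#' Pathway (gene-set) collection
#'
#' Named gene sets with a category label per set, as read from a GMT file
#' or built by the synthetic generator. Gene lists are deduplicated within
#' a set; a gene's multiplicity is the number of sets containing it and is
#' the basis of the 1/multiplicity weights used by [pathway_scores()].
#'
#' @param pathways named list of character vectors (gene ids). Names must
#'   be unique and sets non-empty.
#' @param category optional named character vector of class labels, one
#'   per pathway; missing entries become `"uncategorized"`.
#'
#' @return an object of class `PathwayCollection` with fields `pathways`,
#'   `category`, `universe`.
#' @export
PathwayCollection <- function(pathways, category = NULL) {
  if (!length(pathways) || is.null(names(pathways)))
    stop("'pathways' must be a non-empty named list")
  if (anyDuplicated(names(pathways)))
    stop("duplicate pathway names")
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  if (any(lengths(pathways) == 0L))
    stop("empty pathway gene lists are not allowed")
  if (is.null(category)) category <- character(0)
  cat_full <- rep("uncategorized", length(pathways))
  names(cat_full) <- names(pathways)
  common <- intersect(names(category), names(pathways))
  cat_full[common] <- category[common]
  structure(list(pathways = pathways, category = cat_full,
                 universe = sort(unique(unlist(pathways, use.names = FALSE)))),
            class = "PathwayCollection")
}

#' @exportS3Method base::print
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection: %d pathways, %d genes in universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' @export
length.PathwayCollection <- function(x) length(x$pathways)

#' Gene multiplicity across a pathway collection
#'
#' @param pc a [PathwayCollection()].
#' @return named integer vector: for each universe gene, the number of
#'   pathways containing it (always >= 1).
#' @export
gene_multiplicity <- function(pc) {
  stopifnot(inherits(pc, "PathwayCollection"))
  tab <- table(unlist(pc$pathways, use.names = FALSE))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[pc$universe]
}
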