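#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields are name,
#' description, then member genes. Duplicate genes within a line are
#' collapsed. The description field is used as the category label when it
#' matches one of `known_categories` (case-insensitively), otherwise the
#' set is "uncategorized".
#'
#' @param path GMT file path.
#' @param known_categories character vector of recognised class labels
#'   (e.g. the eleven KEGG metabolic super-classes).
#' @return a [PathwayCollection()], pathways in file order.
#' @export
read_gmt <- function(path, known_categories = kegg_metabolic_classes()) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate pathway name in GMT: ", nm[duplicated(nm)][1L])
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  cat <- ifelse(tolower(desc) %in% tolower(known_categories), desc, "uncategorized")
  names(cat) <- nm
  PathwayCollection(sets, cat)
}

#' Write a PathwayCollection (or plain gene lists) to GMT
#'
#' @param pc a [PathwayCollection()] or a named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(pc, path) {
  if (inherits(pc, "PathwayCollection")) {
    sets <- pc$pathways; desc <- pc$category
  } else {
    sets <- pc; desc <- rep("uncategorized", length(sets))
    names(desc) <- names(sets)
  }
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' The eleven KEGG metabolic super-classes
#'
#' Recognised category labels for metabolic pathway collections.
#' @return character vector of length 11.
#' @export
kegg_metabolic_classes <- function() {
  c("carbohydrate", "energy", "lipid", "nucleotide", "amino acid",
    "other amino acids", "glycan", "cofactors and vitamins",
    "terpenoids and polyketides", "other secondary metabolites",
    "xenobiotics")
}

#' Read an expression matrix with per-column annotation
#'
#' Supports Matrix Market triplets (`format = "mtx"`, with `genes.tsv` and
#' `barcodes.tsv` sidecars next to the matrix file) and dense CSV
#' (`format = "csv"`, genes as rows with rownames in the first column).
#' The annotation TSV must contain a `cell_id` column covering every
#' matrix column.
#'
#' @param path matrix file (`matrix.mtx` or a CSV).
#' @param format `"mtx"` or `"csv"`.
#' @param annotation_path TSV of per-column annotation, or `NULL`.
#' @param units units tag for the values (default `"counts"`).
#' @return an [ExpressionMatrix()].
#' @export
read_expression <- function(path, format = c("mtx", "csv"),
                            annotation_path = NULL, units = "counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "mtx") {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv"); bf <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("MTX sidecars genes.tsv / barcodes.tsv not found in ", dir)
    genes <- readLines(gf); cells <- readLines(bf)
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop(sprintf("dimension mismatch: matrix %dx%d vs %d genes / %d barcodes",
                   nrow(m), ncol(m), length(genes), length(cells)))
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  }
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (is.null(ann$cell_id)) stop("annotation file lacks a 'cell_id' column")
    rownames(ann) <- ann$cell_id
  }
  ExpressionMatrix(m, ann, units = units)
}

#' Write an ExpressionMatrix to disk
#'
#' `"mtx"` writes `matrix.mtx` + `genes.tsv` + `barcodes.tsv` +
#' `cell_metadata.tsv` into a directory; `"csv"` writes a dense CSV (and
#' an annotation TSV alongside when annotation is present).
#'
#' @param x an [ExpressionMatrix()].
#' @param path output directory (mtx) or CSV file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @return invisibly, the paths written.
#' @export
write_expression <- function(x, path, format = c("mtx", "csv")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    mf <- file.path(path, "matrix.mtx")
    Matrix::writeMM(methods::as(methods::as(x$values, "dMatrix"),
                                "CsparseMatrix"), mf)
    writeLines(rownames(x$values), file.path(path, "genes.tsv"))
    writeLines(colnames(x$values), file.path(path, "barcodes.tsv"))
    ann <- cbind(cell_id = colnames(x$values), x$annotation)
    utils::write.table(ann, file.path(path, "cell_metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(mf, file.path(path, c("genes.tsv", "barcodes.tsv", "cell_metadata.tsv")))
  } else {
    utils::write.csv(as.matrix(x$values), path, quote = FALSE)
    out <- path
    if (ncol(x$annotation)) {
      af <- sub("\\.csv$", "_metadata.tsv", path)
      ann <- cbind(cell_id = colnames(x$values), x$annotation)
      utils::write.table(ann, af, sep = "\t", quote = FALSE, row.names = FALSE)
      out <- c(out, af)
    }
  }
  invisible(out)
}

#' Read a gene length table
#'
#' Two-column TSV `gene_id <tab> length` (header optional). Lengths must
#' be positive.
#'
#' @param path TSV path.
#' @return named numeric vector of lengths in bases.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (is.character(df[[2L]]) || tolower(df[1L, 1L]) %in% c("gene", "gene_id"))
    df <- utils::read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  len <- as.numeric(df[[2L]])
  names(len) <- as.character(df[[1L]])
  if (any(!is.finite(len)) || any(len <= 0))
    stop("gene lengths must be positive and finite")
  len
}

#' Convert counts to TPM
#'
#' Per column: `rate_g = count_g / length_g`, then
#' `TPM_g = rate_g / sum(rate) * 1e6`, so every non-empty column sums to
#' one million. All-zero columns stay all-zero.
#'
#' @param counts an [ExpressionMatrix()] with `units = "counts"`.
#' @param lengths named numeric vector of gene lengths in bases; every
#'   gene of `counts` must be present.
#' @return an [ExpressionMatrix()] with `units = "TPM"`.
#' @export
counts_to_tpm <- function(counts, lengths) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  genes <- rownames(counts$values)
  missing <- setdiff(genes, names(lengths))
  if (length(missing))
    stop("missing gene lengths for: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
  len <- lengths[genes]
  v <- as.matrix(counts$values)
  rate <- v / len
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # guard 0/0 for empty columns
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  ExpressionMatrix(tpm, counts$annotation, units = "TPM")
}
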