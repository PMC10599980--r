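# Expression containers, I/O and the normalization variants.

NORMALIZATIONS <- c("log-tpm", "log-fpkm", "log-counts", "sem-raw", "external")

#' Tag a numeric matrix as an expression matrix
#'
#' Expression is stored genes x samples with unique dimnames and a
#' normalization tag recording the units every downstream method saw.
#'
#' @param x numeric matrix, rows = genes, columns = samples.
#' @param normalization one of `"log-tpm"`, `"log-fpkm"`, `"log-counts"`,
#'   `"sem-raw"`, `"external"`.
#' @return The matrix with a `normalization` attribute.
#' @export
expression_matrix <- function(x, normalization) {
  normalization <- match.arg(normalization, NORMALIZATIONS)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("gene and sample labels are required", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate gene labels", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate sample labels", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite expression values", call. = FALSE)
  attr(x, "normalization") <- normalization
  x
}

#' Normalization tag of an expression matrix
#' @param x an expression matrix.
#' @return The tag, or `NULL` for untagged matrices.
#' @export
normalization_tag <- function(x) attr(x, "normalization")

#' Read an expression or count matrix
#'
#' Supports a dense TSV (header row = samples, first column = gene label) and
#' MatrixMarket coordinate triplets accompanied by plain-text row/column name
#' files (one label per line).
#'
#' @param path TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param row_names,col_names label files, required for `format = "mtx"`.
#' @param normalization optional tag; when supplied the result is a tagged
#'   expression matrix, otherwise an untagged (count) matrix.
#' @return A genes x samples numeric matrix.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            row_names = NULL, col_names = NULL,
                            normalization = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cells in expression TSV", call. = FALSE)
    rownames(m) <- genes
  } else {
    if (is.null(row_names) || is.null(col_names))
      stop("MTX input requires row and column name files", call. = FALSE)
    sp <- Matrix::readMM(path)
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(sp) || length(cn) != ncol(sp))
      stop("dimension mismatch between MTX and name files", call. = FALSE)
    m <- as.matrix(sp)
    dimnames(m) <- list(rn, cn)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene labels", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample labels", call. = FALSE)
  if (is.null(normalization)) m else expression_matrix(m, normalization)
}

#' Write an expression matrix as TSV
#'
#' @param x matrix with dimnames.
#' @param path output file; first column `gene`, header row = sample labels.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize a count matrix
#'
#' Implements the three in-package normalization variants, each followed by a
#' `log(x + 1)` transform (natural log by default; the base only rescales
#' values and never changes within-gene sample ranks, so rank-based inference
#' is invariant to it):
#' \describe{
#'   \item{tpm}{counts / gene length, rescaled per sample to sum 1e6.}
#'   \item{fpkm}{counts * 1e9 / (gene length * library size).}
#'   \item{logcounts}{counts scaled to the mean library size.}
#' }
#' Library size is the column sum of the provided counts. Batch-corrected
#' matrices are accepted from external tools via
#' `expression_matrix(x, "external")`, never computed here.
#'
#' @param counts non-negative genes x samples matrix.
#' @param method `"tpm"`, `"fpkm"` or `"logcounts"`.
#' @param gene_lengths named numeric vector of effective lengths in bp,
#'   required for tpm/fpkm.
#' @param log_base base of the final log transform.
#' @return A tagged expression matrix (`"log-tpm"`, `"log-fpkm"` or
#'   `"log-counts"`).
#' @export
normalize_expression <- function(counts, method = c("tpm", "fpkm", "logcounts"),
                                 gene_lengths = NULL, log_base = exp(1)) {
  method <- match.arg(method)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample with zero library size", call. = FALSE)
  if (method %in% c("tpm", "fpkm")) {
    if (is.null(gene_lengths))
      stop("gene lengths required for ", method, call. = FALSE)
    len <- gene_lengths[rownames(counts)]
    if (anyNA(len) || any(len <= 0))
      stop("missing or non-positive gene lengths", call. = FALSE)
  }
  val <- switch(method,
    tpm = {
      rate <- counts / gene_lengths[rownames(counts)]
      sweep(rate, 2, colSums(rate), "/") * 1e6
    },
    fpkm = sweep(counts * 1e9 / gene_lengths[rownames(counts)], 2, libsize, "/"),
    logcounts = sweep(counts, 2, libsize / mean(libsize), "/"))
  tag <- c(tpm = "log-tpm", fpkm = "log-fpkm", logcounts = "log-counts")[[method]]
  expression_matrix(log1p(val) / log(log_base), tag)
}

#' Restrict an expression matrix to the prior-derived vocabulary
#'
#' Keeps, in their original order, the genes that appear in the
#' chromatin-accessibility prior (as TF or target); the TF list is restricted
#' the same way.
#'
#' @param expr expression matrix.
#' @param prior a `regulatory_prior`, or `NULL` to keep all genes.
#' @param tf_list character vector of TF labels.
#' @return List with the restricted `expr` and `tf_list`.
#' @export
restrict_universe <- function(expr, prior = NULL, tf_list) {
  vocab <- rownames(expr)
  if (!is.null(prior)) vocab <- intersect(vocab, unique(c(prior$tf, prior$gene)))
  if (length(vocab) == 0L) stop("no shared vocabulary", call. = FALSE)
  keep <- rownames(expr)[rownames(expr) %in% vocab]
  out <- expr[keep, , drop = FALSE]
  if (!is.null(normalization_tag(expr)))
    attr(out, "normalization") <- normalization_tag(expr)
  list(expr = out, tf_list = intersect(tf_list, keep))
}
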