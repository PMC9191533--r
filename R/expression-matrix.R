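#' Construct a validated expression matrix
#'
#' An expression matrix is a feature-by-sample matrix of non-negative
#' expression values with a declared unit (raw counts, CPM, TPM or RPKM).
#' Feature and sample identifiers must be unique; identifiers are treated
#' case-sensitively and no symbol mapping between annotation namespaces is
#' attempted.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param unit One of `"counts"`, `"cpm"`, `"tpm"`, `"rpkm"`.
#' @return A numeric matrix of class `"expr_matrix"` with a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("counts", "cpm", "tpm", "rpkm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f)) {
    stop("duplicated feature id(s): ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  }
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE]))
  invisible(x)
}

#' Read a feature-by-sample expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column (header `feature_id`)
#' holds feature identifiers and whose remaining column headers are sample
#' identifiers. Values must parse as finite non-negative numbers.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("counts", "cpm", "tpm", "rpkm")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a feature_id column plus >=1 sample",
                         call. = FALSE)
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s' in %s",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]], path),
         call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  expression_matrix(num, unit)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: first column `feature_id`, one
#' column per sample. Round-trips losslessly at 10 significant digits.
#'
#' @param x An [expression_matrix()] (or any named numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x),
                   apply(unclass(x), 2, format_num10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair miRNA and mRNA matrices on their shared samples
#'
#' Subsets and reorders both matrices to the intersection of their sample
#' ids. The miRNA matrix's sample order wins. Samples present on only one
#' side are dropped and reported via a message and the `"dropped_samples"`
#' attribute of the result.
#'
#' @param mirna,mrna [expression_matrix()] objects.
#' @return A list of class `"paired_dataset"` with elements `mirna` and
#'   `mrna` sharing an identical, ordered sample set.
#' @export
align_paired <- function(mirna, mrna) {
  shared <- intersect(colnames(mirna), colnames(mrna))
  if (length(shared) < 3) {
    stop(sprintf("only %d shared sample id(s); need at least 3 matched samples",
                 length(shared)),
         call. = FALSE)
  }
  ord <- colnames(mirna)[colnames(mirna) %in% shared]
  dropped <- c(setdiff(colnames(mirna), shared), setdiff(colnames(mrna), shared))
  if (length(dropped)) {
    message("align_paired: dropped unmatched sample(s): ",
            paste(dropped, collapse = ", "))
  }
  out <- list(
    mirna = expression_matrix(unclass(mirna)[, ord, drop = FALSE], attr(mirna, "unit")),
    mrna  = expression_matrix(unclass(mrna)[, ord, drop = FALSE], attr(mrna, "unit"))
  )
  attr(out, "dropped_samples") <- dropped
  class(out) <- "paired_dataset"
  out
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d miRNAs, %d mRNAs, %d matched samples\n",
              nrow(x$mirna), nrow(x$mrna), ncol(x$mirna)))
  invisible(x)
}

#' Read a log2 fold-change table from TSV
#'
#' First column `feature_id`; remaining headers are comparison labels (for
#' example `"4h_vs_ctrl"`); values are log2 fold changes produced upstream
#' by any differential-expression tool.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix of class `"fc_table"`, features in rows and
#'   comparisons in columns.
#' @export
read_fold_change_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("fold-change TSV needs feature_id plus >=1 comparison",
                         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  fc_table(m)
}

#' Construct a validated fold-change table
#'
#' @param values Numeric matrix of log2 fold changes, features in rows,
#'   comparisons in columns, both dimensions named.
#' @return The matrix with class `"fc_table"`.
#' @export
fc_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("fold-change table needs feature ids and comparison labels", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicated feature ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicated comparison labels", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("fold-change values must be finite", call. = FALSE)
  }
  if (ncol(values) < 1) stop("need at least one comparison column", call. = FALSE)
  structure(values, class = c("fc_table", "matrix", "array"))
}

#' Write a fold-change table to TSV
#' @param x An `fc_table` (or named numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_change_table <- function(x, path) {
  df <- data.frame(feature_id = rownames(x),
                   apply(unclass(x), 2, format_num10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
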