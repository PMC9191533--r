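#' Read a target-prediction table (miRanda- or TargetScan-style)
#'
#' The miRanda dialect expects columns `mirna_id`, `gene_id`, `score` and
#' optionally `energy` (kcal/mol, non-positive), `seed_score` and
#' `align_score`. The TargetScan dialect expects `mirna_id`, `gene_id` and
#' `context_score_percentile` (in `[0, 100]`), which is mapped into `score`.
#' Duplicate (miRNA, gene) rows — miRanda reports one row per predicted
#' site — are collapsed keeping the maximum score.
#'
#' @param path Path to a tab-delimited prediction file.
#' @param source `"miranda"` (default) or `"targetscan"`.
#' @return A data frame of class `"prediction_table"` with columns
#'   `mirna_id`, `gene_id`, `score`, `energy`, `seed_score`, `align_score`
#'   and a `"source"` attribute.
#' @export
read_prediction_table <- function(path, source = c("miranda", "targetscan")) {
  source <- match.arg(source)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (source == "targetscan") {
    need <- c("mirna_id", "gene_id", "context_score_percentile")
  } else {
    need <- c("mirna_id", "gene_id", "score")
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("prediction table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (source == "targetscan") {
    df$score <- as.numeric(df$context_score_percentile)
    if (nrow(df) && any(df$score < 0 | df$score > 100, na.rm = TRUE)) {
      stop("context score percentile must lie in [0, 100]", call. = FALSE)
    }
  }
  for (col in c("energy", "seed_score", "align_score")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  df$score <- as.numeric(df$score)
  prediction_table(df[, c("mirna_id", "gene_id", "score", "energy",
                          "seed_score", "align_score")],
                   source = source)
}

#' Construct a canonical prediction table
#'
#' Canonicalization collapses duplicate (mirna_id, gene_id) records to the
#' one with the maximum score. A positive folding energy triggers a warning
#' (miRanda energies are free energies in kcal/mol and should be <= 0) but
#' the value is kept.
#'
#' @param df Data frame with columns `mirna_id`, `gene_id`, `score` and
#'   optionally `energy`, `seed_score`, `align_score`.
#' @param source `"miranda"` or `"targetscan"`.
#' @return A `"prediction_table"` data frame.
#' @export
prediction_table <- function(df, source = c("miranda", "targetscan")) {
  source <- match.arg(source)
  for (col in c("energy", "seed_score", "align_score")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  }
  df <- df[, c("mirna_id", "gene_id", "score", "energy", "seed_score", "align_score")]
  if (nrow(df)) {
    if (anyNA(df$score)) stop("prediction scores must be numeric", call. = FALSE)
    if (any(df$energy > 0, na.rm = TRUE)) {
      warning("positive folding energy found; value kept", call. = FALSE)
    }
    # keep the best-scoring site per pair
    ord <- order(df$mirna_id, df$gene_id, -df$score)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df[, c("mirna_id", "gene_id")]), , drop = FALSE]
    df <- df[order(df$mirna_id, df$gene_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, source = source,
            class = c("prediction_table", "data.frame"))
}

#' Filter predictions by score threshold or score percentile
#'
#' Exactly one of `min_score` and `percentile` must be given. In
#' `min_score` mode records with `score >= min_score` are kept (inclusive
#' floor, the conventional "score >= 140" usage). In `percentile` mode the
#' given percentile of all scores in the table is computed by linear
#' interpolation and records strictly above it are kept (the "above the
#' 99th percentile" usage).
#'
#' @param table A [prediction_table()].
#' @param min_score Inclusive score floor.
#' @param percentile Percentile in (0, 100); records strictly above the
#'   computed cutoff are kept.
#' @return The filtered `"prediction_table"`, with the computed cutoff in
#'   the `"cutoff"` attribute.
#' @export
filter_predictions <- function(table, min_score = NULL, percentile = NULL) {
  if (is.null(min_score) == is.null(percentile)) {
    stop("supply exactly one of `min_score` or `percentile`", call. = FALSE)
  }
  if (!is.null(min_score)) {
    keep <- table$score >= min_score
    cutoff <- min_score
  } else {
    if (!nrow(table)) stop("cannot take a percentile of an empty table", call. = FALSE)
    if (percentile <= 0 && percentile != 0 || percentile >= 100) {
      stop("`percentile` must lie in [0, 100)", call. = FALSE)
    }
    cutoff <- unname(stats::quantile(table$score, percentile / 100, type = 7))
    keep <- table$score > cutoff
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, source = attr(table, "source"),
                   class = c("prediction_table", "data.frame"))
  attr(out, "cutoff") <- cutoff
  out
}

#' Enumerate candidate miRNA-mRNA pairs
#'
#' Without a prediction table, the full Cartesian product in miRNA-major
#' order. With one, the product intersected with the table's records. For
#' genome-scale id lists the count alone is often wanted: `count_only =
#' TRUE` returns the number of pairs without materializing them.
#'
#' @param mirna_ids,mrna_ids Character vectors of identifiers.
#' @param predictions Optional [prediction_table()] to intersect with.
#' @param count_only If `TRUE`, return the pair count as a number.
#' @return A data frame of class `"pair_list"` with columns `mirna_id` and
#'   `mrna_id` (unique rows), or a count.
#' @export
enumerate_pairs <- function(mirna_ids, mrna_ids, predictions = NULL,
                            count_only = FALSE) {
  mirna_ids <- unique(as.character(mirna_ids))
  mrna_ids <- unique(as.character(mrna_ids))
  if (is.null(predictions)) {
    if (count_only) return(as.numeric(length(mirna_ids)) * length(mrna_ids))
    out <- data.frame(
      mirna_id = rep(mirna_ids, each = length(mrna_ids)),
      mrna_id = rep(mrna_ids, times = length(mirna_ids)),
      stringsAsFactors = FALSE
    )
  } else {
    keep <- predictions$mirna_id %in% mirna_ids & predictions$gene_id %in% mrna_ids
    out <- data.frame(mirna_id = predictions$mirna_id[keep],
                      mrna_id = predictions$gene_id[keep],
                      stringsAsFactors = FALSE)
    out <- out[!duplicated(out), , drop = FALSE]
    out <- out[order(match(out$mirna_id, mirna_ids), match(out$mrna_id, mrna_ids)), ,
               drop = FALSE]
    if (count_only) return(as.numeric(nrow(out)))
  }
  rownames(out) <- NULL
  structure(out, class = c("pair_list", "data.frame"))
}

#' Write a per-pair result table to TSV
#'
#' Serializes any result data frame with a stable column order (the order
#' of the input). Numeric fields are written with 10 significant digits so
#' the file round-trips losslessly through [read_results_table()]; integers
#' and exact values (for example a p-value of exactly 1) are printed
#' without trailing noise.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- format_num10(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#' @param path Path to the TSV file.
#' @return A data frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# 10-significant-digit text form; "%.10g" prints 1 as "1", not "0.9999999999"
format_num10 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.10g", v)
  }, character(1))
  out
}
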