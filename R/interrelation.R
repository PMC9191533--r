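#' Interrelation statistic: absolute difference of two fold changes
#'
#' `d = |x - y|` where `x` is a miRNA's log2 fold change over an interval
#' and `y` an mRNA's log2 fold change over the same interval. Large `d`
#' means the two features moved very differently between the two time
#' points.
#'
#' @param x,y Finite numerics (vectorized).
#' @return `|x - y|`, non-negative.
#' @export
difference_stat <- function(x, y) {
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  abs(x - y)
}

#' Build a background null of fold-change differences
#'
#' Draws `n_perm` uniformly random (miRNA, mRNA) cross-pairs with
#' replacement from the two single-comparison fold-change tables and
#' records their `d = |x - y|` values.
#'
#' @param fc_mirna,fc_mrna [fc_table()] objects with the same single
#'   comparison column.
#' @param n_perm Number of resampled background pairs.
#' @param seed Integer seed.
#' @return A `"null_distribution"` of kind `"difference"`.
#' @export
build_null_diff <- function(fc_mirna, fc_mrna, n_perm = 100, seed) {
  .check_fc_pairing(fc_mirna, fc_mrna, min_comparisons = 1)
  if (ncol(fc_mirna) != 1) {
    stop("interrelation analysis takes exactly one comparison column; ",
         "run each interval separately", call. = FALSE)
  }
  if (!nrow(fc_mirna) || !nrow(fc_mrna)) stop("empty fold-change table", call. = FALSE)
  x <- fc_mirna[, 1]
  y <- fc_mrna[, 1]
  vals <- withr::with_seed(seed, {
    i <- sample.int(length(x), n_perm, replace = TRUE)
    j <- sample.int(length(y), n_perm, replace = TRUE)
    abs(x[i] - y[j])
  })
  structure(list(values = unname(vals), n_perm = n_perm, seed = seed,
                 kind = "difference"),
            class = "null_distribution")
}

#' Upper-tail permutation p-value for an observed difference
#'
#' `p = (1 + #\{d_null >= d_obs\}) / (n_perm + 1)`. The upper tail is the
#' relevant one: a significant pair is one whose miRNA and mRNA fold
#' changes diverge more than random cross-pairs do.
#'
#' @param d_obs Observed `d` statistic.
#' @param null A `"null_distribution"` of kind `"difference"`.
#' @return A p-value in `(0, 1]`.
#' @export
diff_pvalue <- function(d_obs, null) {
  stopifnot(inherits(null, "null_distribution"), null$kind == "difference")
  (1 + sum(null$values >= d_obs)) / (null$n_perm + 1)
}

#' Classify a pair's regulation type from fold-change signs
#'
#' The four informative sign patterns of (miRNA fold change, mRNA fold
#' change) map to: `(+,-)` `mirna_up_mrna_down`, `(-,+)`
#' `mirna_down_mrna_up`, `(+,+)` `coregulation_increase`, `(-,-)`
#' `coregulation_decrease`. A fold change with `|value| <= zero_tol` is
#' treated as zero and yields `no_change`. Display labels for reports
#' ("Inverse Regulation", "Coregulation (increase)", ...) are applied only
#' at serialization via [regulation_labels()].
#'
#' @param log2fc_mirna,log2fc_mrna Finite log2 fold changes (vectorized).
#' @param zero_tol Non-negative tolerance below which a fold change counts
#'   as zero. Default 0: only an exact zero maps to `no_change` (upstream
#'   log2FCs are rarely exactly zero; raise this for shrunken estimates).
#' @return A character vector of class labels.
#' @export
classify_regulation <- function(log2fc_mirna, log2fc_mrna, zero_tol = 0) {
  stopifnot(zero_tol >= 0, all(is.finite(log2fc_mirna)), all(is.finite(log2fc_mrna)))
  sx <- sign(log2fc_mirna) * (abs(log2fc_mirna) > zero_tol)
  sy <- sign(log2fc_mrna) * (abs(log2fc_mrna) > zero_tol)
  out <- rep("no_change", length(sx))
  out[sx > 0 & sy < 0] <- "mirna_up_mrna_down"
  out[sx < 0 & sy > 0] <- "mirna_down_mrna_up"
  out[sx > 0 & sy > 0] <- "coregulation_increase"
  out[sx < 0 & sy < 0] <- "coregulation_decrease"
  out
}

#' Display labels for regulation classes
#'
#' The conventional report wording for each sign-pattern class. The
#' mapping is a plain named character vector, so callers can substitute
#' their own labels.
#'
#' @return Named character vector mapping class -> display label.
#' @export
regulation_labels <- function() {
  c(mirna_up_mrna_down = "Inverse Regulation",
    mirna_down_mrna_up = "Inverse Regulation (miRNA down)",
    coregulation_increase = "Coregulation (increase)",
    coregulation_decrease = "Coregulation (reduction)",
    no_change = "No Change")
}

#' Run the Part 3 two-timepoint interrelation screen
#'
#' For every candidate pair over one interval: the statistic
#' `d = |x - y|`, an upper-tail p-value against one shared resampled null
#' of cross-pair differences, Benjamini-Hochberg adjustment, and the
#' sign-pattern regulation class. A heatmap-ready wide matrix (mRNA rows x
#' miRNA columns of `d`, non-significant cells `NA`) is attached as the
#' `"d_matrix"` attribute.
#'
#' @inheritParams build_null_diff
#' @param pairs Optional `"pair_list"`; defaults to all combinations (or
#'   the prediction table's pairs when `predictions` is given).
#' @param alpha Adjusted-p significance threshold.
#' @param zero_tol Passed to [classify_regulation()].
#' @param predictions Optional (pre-filtered) [prediction_table()].
#' @param null_mode `"shared"` (one null for the run, default) or
#'   `"per_pair"` (an independent null per pair, exactly calibrated; see
#'   [run_part2()]).
#' @return A data frame with columns `mirna_id`, `mrna_id`,
#'   `log2fc_mirna`, `log2fc_mrna`, `d`, `p`, `p_adj`, `regulation`,
#'   `prediction_score`, `significant`, sorted by `p` then descending `d`.
#' @export
run_part3 <- function(fc_mirna, fc_mrna, pairs = NULL, n_perm = 100, seed,
                      alpha = 0.05, zero_tol = 0, predictions = NULL,
                      null_mode = c("shared", "per_pair")) {
  null_mode <- match.arg(null_mode)
  .check_fc_pairing(fc_mirna, fc_mrna, min_comparisons = 1)
  if (ncol(fc_mirna) != 1) {
    stop("interrelation analysis takes exactly one comparison column; ",
         "run each interval separately", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- enumerate_pairs(rownames(fc_mirna), rownames(fc_mrna),
                             predictions = predictions)
  } else if (!is.null(predictions)) {
    key <- paste(predictions$mirna_id, predictions$gene_id, sep = "\r")
    pairs <- pairs[paste(pairs$mirna_id, pairs$mrna_id, sep = "\r") %in% key, ,
                   drop = FALSE]
  }
  pairs <- pairs[pairs$mirna_id %in% rownames(fc_mirna) &
                 pairs$mrna_id %in% rownames(fc_mrna), , drop = FALSE]

  x <- fc_mirna[pairs$mirna_id, 1]
  y <- fc_mrna[pairs$mrna_id, 1]
  d <- difference_stat(x, y)
  if (null_mode == "shared") {
    null <- build_null_diff(fc_mirna, fc_mrna, n_perm = n_perm, seed = seed)
    p <- vapply(d, diff_pvalue, numeric(1), null = null)
  } else {
    xs <- fc_mirna[, 1]
    ys <- fc_mrna[, 1]
    np <- nrow(pairs)
    dnull <- withr::with_seed(seed, {
      i <- sample.int(length(xs), np * n_perm, replace = TRUE)
      j <- sample.int(length(ys), np * n_perm, replace = TRUE)
      matrix(abs(xs[i] - ys[j]), nrow = np)
    })
    p <- (1 + rowSums(dnull >= d)) / (n_perm + 1)
    null <- NULL
  }
  out <- data.frame(mirna_id = pairs$mirna_id, mrna_id = pairs$mrna_id,
                    log2fc_mirna = unname(x), log2fc_mrna = unname(y),
                    d = unname(d), p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    regulation = classify_regulation(x, y, zero_tol = zero_tol),
                    stringsAsFactors = FALSE)
  out$prediction_score <- .prediction_score(out$mirna_id, out$mrna_id, predictions)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, -out$d, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "null") <- null
  attr(out, "d_matrix") <- interrelation_matrix(out)
  out
}

#' Wide significant-pair matrix for heatmaps
#'
#' One row per mRNA and one column per miRNA appearing in the significant
#' set; cells hold the `d` statistic, with `NA` where the pair is not
#' significant (rendered gray/blank downstream).
#'
#' @param results A [run_part3()] result table.
#' @return A numeric matrix (possibly 0 x 0).
#' @export
interrelation_matrix <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  mrnas <- sort(unique(sig$mrna_id))
  mirnas <- sort(unique(sig$mirna_id))
  m <- matrix(NA_real_, nrow = length(mrnas), ncol = length(mirnas),
              dimnames = list(mrnas, mirnas))
  if (nrow(sig)) m[cbind(sig$mrna_id, sig$mirna_id)] <- sig$d
  m
}

#' Write the wide interrelation matrix to TSV (empty cells for NA)
#' @param m Matrix from [interrelation_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interrelation_matrix <- function(m, path) {
  df <- data.frame(mrna_id = rownames(m),
                   apply(m, 2, function(col) ifelse(is.na(col), "", format_num10(col))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(m)) df <- data.frame(mrna_id = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
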