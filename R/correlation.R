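#' Pearson product-moment correlation of two fold-change vectors
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant (the correlation is undefined for a zero-variance vector).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 comparisons", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Build a background null of correlations from random cross-pairs
#'
#' Draws `n_perm` uniformly random (miRNA, mRNA) feature pairs with
#' replacement from the two fold-change tables — excluding features with
#' constant vectors, for which the correlation is undefined — and records
#' their Pearson correlations. One shared null per run is the intended
#' usage.
#'
#' @param fc_mirna,fc_mrna [fc_table()] objects sharing the same >= 3
#'   comparison columns.
#' @param n_perm Number of resampled background pairs (conventional
#'   default 100; >= 1000 recommended for stable tails).
#' @param seed Integer seed; the null is reproducible from it.
#' @return A list of class `"null_distribution"` with elements `values`,
#'   `n_perm`, `seed` and `kind = "correlation"`.
#' @export
build_null_corr <- function(fc_mirna, fc_mrna, n_perm = 100, seed) {
  .check_fc_pairing(fc_mirna, fc_mrna, min_comparisons = 3)
  usable_mir <- rownames(fc_mirna)[apply(fc_mirna, 1, stats::sd) > 0]
  usable_mrna <- rownames(fc_mrna)[apply(fc_mrna, 1, stats::sd) > 0]
  if (length(usable_mir) < 2 || length(usable_mrna) < 2) {
    stop("need at least 2 non-constant features on each side", call. = FALSE)
  }
  zm <- .row_unit(fc_mirna[usable_mir, , drop = FALSE])
  zr <- .row_unit(fc_mrna[usable_mrna, , drop = FALSE])
  vals <- withr::with_seed(seed, {
    i <- sample.int(length(usable_mir), n_perm, replace = TRUE)
    j <- sample.int(length(usable_mrna), n_perm, replace = TRUE)
    unname(rowSums(zm[i, , drop = FALSE] * zr[j, , drop = FALSE]))
  })
  structure(list(values = vals, n_perm = n_perm, seed = seed,
                 kind = "correlation"),
            class = "null_distribution")
}

#' Construct a null distribution object
#'
#' Mostly produced by [build_null_corr()] / [build_null_diff()]; the
#' constructor is exported so callers can wrap an externally computed
#' background (or a hand-built one in tests).
#'
#' @param values Numeric vector of null statistic values.
#' @param kind `"correlation"` or `"difference"`.
#' @param seed Seed the values were generated from, or `NA`.
#' @return A list of class `"null_distribution"`.
#' @export
null_distribution <- function(values, kind = c("correlation", "difference"),
                              seed = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(values), length(values) >= 1)
  structure(list(values = as.numeric(values), n_perm = length(values),
                 seed = seed, kind = kind),
            class = "null_distribution")
}

#' Rank-based permutation p-value for an observed correlation
#'
#' Add-one-corrected rank of the observed correlation within the
#' background null, so the smallest attainable p is `1/(n_perm + 1)` and
#' p = 0 is impossible:
#'
#' * `negative`: `p = (1 + #\{r_null <= r_obs\}) / (n_perm + 1)`
#' * `positive`: `p = (1 + #\{r_null >= r_obs\}) / (n_perm + 1)`
#' * `two_sided`: `p = (1 + #\{|r_null| >= |r_obs|\}) / (n_perm + 1)`
#'
#' @param r_obs Observed correlation.
#' @param null A `"null_distribution"` of kind `"correlation"`.
#' @param alternative `"negative"` (default; canonical miRNA repression),
#'   `"positive"`, or `"two_sided"`.
#' @return A p-value in `(0, 1]`.
#' @export
corr_pvalue <- function(r_obs, null,
                        alternative = c("negative", "positive", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(null, "null_distribution"), null$kind == "correlation")
  v <- null$values
  hits <- switch(alternative,
    negative = sum(v <= r_obs),
    positive = sum(v >= r_obs),
    two_sided = sum(abs(v) >= abs(r_obs))
  )
  (1 + hits) / (null$n_perm + 1)
}

#' Run the Part 2 fold-change correlation screen
#'
#' Computes the Pearson correlation of miRNA and mRNA log2 fold-change
#' vectors across >= 3 comparisons for every candidate pair, assigns
#' rank-based p-values against a resampled null, and applies
#' Benjamini-Hochberg adjustment. Pairs with a constant fold-change vector
#' are skipped (listed in the `"skipped"` attribute). Optional filters:
#' keep only correlations `r <= r_max` (for example -0.85 for strong
#' inverse relationships), and/or intersect with a prediction table.
#'
#' Two null modes are available. `"shared"` (default) draws one null of
#' `n_perm` random cross-pair correlations for the whole run — cost
#' `O(n_perm)`, but the null's own Monte-Carlo error is inherited by
#' every p-value. `"per_pair"` draws an independent null for each pair,
#' giving exactly calibrated (discrete-uniform under the null) p-values
#' at `O(n_pairs * n_perm)` cost.
#'
#' @inheritParams build_null_corr
#' @param pairs Optional `"pair_list"`; defaults to all combinations of
#'   the two tables' features (or the prediction table's pairs when
#'   `predictions` is given).
#' @param alternative Passed to [corr_pvalue()].
#' @param alpha Adjusted-p significance threshold.
#' @param r_max Optional ceiling: keep rows with `r <= r_max`.
#' @param predictions Optional (pre-filtered) [prediction_table()]; output
#'   is restricted to its pairs and annotated with `prediction_score`.
#' @param null_mode `"shared"` or `"per_pair"` (see Details).
#' @return A data frame with columns `mirna_id`, `mrna_id`, `r`, `p`,
#'   `p_adj`, `n_comparisons`, `prediction_score`, `significant`, sorted
#'   by `p`, then `r`, then ids.
#' @export
run_part2 <- function(fc_mirna, fc_mrna, pairs = NULL, n_perm = 100, seed,
                      alternative = c("negative", "positive", "two_sided"),
                      alpha = 0.05, r_max = NULL, predictions = NULL,
                      null_mode = c("shared", "per_pair")) {
  alternative <- match.arg(alternative)
  null_mode <- match.arg(null_mode)
  .check_fc_pairing(fc_mirna, fc_mrna, min_comparisons = 3)
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

  sd_mir <- apply(fc_mirna, 1, stats::sd)
  sd_mrna <- apply(fc_mrna, 1, stats::sd)
  const <- sd_mir[pairs$mirna_id] == 0 | sd_mrna[pairs$mrna_id] == 0
  skipped <- pairs[const, , drop = FALSE]
  if (nrow(skipped)) skipped$reason <- "constant fold-change vector"
  pairs <- pairs[!const, , drop = FALSE]

  zm <- .row_unit(fc_mirna)
  zr <- .row_unit(fc_mrna)
  r <- rowSums(zm[pairs$mirna_id, , drop = FALSE] *
               zr[pairs$mrna_id, , drop = FALSE])
  if (null_mode == "shared") {
    null <- build_null_corr(fc_mirna, fc_mrna, n_perm = n_perm, seed = seed)
    p <- vapply(r, corr_pvalue, numeric(1), null = null, alternative = alternative)
  } else {
    usable_mir <- which(sd_mir > 0)
    usable_mrna <- which(sd_mrna > 0)
    if (length(usable_mir) < 2 || length(usable_mrna) < 2) {
      stop("need at least 2 non-constant features on each side", call. = FALSE)
    }
    np <- nrow(pairs)
    rnull <- withr::with_seed(seed, {
      i <- sample(usable_mir, np * n_perm, replace = TRUE)
      j <- sample(usable_mrna, np * n_perm, replace = TRUE)
      matrix(rowSums(zm[i, , drop = FALSE] * zr[j, , drop = FALSE]),
             nrow = np)
    })
    hits <- switch(alternative,
      negative = rowSums(rnull <= r),
      positive = rowSums(rnull >= r),
      two_sided = rowSums(abs(rnull) >= abs(r))
    )
    p <- (1 + hits) / (n_perm + 1)
    null <- NULL
  }
  out <- data.frame(mirna_id = pairs$mirna_id, mrna_id = pairs$mrna_id,
                    r = r, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    n_comparisons = ncol(fc_mirna),
                    stringsAsFactors = FALSE)
  out$prediction_score <- .prediction_score(out$mirna_id, out$mrna_id, predictions)
  if (!is.null(r_max)) out <- out[out$r <= r_max, , drop = FALSE]
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$r, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "null") <- null
  attr(out, "skipped") <- skipped
  out
}

# rows centered and scaled to unit norm, so a row dot product is Pearson r
.row_unit <- function(m) {
  m <- unclass(m)
  ctr <- m - rowMeans(m)
  ctr / sqrt(rowSums(ctr^2))
}

.check_fc_pairing <- function(fc_mirna, fc_mrna, min_comparisons) {
  if (!identical(colnames(fc_mirna), colnames(fc_mrna))) {
    stop("the two fold-change tables must share the same comparison columns",
         call. = FALSE)
  }
  if (ncol(fc_mirna) < min_comparisons) {
    stop(sprintf("need at least %d comparison column(s), have %d",
                 min_comparisons, ncol(fc_mirna)), call. = FALSE)
  }
  invisible(TRUE)
}

.prediction_score <- function(mirna_id, mrna_id, predictions) {
  if (is.null(predictions)) return(rep(NA_real_, length(mirna_id)))
  key <- paste(predictions$mirna_id, predictions$gene_id, sep = "\r")
  idx <- match(paste(mirna_id, mrna_id, sep = "\r"), key)
  predictions$score[idx]
}
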