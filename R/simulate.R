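#' Simulate a paired miRNA/mRNA expression dataset with planted effects
#'
#' miRNA baselines are log-normal (`meanlog = 3`, `sdlog = 1` by default),
#' mimicking the scale heterogeneity of CPM/TPM data. Each planted
#' (miRNA, mRNA) pair generates its mRNA response through the family's
#' canonical link with the stated coefficients: identity plus Gaussian
#' noise for `gaussian`, log-linear mean for the count families, with an
#' extra constant zero-inflation probability for the zero-inflated ones.
#' Non-planted mRNAs are intercept-only draws from the same family,
#' independent of every miRNA.
#'
#' @param n_samples Number of matched samples.
#' @param n_mirna,n_mrna Numbers of miRNA and mRNA features; ids are
#'   `mir001...` and `gene0001...`.
#' @param planted Data frame with columns `mirna_id`, `mrna_id`, `beta0`,
#'   `beta1` (one planted regression per row), or `NULL` for a global
#'   null.
#' @param family Distribution family for the mRNA responses (not
#'   `"auto"`).
#' @param noise List of family parameters: `sigma` (Gaussian sd, default
#'   0.1), `size` (NB dispersion, default 2), `zi_prob` (zero-inflation
#'   probability, default 0.3), `meanlog`/`sdlog` (miRNA baseline,
#'   defaults 3/1), `bg_beta0` (background intercept on the link scale,
#'   default matches `beta0` usage).
#' @param seed Integer seed; generation is a pure function of seed and
#'   parameters.
#' @return A list: `data` (a `"paired_dataset"`) and `truth` (data frame
#'   of planted effects with columns `mirna_id`, `mrna_id`, `effect`,
#'   `value`, `family`).
#' @export
simulate_paired_counts <- function(n_samples, n_mirna, n_mrna, planted = NULL,
                                   family = "gaussian", noise = list(), seed) {
  family <- match.arg(family, .FAMILIES)
  p <- utils::modifyList(list(sigma = 0.1, size = 2, zi_prob = 0.3,
                              meanlog = 3, sdlog = 1, bg_beta0 = NULL), noise)
  if (p$size <= 0) stop("dispersion `size` must be positive", call. = FALSE)
  if (p$zi_prob < 0 || p$zi_prob >= 1) stop("`zi_prob` must be in [0, 1)", call. = FALSE)
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirna))
  mrna_ids <- sprintf("gene%04d", seq_len(n_mrna))
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(planted$mirna_id %in% mirna_ids),
              all(planted$mrna_id %in% mrna_ids))
    if (anyDuplicated(planted$mrna_id)) {
      stop("at most one planted regression per mRNA", call. = FALSE)
    }
  }
  # background intercept on the link scale: keeps null mRNAs at a
  # realistic magnitude for each family
  bg_b0 <- if (!is.null(p$bg_beta0)) p$bg_beta0 else
    if (family == "gaussian") exp(p$meanlog) else log1p(exp(p$meanlog)) / 2 + 1

  sim <- withr::with_seed(seed, {
    mir <- matrix(stats::rlnorm(n_mirna * n_samples, p$meanlog, p$sdlog),
                  nrow = n_mirna,
                  dimnames = list(mirna_ids, sprintf("s%02d", seq_len(n_samples))))
    mrna <- matrix(NA_real_, nrow = n_mrna, ncol = n_samples,
                   dimnames = list(mrna_ids, colnames(mir)))
    for (g in mrna_ids) {
      row <- if (!is.null(planted)) planted[planted$mrna_id == g, , drop = FALSE]
             else planted
      if (!is.null(row) && nrow(row) == 1) {
        eta <- row$beta0 + row$beta1 * mir[row$mirna_id, ]
      } else {
        eta <- rep(bg_b0, n_samples)
      }
      val <- .draw_response(eta, family, p, n_samples)
      # expression is non-negative: a Gaussian response crossing zero is
      # shifted up by a constant, which only moves the intercept
      if (family == "gaussian" && min(val) < 0) val <- val - min(val)
      mrna[g, ] <- val
    }
    list(mir = mir, mrna = mrna)
  })
  unit <- if (family == "gaussian") "tpm" else "counts"
  data <- structure(
    list(mirna = expression_matrix(sim$mir, "tpm"),
         mrna = expression_matrix(sim$mrna, unit)),
    class = "paired_dataset")
  truth <- if (is.null(planted) || !nrow(planted)) {
    data.frame(mirna_id = character(0), mrna_id = character(0),
               effect = character(0), value = numeric(0), family = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(mirna_id = planted$mirna_id, mrna_id = planted$mrna_id,
               effect = "beta1", value = planted$beta1, family = family,
               stringsAsFactors = FALSE)
  }
  list(data = data, truth = truth)
}

.draw_response <- function(eta, family, p, n) {
  switch(family,
    gaussian = eta + stats::rnorm(n, 0, p$sigma),
    poisson = stats::rpois(n, exp(eta)),
    negative_binomial = stats::rnbinom(n, mu = exp(eta), size = p$size),
    zero_inflated_poisson =
      stats::rpois(n, exp(eta)) * (stats::runif(n) >= p$zi_prob),
    zero_inflated_negative_binomial =
      stats::rnbinom(n, mu = exp(eta), size = p$size) * (stats::runif(n) >= p$zi_prob)
  )
}

#' Simulate paired fold-change tables with planted correlations and
#' differences
#'
#' Background fold changes are i.i.d. normal (`sd = 2`, a realistic log2FC
#' spread). A planted correlation constructs the mRNA vector by orthogonal
#' projection so its in-sample Pearson correlation with the miRNA vector
#' equals the target exactly (up to floating point). A planted difference
#' writes the canonical inverse-regulation pattern into the first
#' (designated) comparison column — miRNA fold change `+d/2`, mRNA fold
#' change `-d/2` — so `|x - y| = d` exactly while both marginal fold
#' changes stay moderate.
#'
#' @param n_comparisons Number of comparison columns (>= 3 required when
#'   `planted_corr` is non-empty).
#' @param n_mirna,n_mrna Feature counts; ids as in
#'   [simulate_paired_counts()].
#' @param planted_corr Data frame `mirna_id`, `mrna_id`, `r` or `NULL`.
#' @param planted_diff Data frame `mirna_id`, `mrna_id`, `d` or `NULL`.
#' @param bg_sd Background log2FC standard deviation (default 2).
#' @param seed Integer seed.
#' @return A list: `fc_mirna`, `fc_mrna` ([fc_table()]s) and `truth`.
#' @export
simulate_fc_tables <- function(n_comparisons, n_mirna, n_mrna,
                               planted_corr = NULL, planted_diff = NULL,
                               bg_sd = 2, seed) {
  has_corr <- !is.null(planted_corr) && nrow(planted_corr) > 0
  has_diff <- !is.null(planted_diff) && nrow(planted_diff) > 0
  if (has_corr && n_comparisons < 3) {
    stop("planted correlations need at least 3 comparisons", call. = FALSE)
  }
  if (n_comparisons < 1) stop("need at least one comparison", call. = FALSE)
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirna))
  mrna_ids <- sprintf("gene%04d", seq_len(n_mrna))
  cmp <- sprintf("cmp%d", seq_len(n_comparisons))
  if (has_corr && has_diff) {
    both <- intersect(paste(planted_corr$mirna_id, planted_corr$mrna_id),
                      paste(planted_diff$mirna_id, planted_diff$mrna_id))
    if (length(both)) {
      stop("contradictory plantings on pair(s): ", paste(both, collapse = "; "),
           call. = FALSE)
    }
  }
  for (pl in list(planted_corr, planted_diff)) {
    if (!is.null(pl) && nrow(pl)) {
      stopifnot(all(pl$mirna_id %in% mirna_ids), all(pl$mrna_id %in% mrna_ids))
      if (anyDuplicated(pl$mrna_id)) {
        stop("at most one planting per mRNA", call. = FALSE)
      }
    }
  }
  if (has_diff && anyDuplicated(planted_diff$mirna_id)) {
    stop("at most one planted difference per miRNA", call. = FALSE)
  }
  tabs <- withr::with_seed(seed, {
    fm <- matrix(stats::rnorm(n_mirna * n_comparisons, 0, bg_sd), nrow = n_mirna,
                 dimnames = list(mirna_ids, cmp))
    fr <- matrix(stats::rnorm(n_mrna * n_comparisons, 0, bg_sd), nrow = n_mrna,
                 dimnames = list(mrna_ids, cmp))
    if (has_corr) {
      for (i in seq_len(nrow(planted_corr))) {
        x <- fm[planted_corr$mirna_id[i], ]
        r <- planted_corr$r[i]
        stopifnot(abs(r) <= 1)
        zx <- (x - mean(x)) / stats::sd(x)
        e <- stats::resid(stats::lm(stats::rnorm(n_comparisons) ~ zx))
        ze <- e / stats::sd(e)                     # centered, orthogonal to zx
        y <- r * zx + sqrt(1 - r^2) * ze           # in-sample cor(x, y) == r
        fr[planted_corr$mrna_id[i], ] <- y * bg_sd # affine scale preserves r
      }
    }
    if (has_diff) {
      for (i in seq_len(nrow(planted_diff))) {
        fm[planted_diff$mirna_id[i], 1] <- planted_diff$d[i] / 2
        fr[planted_diff$mrna_id[i], 1] <- -planted_diff$d[i] / 2
      }
    }
    list(fm = fm, fr = fr)
  })
  truth <- rbind(
    if (has_corr) data.frame(mirna_id = planted_corr$mirna_id,
                             mrna_id = planted_corr$mrna_id,
                             effect = "r", value = planted_corr$r,
                             family = NA_character_, stringsAsFactors = FALSE),
    if (has_diff) data.frame(mirna_id = planted_diff$mirna_id,
                             mrna_id = planted_diff$mrna_id,
                             effect = "d", value = planted_diff$d,
                             family = NA_character_, stringsAsFactors = FALSE)
  )
  if (is.null(truth)) {
    truth <- data.frame(mirna_id = character(0), mrna_id = character(0),
                        effect = character(0), value = numeric(0),
                        family = character(0), stringsAsFactors = FALSE)
  }
  list(fc_mirna = fc_table(tabs$fm), fc_mrna = fc_table(tabs$fr), truth = truth)
}

#' Simulate a miRanda-style prediction table covering given truth pairs
#'
#' Every truth pair receives a total score uniform in `score_range`
#' (default `c(140, 189)`, the span typically seen in genome-wide miRanda
#' output); `decoy_count` additional non-truth pairs are added. Folding
#' energies are uniform in `[-30, -5]` kcal/mol; seed and alignment
#' sub-scores uniform in plausible ranges.
#'
#' @param truth Data frame with columns `mirna_id`, `mrna_id` (extra
#'   columns ignored).
#' @param decoy_count Number of decoy (non-truth) records to add.
#' @param score_range Length-2 numeric, `low < high`.
#' @param mirna_ids,mrna_ids Optional id universes to draw decoys from;
#'   defaults to fresh `decoymirN`/`decoygeneN` ids so decoys can never
#'   collide with truth pairs.
#' @param seed Integer seed.
#' @return A [prediction_table()] with source `"miranda"`.
#' @export
simulate_prediction_table <- function(truth, decoy_count = 0,
                                      score_range = c(140, 189),
                                      mirna_ids = NULL, mrna_ids = NULL, seed) {
  stopifnot(length(score_range) == 2, score_range[1] < score_range[2])
  truth_pairs <- unique(data.frame(mirna_id = as.character(truth$mirna_id),
                                   mrna_id = as.character(truth$mrna_id),
                                   stringsAsFactors = FALSE))
  df <- withr::with_seed(seed, {
    records <- truth_pairs
    if (decoy_count > 0) {
      if (is.null(mirna_ids)) {
        decoys <- data.frame(
          mirna_id = sprintf("decoymir%03d", seq_len(decoy_count)),
          mrna_id = sprintf("decoygene%04d", seq_len(decoy_count)),
          stringsAsFactors = FALSE)
      } else {
        pool <- expand.grid(mirna_id = mirna_ids, mrna_id = mrna_ids,
                            stringsAsFactors = FALSE)
        pool <- pool[!paste(pool$mirna_id, pool$mrna_id) %in%
                       paste(truth_pairs$mirna_id, truth_pairs$mrna_id), ,
                     drop = FALSE]
        if (nrow(pool) < decoy_count) {
          stop("id universe too small for the requested decoy count", call. = FALSE)
        }
        decoys <- pool[sample.int(nrow(pool), decoy_count), , drop = FALSE]
      }
      records <- rbind(records, decoys)
    }
    n <- nrow(records)
    names(records)[names(records) == "mrna_id"] <- "gene_id"
    records$score <- stats::runif(n, score_range[1], score_range[2])
    records$energy <- stats::runif(n, -30, -5)
    records$seed_score <- stats::runif(n, 60, 100)
    records$align_score <- stats::runif(n, 80, 180)
    records
  })
  prediction_table(df, source = "miranda")
}
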