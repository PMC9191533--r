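# Shared fixture builders; everything is generated in code at test time.

# planted pair frame: mir001->gene0001, mir002->gene0002, ...
planted_pairs <- function(n) {
  data.frame(mirna_id = sprintf("mir%03d", seq_len(n)),
             mrna_id = sprintf("gene%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

pair_key <- function(mirna_id, mrna_id) paste(mirna_id, mrna_id, sep = "\r")

# candidate list: the planted pairs plus background pairs sampled from the
# full product, deterministic
candidate_pairs <- function(truth, fc_mirna, fc_mrna, n_total, seed) {
  all <- enumerate_pairs(rownames(fc_mirna), rownames(fc_mrna))
  withr::with_seed(seed, {
    bg <- all[sample.int(nrow(all), n_total), , drop = FALSE]
    out <- rbind(truth[, c("mirna_id", "mrna_id")], bg)
    out <- out[!duplicated(out), , drop = FALSE][seq_len(n_total), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# paired dataset built directly from two matrices with shared samples
make_paired <- function(mir, mrna, unit_mir = "tpm", unit_mrna = "tpm") {
  align_paired(expression_matrix(mir, unit_mir), expression_matrix(mrna, unit_mrna))
}

named_matrix <- function(values, feat_prefix, n_feat, n_samp) {
  matrix(values, nrow = n_feat, ncol = n_samp,
         dimnames = list(sprintf("%s%d", feat_prefix, seq_len(n_feat)),
                         sprintf("s%d", seq_len(n_samp))))
}

# independent sum-of-products Pearson implementation (oracle; distinct from
# the package's centered-unit-row code path)
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# brute-force BH oracle: step-up over sorted p-values
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

expect_file_identical <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
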