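# mirpair

Statistical detection of miRNA–mRNA expression relationships in matched
samples.

microRNAs repress their target mRNAs through seed-region base pairing,
but sequence-based target predictors (miRanda, TargetScan) over-predict:
most predicted sites show no effect in cells. `mirpair` is for
transcriptomics analysts who have **matched miRNA and mRNA expression
from the same samples** — bulk or single-cell, raw counts or
CPM/TPM/RPKM — and want to know which candidate pairs carry actual
statistical evidence of a relationship. It complements (and can be
filtered by) sequence-based prediction scores.

## The three analyses

**Part 1 — regression across samples.** For each candidate pair, the mRNA
response *Y* is regressed on one or two miRNA predictors:

- univariate: *Y* = β₀ + β₁x₁ + ε
- multivariate: *Y* = β₀ + β₁x₁ + β₂x₂ + ε
- interaction: *Y* = β₀ + β₁x₁ + β₂x₂ + β₃x₁x₂ + ε

under Gaussian, Poisson, negative binomial, zero-inflated Poisson or
zero-inflated negative binomial families — or all five, keeping the fit
with the smallest AIC = 2k − 2 ln L (`family = "auto"`). Wald p-values on
the coefficient of interest are BH-adjusted across the run, with an
optional sign filter (negative = canonical repression) and a
co-prediction flag against a miRanda/TargetScan table.

**Part 2 — fold-change correlation.** Across ≥ 3 differential-expression
comparisons (time points, conditions), each pair is scored by the Pearson
correlation *r* of its log2 fold-change vectors. p-values are rank-based
against a resampled background of random cross-pairs, with the add-one
rule p = (1 + #{r_null ≤ r_obs})/(n_perm + 1), so the smallest attainable
p is 1/(n_perm + 1).

**Part 3 — two-timepoint interrelation.** Over a single interval, pairs
are scored by d = |x − y|, the absolute difference of the two log2 fold
changes, tested against the upper tail of a resampled cross-pair
background, and classified by fold-change sign pattern (miRNA-up/mRNA-down,
miRNA-down/mRNA-up, coregulation increase/decrease).

A synthetic-data module generates fixtures with planted ground truth for
every statistical path, and a CLI (`inst/cli/mirpair`) exposes
`part1` / `part2` / `part3` / `simulate` subcommands with reproducible
`run_config.yaml` run metadata.

## Worked example

Plant one repression (β₁ = −2) in a small matched dataset, then screen
all 50 miRNA–mRNA pairs:

```r
library(mirpair)

planted <- data.frame(mirna_id = "mir001", mrna_id = "gene0001",
                      beta0 = 3, beta1 = -2)
sim <- simulate_paired_counts(n_samples = 50, n_mirna = 5, n_mrna = 10,
                              planted = planted, family = "gaussian",
                              noise = list(sigma = 0.1), seed = 7)

select_model(sim$data, "gene0001", "mir001", formula = "univariate")
#> <pair_fit> gene0001 ~ mir001 [gaussian, univariate]
#>             beta          se             p
#> beta0 395.758211 0.021743674 8.398273e-166
#> beta1  -2.000388 0.000360602 4.928305e-141
#> AIC -67.880  logLik 36.940  R2 1.0000  converged TRUE

cand <- enumerate_pairs(rownames(sim$data$mirna), rownames(sim$data$mrna))
rep1 <- run_part1(sim$data, cand, family = "gaussian", direction = "negative")
head(rep1[, c("mrna_id", "mirna_id1", "beta1", "p_raw", "p_adj", "r2",
              "significant")], 3)
#>    mrna_id mirna_id1     beta1     p_raw     p_adj     r2 significant
#> 1 gene0001    mir001 -2.000388 4.93e-141 2.46e-139 1.0000        TRUE
#> 2 gene0010    mir004 -0.001306  2.68e-02  6.70e-01 0.0981       FALSE
#> 3 gene0003    mir002 -0.000558  5.97e-02  8.61e-01 0.0719       FALSE
```

The AIC comparison picks the Gaussian family, the planted slope −2 is
recovered to three decimals (the intercept absorbs the generator's
non-negativity shift), and after BH adjustment exactly the planted pair
is significant: `p_adj` for every unplanted pair is ≥ 0.67, while the
planted pair's is ~10⁻¹³⁹. The `r2` column is the squared correlation of
fitted versus observed response.

The same flow from the shell:

```sh
inst/cli/mirpair simulate part2 --seed 5 --out-dir fx/
inst/cli/mirpair part2 --fc-mirna fx/fc_mirna.tsv --fc-mrna fx/fc_mrna.tsv \
    --n-perm 1000 --seed 11 --r-max -0.85 --out part2.tsv
```

Every run writes a `run_config.yaml`; re-running with
`--config run_config.yaml` reproduces the output byte-for-byte.

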