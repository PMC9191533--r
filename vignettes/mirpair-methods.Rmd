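---
title: "Statistical models behind mirpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models behind mirpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpair)
```

microRNAs (miRNAs) repress messenger RNAs mostly through seed-region
complementarity with the target's 3′UTR, but a predicted binding site is
weak evidence on its own: most sequence-predicted interactions are never
observed in cells. `mirpair` asks the complementary question — given
matched miRNA and mRNA expression profiles from the *same* samples, which
predicted (or unknown) pairs show statistical evidence of a relationship?
It answers it three ways, each suited to a different experimental design.

## Part 1 — per-pair regression across samples

For an mRNA expression vector $Y$ (counts, CPM, TPM or RPKM) and miRNA
predictors $x_1$ (and optionally $x_2$), three model shapes are available:

* univariate: $Y = \beta_0 + \beta_1 x_1 + \varepsilon$
* multivariate: $Y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \varepsilon$
* interaction: $Y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3 x_1 x_2 + \varepsilon$

under five distribution families: Gaussian (identity link), Poisson and
negative binomial (log link), and their zero-inflated versions with a
constant logit-linked zero-inflation probability. Zero inflation is not
regressed on the miRNA — that is the smallest model consistent with the
family list, and the fitting surface (`fit_pair()`) is the place to extend
if structural zeros need covariates. The NB dispersion is estimated by
maximum likelihood jointly with the mean so that the AIC parameter count
is correct: $k$ counts the intercept and slopes, plus one for NB
dispersion, plus one for zero inflation where present, and for the
Gaussian family one for the residual variance.

`select_model()` fits all five families and keeps the converged fit with
the smallest $AIC = 2k - 2\ln L$. Count families are skipped when the
response is not integer-valued; there is *no* silent rounding, because a
count likelihood on coerced data is simply a different likelihood — the
`round_counts` argument makes the coercion explicit when the user wants
it. AIC ties break toward the simpler family in the fixed order Gaussian
< Poisson < NB < ZIP < ZINB, for determinism.

Coefficient p-values are Wald tests — $t$ for the Gaussian fit, $z$ for
the maximum-likelihood families. A likelihood-ratio alternative would be
asymptotically equivalent here and harder to oracle-test; Wald is also
what every GLM summary in the field reports. The per-fit $R^2$ is the
squared Pearson correlation between fitted and observed response: for
non-Gaussian fits there is no unique $R^2$, and this definition is
family-agnostic, bounded in $[0,1]$, and reduces to the classical
definition for ordinary least squares. A constant response or predictor
makes the fit degenerate; such fits are returned with $\beta_1 = 0$, a
p-value of 1 and a `degenerate` flag rather than an error, so batch runs
keep going.

`run_part1()` applies Benjamini–Hochberg adjustment once across all pairs
in a run, filters significance by the sign of the coefficient of interest
($\beta_1$, or $\beta_3$ for the interaction model — `direction =
"negative"` is the default because canonical miRNA action is repression),
and flags pairs that are co-predicted by a sequence-based table. The
`scale` argument multiplies the miRNA predictors before fitting; it is a
pure reparameterization for the Gaussian family (useful when TPM
magnitudes are tiny), with default 1.

## Part 2 — fold-change correlation across three or more comparisons

When the design is a time course (or any set of $\ge 3$ differential-
expression contrasts), each feature is summarized by its vector of log2
fold changes and pairs are scored by the Pearson correlation

$$r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
          {\sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}.$$

The package does not compute fold changes itself: any upstream DE tool's
output is accepted as a feature-by-comparison table, and the columns are
used as supplied.

Significance comes from a resampled background: random (miRNA, mRNA)
cross-pairs drawn with replacement from the two tables, with the rank-based
add-one p-value

$$p = \frac{1 + \#\{r_{null} \le r_{obs}\}}{n_{perm} + 1}$$

for the default negative (repression) alternative; positive and two-sided
alternatives mirror it. The add-one correction means $p = 0$ is
unattainable and the smallest possible p-value is $1/(n_{perm}+1)$ — with
the conventional default of 100 resamples that floor is $\approx 0.0099$,
so runs that need small BH-adjusted p-values over many candidate pairs
should raise `n_perm` (we recommend $\ge 1000$).

Two null modes are exposed. `"shared"` (default) draws one background for
the whole run: cost $O(n_{perm})$, appropriate at genome scale. Its
limitation is that the background's own Monte-Carlo error is shared by
every p-value in the run: the p-values are individually valid but
correlated, so the *empirical distribution* of p across pairs deviates
from uniform by roughly the Kolmogorov–Smirnov error of an
$n_{perm}$-point sample ($\approx 0.85/\sqrt{n_{perm}}$), however many
pairs are tested. `"per_pair"` draws an independent background for every
pair at $O(n_{pairs} \cdot n_{perm})$ cost and gives exactly calibrated
(discrete-uniform under the null) p-values; it is what the package's own
calibration tests use, and the right choice when downstream analysis
depends on the joint distribution of p-values rather than on individual
pair calls.

A caveat worth knowing: with very few comparisons the null correlation is
heavy-tailed (for $n = 3$ it follows an arcsine-type law with substantial
mass beyond $\pm 0.99$), so strong observed correlations are *not*
automatically significant. The permutation machinery accounts for this
correctly — it is the reason correlation-based screening wants as many
contrasts as the design affords. The package's own demonstrations and
tests use 8 comparisons.

## Part 3 — two-timepoint interrelation

With exactly one contrast per feature, pairs are scored by
$d = |x - y|$, the absolute difference between the miRNA's and the
mRNA's log2 fold change over the same interval. Significance is the
*upper* tail against a resampled cross-pair background,
$p = (1 + \#\{d_{null} \ge d_{obs}\})/(n_{perm}+1)$: a significant pair
is one whose two fold changes diverge more than random pairings do.
Each time interval is a separate run; the package does not pool
intervals into one test.

Separately from the test, every pair is classified by the sign pattern of
its two fold changes: miRNA up/mRNA down, miRNA down/mRNA up,
coregulation (increase), coregulation (decrease), with `no_change` for a
fold change at zero (within `zero_tol`, default 0 — upstream log2FCs are
essentially never exactly zero, but shrunken estimators warrant a small
tolerance). Classification is reported alongside the p-value, never
folded into it, because all four classes can be biologically meaningful
among significant pairs. Display labels ("Inverse Regulation",
"Coregulation (increase)", "Coregulation (reduction)") are applied only
at serialization through `regulation_labels()` and are user-replaceable —
field usage of these terms is not consistent, so the sign-pattern names
are authoritative inside the package.

## Prediction-score filtering

miRanda-style tables carry a composite score per (miRNA, gene) pair plus
folding energy and seed/alignment sub-scores; TargetScan tables carry a
context score percentile, which is mapped into the same `score` field.
Duplicate records per pair (miRanda emits one row per predicted site) are
collapsed keeping the maximum score — a target with several sites keeps
its best one. Filtering supports the two conventional usages: an
inclusive absolute floor (`min_score = 140` keeps scores $\ge 140$) and a
strict percentile cutoff (`percentile = 99` keeps scores strictly above
the 99th percentile of all scores in the table, computed by
linear-interpolation quantiles). All identifiers are matched
case-sensitively; no symbol mapping between annotation namespaces is
attempted.

## What the synthetic generator does (and does not) emulate

`simulate_paired_counts()` draws miRNA baselines from a log-normal
(meanlog 3, sdlog 1), mimicking the right-skewed magnitude heterogeneity
of CPM/TPM data, and generates planted mRNA responses through each
family's canonical link with stated coefficients; zero-inflated fixtures
default to a 0.3 inflation probability, large enough that ZI families are
AIC-distinguishable from their base families at $n = 100$. Gaussian
responses that cross zero are shifted up by a constant — expression is
non-negative, and the shift moves only the intercept, leaving the planted
slope and all AIC comparisons intact.

`simulate_fc_tables()` draws background log2 fold changes as i.i.d.
normal with sd 2 (a realistic genome-wide spread). Planted correlations
are constructed by orthogonal projection so the in-sample Pearson
correlation equals the target exactly; planted differences write the
canonical inverse-regulation pattern ($+d/2$ for the miRNA, $-d/2$ for
the mRNA) so $|x-y| = d$ exactly while both marginals stay moderate — a
one-sided shift would make planted features marginal outliers that
contaminate the resampled null. All generators are pure functions of
their seed: same seed, bit-identical output.

Not emulated: read-level sequencing noise, library-size normalization,
batch effects, correlated co-regulation structure among background genes,
and the heavy non-Gaussian tails of real DE fold-change estimates.
Passing recovery tests on these fixtures therefore demonstrates that the
statistical machinery is correct, not that any particular biological
dataset will yield calibrated discoveries.

## Problem sizes and numerical choices

The package's demonstration and test scales, chosen to emulate sparse
signal in a realistic feature space: regression screens with 20–200
candidate pairs at 50–100 samples; correlation/interrelation screens over
100 miRNAs × 400 mRNAs with 100–200 candidate pairs, 8 comparisons
(Part 2), planted $|r| = 0.99$ or $d = 10$, and 1000 resamples.
Calibration checks use 2000 null pairs at 200 resamples in per-pair mode.
Keeping planted pairs rare relative to the cross-pair space matters:
the resampled background is drawn from the observed tables, so a dense
planted signal contaminates its own null — exactly as a biological
dataset where half the transcriptome is truly regulated would.

Other numerical conventions: permutation p-values use the add-one rule
(p is never 0); BH adjustment is applied once per run across all tested
pairs; BH-significant sets use strict inequality `p_adj < alpha`
(default `alpha = 0.05`, freely settable); AIC ties break to the simpler
family; result tables serialize numerics at 10 significant digits and
round-trip losslessly; sample alignment takes the miRNA matrix's column
order and drops (with a logged message) samples missing on either side,
requiring at least 3 matched samples.

## Known limitations

* The interaction and multivariate designs take exactly two miRNAs; wider
  covariate sets (or sparse partial correlation in the style of elastic-net
  regularized approaches) are out of scope, though `fit_pair()`'s design
  is the natural extension point.
* Zero-inflation probability is constant per fit, not covariate-dependent.
* No spline or longitudinal modeling: time courses enter only through
  fold-change summaries.
* Empirical FDR in any single run fluctuates around the BH target; with
  few discoveries a realized false-discovery proportion above
  $\alpha$ is expected behavior, not an error.

## A worked miniature

```{r example}
planted <- data.frame(mirna_id = "mir001", mrna_id = "gene0001",
                      beta0 = 3, beta1 = -2)
sim <- simulate_paired_counts(n_samples = 50, n_mirna = 5, n_mrna = 10,
                              planted = planted, family = "gaussian",
                              noise = list(sigma = 0.1), seed = 7)
fit <- select_model(sim$data, "gene0001", "mir001", formula = "univariate")
fit
```

The planted slope of $-2$ is recovered, the Gaussian family wins the AIC
comparison, and the Wald p-value for $\beta_1$ is effectively zero —
which is what `run_part1()` then feeds into BH adjustment over a full
batch of candidate pairs.
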