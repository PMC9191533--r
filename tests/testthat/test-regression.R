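test_that("gaussian univariate fit matches the closed-form OLS solution", {
  withr::with_seed(101, {
    x <- rlnorm(30, 1, 0.6)
    y <- 3 - 2 * x + rnorm(30, 0, 0.01)
    y <- y - min(y)  # keep expression non-negative; shifts only the intercept
  })
  pd <- make_paired(named_matrix(x, "m", 1, 30), named_matrix(y, "g", 1, 30))
  fit <- fit_pair(pd, "g1", "m1", family = "gaussian", formula = "univariate")

  X <- cbind(1, x)
  beta_ols <- solve(t(X) %*% X, t(X) %*% y)  # independent normal-equations oracle
  expect_equal(unname(fit$beta["beta0"]), beta_ols[1], tolerance = 1e-8)
  expect_equal(unname(fit$beta["beta1"]), beta_ols[2], tolerance = 1e-8)
  expect_equal(unname(fit$beta["beta1"]), -2, tolerance = 0.05)
  expect_true(fit$converged)
  expect_gt(fit$r2, 0.99)
})

test_that("constant response or predictor yields a flagged degenerate fit", {
  pd <- make_paired(named_matrix(rep(2, 10), "m", 1, 10),
                    named_matrix(withr::with_seed(1, runif(10, 1, 5)), "g", 1, 10))
  fit <- fit_pair(pd, "g1", "m1")
  expect_true(fit$degenerate)
  expect_equal(unname(fit$beta["beta1"]), 0)
  expect_equal(unname(fit$pvalues["beta1"]), 1)
  expect_equal(fit$r2, 0)
})

test_that("interaction fits recover a planted synergy coefficient", {
  withr::with_seed(7, {
    x1 <- rlnorm(100, 0, 0.4)
    x2 <- rlnorm(100, 0, 0.4)
    y <- 1 + 0.5 * x1 - 0.3 * x2 + 1.5 * x1 * x2 + rnorm(100, 0, 0.1)
    y <- y - min(y)
  })
  pd <- make_paired(named_matrix(c(rbind(x1, x2)), "m", 2, 100),
                    named_matrix(y, "g", 1, 100))
  fit <- fit_pair(pd, "g1", c("m1", "m2"), formula = "interaction")
  expect_equal(unname(fit$beta["beta3"]), 1.5, tolerance = 0.1)
  expect_length(fit$beta, 4)
})

test_that("gaussian AIC equals the closed form n*ln(RSS/n) + 2k + n*ln(2pi) + n", {
  withr::with_seed(55, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      x <- rlnorm(n, 1, 0.5)
      y <- runif(1, 0, 5) + runif(1, -2, 2) * x + rnorm(n, 0, runif(1, 0.1, 2))
      y <- y - min(y)
      pd <- make_paired(named_matrix(x, "m", 1, n), named_matrix(y, "g", 1, n))
      fit <- fit_pair(pd, "g1", "m1")
      rss <- sum((y - (fit$beta["beta0"] + fit$beta["beta1"] * x))^2)
      k <- 3  # intercept, slope, residual variance
      expect_equal(fit$aic, n * log(rss / n) + 2 * k + n * log(2 * pi) + n,
                   tolerance = 1e-6)
    }
  })
})

test_that("the scale parameter is a pure predictor rescaling", {
  withr::with_seed(12, {
    x <- rlnorm(40, 2, 0.5)
    y <- 10 + 0.2 * x + rnorm(40, 0, 0.3)
  })
  pd1 <- make_paired(named_matrix(x, "m", 1, 40), named_matrix(y, "g", 1, 40))
  pd2 <- make_paired(named_matrix(x * 10, "m", 1, 40), named_matrix(y, "g", 1, 40))
  f1 <- fit_pair(pd1, "g1", "m1", scale = 1)
  f2 <- fit_pair(pd2, "g1", "m1", scale = 1 / 10)
  expect_equal(unname(f1$beta["beta1"]), unname(f2$beta["beta1"]), tolerance = 1e-8)
  expect_equal(unname(f1$pvalues["beta1"]), unname(f2$pvalues["beta1"]),
               tolerance = 1e-8)
})

test_that("count families demand integer responses unless rounding is requested", {
  pd <- make_paired(named_matrix(withr::with_seed(2, rlnorm(10, 1, 1)), "m", 1, 10),
                    named_matrix(withr::with_seed(3, runif(10, 1, 20)), "g", 1, 10))
  expect_error(fit_pair(pd, "g1", "m1", family = "poisson"), "integer")
  fit <- fit_pair(pd, "g1", "m1", family = "poisson", round_counts = TRUE)
  expect_s3_class(fit, "pair_fit")
  expect_true(is.finite(fit$aic))
})

test_that("each family reports an AIC consistent with its parameter count", {
  sim <- simulate_paired_counts(60, 2, 2, planted_pairs(1) |>
                                  transform(beta0 = 1, beta1 = 0.02),
                                family = "zero_inflated_poisson",
                                seed = 31)
  fits <- lapply(c("poisson", "negative_binomial", "zero_inflated_poisson",
                   "zero_inflated_negative_binomial"),
                 function(f) fit_pair(sim$data, "gene0001", "mir001", family = f))
  # 2k - 2logLik with k = coefficients (+1 dispersion for NB, +1 zero inflation)
  ks <- c(2, 3, 3, 4)
  for (i in seq_along(fits)) {
    expect_equal(fits[[i]]$aic, 2 * ks[i] - 2 * fits[[i]]$loglik, tolerance = 1e-8)
  }
})

test_that("AIC model selection picks matching families and honours explicit requests", {
  # continuous, linearly generated -> gaussian
  simg <- simulate_paired_counts(100, 2, 2,
                                 transform(planted_pairs(1), beta0 = 3, beta1 = -2),
                                 family = "gaussian", seed = 41)
  sel <- select_model(simg$data, "gene0001", "mir001")
  expect_identical(sel$family, "gaussian")
  aics <- attr(sel, "aic_by_family")
  expect_true(all(sel$aic <= aics[is.finite(aics)] + 1e-12))

  # log-linear counts -> poisson or negative binomial
  simp <- simulate_paired_counts(100, 2, 2,
                                 transform(planted_pairs(1), beta0 = 1, beta1 = 0.02),
                                 family = "poisson", seed = 42)
  selp <- select_model(simp$data, "gene0001", "mir001")
  expect_true(selp$family %in% c("poisson", "negative_binomial"))
  expect_true(all(selp$aic <= attr(selp, "aic_by_family") + 1e-12))

  # explicit family bypasses selection
  f <- fit_pair(simp$data, "gene0001", "mir001", family = "negative_binomial")
  expect_identical(f$family, "negative_binomial")
})

test_that("BH adjustment matches a sort-based step-up oracle", {
  withr::with_seed(77, {
    for (i in 1:10) {
      p <- runif(sample(1:100, 1))
      expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("the regression screen recovers planted repressions and respects direction", {
  planted <- transform(planted_pairs(5), beta0 = 3, beta1 = -2)
  sim <- simulate_paired_counts(50, 10, 20, planted, family = "gaussian",
                                noise = list(sigma = 0.1), seed = 11)
  cand <- rbind(planted[, 1:2],
                data.frame(mirna_id = sprintf("mir%03d", 6:10),
                           mrna_id = sprintf("gene%04d", 6:20)))
  rep1 <- run_part1(sim$data, cand, formula = "univariate", family = "gaussian",
                    alpha = 0.05, direction = "negative")
  sig <- rep1[rep1$significant, ]
  expect_true(all(pair_key(planted$mirna_id, planted$mrna_id) %in%
                    pair_key(sig$mirna_id1, sig$mrna_id)))
  expect_lte(sum(!pair_key(sig$mirna_id1, sig$mrna_id) %in%
                   pair_key(planted$mirna_id, planted$mrna_id)), 1)
  expect_true(all(diff(rank(rep1$p_adj, na.last = TRUE)) >= 0))

  # repressions cannot be significant under a positive-direction filter
  repp <- run_part1(sim$data, planted[, 1:2], formula = "univariate",
                    family = "gaussian", direction = "positive")
  expect_equal(sum(repp$significant), 0)
})

test_that("co-prediction summary counts and percentages are exact", {
  planted <- transform(planted_pairs(3), beta0 = 3, beta1 = -2)
  sim <- simulate_paired_counts(40, 3, 3, planted, family = "gaussian", seed = 19)
  pred <- prediction_table(data.frame(
    mirna_id = c("mir001", "mir002"), gene_id = c("gene0001", "gene0002"),
    score = c(150, 160)))
  rep1 <- run_part1(sim$data, planted[, 1:2], family = "gaussian",
                    predictions = pred)
  s <- attr(rep1, "summary")
  expect_equal(s$n_significant, 3)
  expect_equal(s$n_co_predicted, 2)
  expect_equal(s$pct_co_predicted, 66.67)
})

test_that("per-pair failures become flagged rows and the batch continues", {
  sim <- simulate_paired_counts(20, 3, 3, NULL, family = "gaussian", seed = 23)
  cand <- data.frame(mirna_id = c("mir001", "nosuchmir"),
                     mrna_id = c("gene0001", "gene0002"))
  rep1 <- run_part1(sim$data, cand, family = "gaussian")
  expect_equal(nrow(rep1), 2)
  bad <- rep1[!is.na(rep1$error), ]
  expect_equal(nrow(bad), 1)
  expect_match(bad$error, "nosuchmir")
  expect_false(bad$converged)
})

test_that("raw p-values are calibrated under a global null", {
  sim <- simulate_paired_counts(30, 25, 20, NULL, family = "gaussian",
                                noise = list(sigma = 5), seed = 59)
  cand <- enumerate_pairs(rownames(sim$data$mirna), rownames(sim$data$mrna))
  rep1 <- run_part1(sim$data, cand, family = "gaussian", direction = "both")
  frac <- mean(rep1$p_raw < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  expect_lte(sum(rep1$significant), 2)
})
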