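#' @importFrom MASS glm.nb
NULL

.FAMILIES <- c("gaussian", "poisson", "negative_binomial",
               "zero_inflated_poisson", "zero_inflated_negative_binomial")
.COUNT_FAMILIES <- .FAMILIES[-1]

#' Fit one miRNA-mRNA regression
#'
#' Fits the mRNA response (one row of the paired mRNA matrix) against one
#' or two miRNA predictors under the requested distribution family:
#'
#' * `univariate`:  `Y = b0 + b1*x1 + e`
#' * `multivariate`: `Y = b0 + b1*x1 + b2*x2 + e`
#' * `interaction`:  `Y = b0 + b1*x1 + b2*x2 + b3*x1*x2 + e`
#'
#' The Gaussian family uses the identity link; the count families model
#' the mean on the log link; the zero-inflated families add a constant
#' logit-linked zero-inflation probability. Coefficient p-values are Wald
#' tests (t for Gaussian, z for the maximum-likelihood families). The
#' pseudo-R-squared is the squared Pearson correlation between fitted and
#' observed response, a family-agnostic definition.
#'
#' @param data A `"paired_dataset"` from [align_paired()] or
#'   [simulate_paired_counts()].
#' @param mrna_id Response mRNA id (row of `data$mrna`).
#' @param mirna_ids One or two predictor miRNA ids (rows of `data$mirna`).
#' @param family One of `"gaussian"`, `"poisson"`, `"negative_binomial"`,
#'   `"zero_inflated_poisson"`, `"zero_inflated_negative_binomial"`; use
#'   [select_model()] for AIC-based multi-model selection.
#' @param formula One of `"univariate"`, `"multivariate"`, `"interaction"`.
#' @param scale Positive multiplier applied to the miRNA predictor values
#'   before fitting (useful when TPM/RPKM magnitudes are small). Default 1.
#' @param round_counts If `TRUE`, round a non-integer response before a
#'   count-family fit instead of erroring. Default `FALSE`: count
#'   likelihoods on silently coerced data are wrong, so the coercion must
#'   be explicit.
#' @return A list of class `"pair_fit"` with elements `mrna_id`,
#'   `mirna_ids`, `family`, `formula`, `beta`, `se`, `pvalues` (named
#'   `beta0`..`beta3` as applicable), `aic`, `loglik`, `r2`, `converged`,
#'   `degenerate` and `n`.
#' @export
fit_pair <- function(data, mrna_id, mirna_ids, family = "gaussian",
                     formula = c("univariate", "multivariate", "interaction"),
                     scale = 1, round_counts = FALSE) {
  formula <- match.arg(formula)
  family <- match.arg(family, .FAMILIES)
  stopifnot(scale > 0)
  n_mir <- if (formula == "univariate") 1L else 2L
  if (length(mirna_ids) != n_mir) {
    stop(sprintf("formula '%s' requires exactly %d miRNA predictor(s)",
                 formula, n_mir), call. = FALSE)
  }
  if (!mrna_id %in% rownames(data$mrna)) {
    stop("unknown mRNA id: ", mrna_id, call. = FALSE)
  }
  if (!all(mirna_ids %in% rownames(data$mirna))) {
    stop("unknown miRNA id(s): ",
         paste(setdiff(mirna_ids, rownames(data$mirna)), collapse = ", "),
         call. = FALSE)
  }

  y <- as.numeric(data$mrna[mrna_id, ])
  x1 <- as.numeric(data$mirna[mirna_ids[1], ]) * scale
  x2 <- if (n_mir == 2L) as.numeric(data$mirna[mirna_ids[2], ]) * scale else NULL
  n <- length(y)
  k_coef <- switch(formula, univariate = 2L, multivariate = 3L, interaction = 4L)
  if (n < k_coef + 2L) {
    stop(sprintf("need at least %d samples for a %s fit, have %d",
                 k_coef + 2L, formula, n), call. = FALSE)
  }

  if (family %in% .COUNT_FAMILIES) {
    if (any(abs(y - round(y)) > 1e-8)) {
      if (round_counts) {
        y <- round(y)
      } else {
        stop("response is not integer-valued; count families need counts ",
             "(use family = 'gaussian', or round_counts = TRUE to coerce)",
             call. = FALSE)
      }
    }
    y <- round(y)
  }

  coef_names <- c("beta0", "beta1", "beta2", "beta3")[seq_len(k_coef)]
  fit0 <- list(mrna_id = mrna_id, mirna_ids = mirna_ids, family = family,
               formula = formula,
               beta = stats::setNames(rep(NA_real_, k_coef), coef_names),
               se = stats::setNames(rep(NA_real_, k_coef), coef_names),
               pvalues = stats::setNames(rep(NA_real_, k_coef), coef_names),
               aic = NA_real_, loglik = NA_real_, r2 = NA_real_,
               converged = FALSE, degenerate = FALSE, n = n)
  class(fit0) <- "pair_fit"

  # singular design: a constant predictor carries no information
  if (stats::sd(x1) == 0 || (!is.null(x2) && stats::sd(x2) == 0)) {
    fit0$beta[] <- 0
    fit0$beta["beta0"] <- mean(y)
    fit0$pvalues[] <- 1
    fit0$r2 <- 0
    fit0$converged <- TRUE
    fit0$degenerate <- TRUE
    return(fit0)
  }

  d <- if (n_mir == 1L) data.frame(y = y, x1 = x1) else data.frame(y = y, x1 = x1, x2 = x2)
  fml <- switch(formula,
    univariate   = y ~ x1,
    multivariate = y ~ x1 + x2,
    interaction  = y ~ x1 + x2 + x1:x2
  )

  res <- tryCatch(.fit_engine(fml, d, family), error = function(e) NULL)
  if (is.null(res)) return(fit0)

  fit0$beta[] <- res$coef[seq_len(k_coef)]
  fit0$se[] <- res$se[seq_len(k_coef)]
  fit0$pvalues[] <- res$p[seq_len(k_coef)]
  fit0$loglik <- res$loglik
  fit0$aic <- 2 * res$df - 2 * res$loglik
  fit0$converged <- res$converged
  fit0$r2 <- if (stats::sd(y) == 0 || stats::sd(res$fitted) == 0) 0 else
    stats::cor(res$fitted, y)^2
  fit0
}

# One engine per family; returns coef/se/p in model order plus ll, df, fitted.
.fit_engine <- function(fml, d, family) {
  if (family == "gaussian") {
    m <- stats::lm(fml, data = d)
    s <- summary(m)$coefficients
    ll <- stats::logLik(m)
    return(list(coef = s[, 1], se = s[, 2], p = s[, 4],
                loglik = as.numeric(ll), df = attr(ll, "df"),
                fitted = stats::fitted(m), converged = TRUE))
  }
  if (family == "poisson") {
    m <- stats::glm(fml, data = d, family = stats::poisson())
    s <- summary(m)$coefficients
    ll <- stats::logLik(m)
    return(list(coef = s[, 1], se = s[, 2], p = s[, 4],
                loglik = as.numeric(ll), df = attr(ll, "df"),
                fitted = stats::fitted(m), converged = m$converged))
  }
  if (family == "negative_binomial") {
    m <- suppressWarnings(MASS::glm.nb(fml, data = d))
    s <- summary(m)$coefficients
    ll <- stats::logLik(m)   # df includes the ML dispersion parameter
    return(list(coef = s[, 1], se = s[, 2], p = s[, 4],
                loglik = as.numeric(ll), df = attr(ll, "df"),
                fitted = stats::fitted(m), converged = m$converged))
  }
  tmb_family <- if (family == "zero_inflated_poisson") glmmTMB::poisson
                else glmmTMB::nbinom2
  m <- suppressWarnings(
    glmmTMB::glmmTMB(fml, ziformula = ~1, family = tmb_family(), data = d)
  )
  # a singular Hessian yields NaN standard errors; the convergence check
  # below turns that into converged = FALSE rather than a warning
  s <- suppressWarnings(summary(m)$coefficients$cond)
  ll <- stats::logLik(m)     # df includes zero-inflation (and NB dispersion)
  conv <- isTRUE(m$fit$convergence == 0) && isTRUE(m$sdr$pdHess) &&
    all(is.finite(s[, 2]))
  list(coef = s[, 1], se = s[, 2], p = s[, 4],
       loglik = as.numeric(ll), df = attr(ll, "df"),
       fitted = stats::fitted(m), converged = conv)
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf("<pair_fit> %s ~ %s [%s, %s]\n", x$mrna_id,
              paste(x$mirna_ids, collapse = " + "), x$family, x$formula))
  print(data.frame(beta = x$beta, se = x$se, p = x$pvalues))
  cat(sprintf("AIC %.3f  logLik %.3f  R2 %.4f  converged %s%s\n",
              x$aic, x$loglik, x$r2, x$converged,
              if (isTRUE(x$degenerate)) "  (degenerate)" else ""))
  invisible(x)
}

#' Select the best distribution family by AIC
#'
#' Fits the pair under all five families (count families are skipped when
#' the response is not integer-valued) and returns the converged fit with
#' the smallest AIC. Ties break toward the simpler family in the order
#' gaussian < poisson < negative binomial < zero-inflated Poisson <
#' zero-inflated negative binomial.
#'
#' @inheritParams fit_pair
#' @return The winning `"pair_fit"`, with all per-family AICs in the
#'   `"aic_by_family"` attribute.
#' @export
select_model <- function(data, mrna_id, mirna_ids,
                         formula = c("univariate", "multivariate", "interaction"),
                         scale = 1, round_counts = FALSE) {
  formula <- match.arg(formula)
  y <- as.numeric(data$mrna[mrna_id, ])
  integer_response <- all(abs(y - round(y)) <= 1e-8) || round_counts
  families <- if (integer_response) .FAMILIES else "gaussian"
  fits <- lapply(families, function(fam) {
    tryCatch(fit_pair(data, mrna_id, mirna_ids, family = fam, formula = formula,
                      scale = scale, round_counts = round_counts),
             error = function(e) NULL)
  })
  names(fits) <- families
  aics <- vapply(fits, function(f) {
    if (is.null(f) || !isTRUE(f$converged) || !is.finite(f$aic)) Inf else f$aic
  }, numeric(1))
  if (all(!is.finite(aics))) {
    stop(sprintf("no family converged for pair (%s, %s)",
                 paste(mirna_ids, collapse = "+"), mrna_id), call. = FALSE)
  }
  best <- fits[[which.min(aics)]]  # which.min takes the first minimum: simplest family
  attr(best, "aic_by_family") <- aics
  best
}

#' Run the Part 1 regression screen over a batch of pairs
#'
#' Fits every pair, applies Benjamini-Hochberg adjustment once across all
#' tested pairs, filters significance by the sign of the coefficient of
#' interest (`beta1` for univariate/multivariate, `beta3` for interaction)
#' and flags pairs co-predicted by a sequence-based prediction table.
#' Per-pair fit failures are reported as flagged rows; the batch never
#' aborts.
#'
#' @param data A `"paired_dataset"`.
#' @param pairs For `formula = "univariate"` a `"pair_list"` (columns
#'   `mirna_id`, `mrna_id`); for the two-miRNA formulas a data frame with
#'   columns `mirna_id1`, `mirna_id2`, `mrna_id`.
#' @param formula,scale,round_counts As in [fit_pair()].
#' @param family A family name, or `"auto"` for AIC selection via
#'   [select_model()].
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param direction Which sign of the coefficient of interest counts as a
#'   hit: `"negative"` (canonical miRNA repression), `"positive"`, or
#'   `"both"`.
#' @param predictions Optional (pre-filtered) [prediction_table()] used to
#'   set the `co_predicted` flag.
#' @return A data frame of class `"part1_report"`, one row per pair, with
#'   columns `mrna_id`, `mirna_id1`, `mirna_id2`, `family`, `formula`,
#'   `beta0`..`beta3`, `se1`..`se3`, `p_raw`, `p_adj`, `r2`, `aic`,
#'   `direction`, `significant`, `co_predicted`, `converged`, sorted by
#'   `p_adj`, then `p_raw`, then ids. The `"summary"` attribute holds the
#'   significant-pair count and the co-prediction count and percentage.
#' @export
run_part1 <- function(data, pairs, formula = c("univariate", "multivariate", "interaction"),
                      family = "auto", scale = 1, alpha = 0.05,
                      direction = c("negative", "positive", "both"),
                      predictions = NULL, round_counts = FALSE) {
  formula <- match.arg(formula)
  direction <- match.arg(direction)
  family <- match.arg(family, c("auto", .FAMILIES))
  stopifnot(nrow(pairs) > 0)
  two_mir <- formula != "univariate"
  if (two_mir && !all(c("mirna_id1", "mirna_id2", "mrna_id") %in% names(pairs))) {
    stop("two-miRNA formulas need columns mirna_id1, mirna_id2, mrna_id",
         call. = FALSE)
  }
  if (!two_mir && !all(c("mirna_id", "mrna_id") %in% names(pairs))) {
    stop("pairs must have columns mirna_id and mrna_id", call. = FALSE)
  }

  coef_of_interest <- if (formula == "interaction") "beta3" else "beta1"
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    mir <- if (two_mir) c(pairs$mirna_id1[i], pairs$mirna_id2[i]) else pairs$mirna_id[i]
    mr <- pairs$mrna_id[i]
    fit <- tryCatch({
      if (family == "auto") {
        select_model(data, mr, mir, formula = formula, scale = scale,
                     round_counts = round_counts)
      } else {
        fit_pair(data, mr, mir, family = family, formula = formula,
                 scale = scale, round_counts = round_counts)
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(
        mrna_id = mr, mirna_id1 = mir[1],
        mirna_id2 = if (two_mir) mir[2] else NA_character_,
        family = NA_character_, formula = formula,
        beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_, beta3 = NA_real_,
        se1 = NA_real_, se2 = NA_real_, se3 = NA_real_,
        p_raw = NA_real_, r2 = NA_real_, aic = NA_real_,
        converged = FALSE, degenerate = FALSE,
        error = conditionMessage(fit), stringsAsFactors = FALSE)
      next
    }
    b <- fit$beta; se <- fit$se; p <- fit$pvalues
    g <- function(v, nm) if (nm %in% names(v)) unname(v[nm]) else NA_real_
    rows[[i]] <- data.frame(
      mrna_id = mr, mirna_id1 = mir[1],
      mirna_id2 = if (two_mir) mir[2] else NA_character_,
      family = fit$family, formula = formula,
      beta0 = g(b, "beta0"), beta1 = g(b, "beta1"),
      beta2 = g(b, "beta2"), beta3 = g(b, "beta3"),
      se1 = g(se, "beta1"), se2 = g(se, "beta2"), se3 = g(se, "beta3"),
      p_raw = g(p, coef_of_interest), r2 = fit$r2, aic = fit$aic,
      converged = fit$converged, degenerate = fit$degenerate,
      error = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)

  # non-converged fits are excluded from testing but kept as flagged rows
  testable <- out$converged & !is.na(out$p_raw)
  out$p_adj <- NA_real_
  out$p_adj[testable] <- stats::p.adjust(out$p_raw[testable], method = "BH")
  coef_val <- out[[coef_of_interest]]
  sign_ok <- switch(direction,
    negative = coef_val < 0,
    positive = coef_val > 0,
    both = rep(TRUE, nrow(out))
  )
  out$direction <- direction
  out$significant <- testable & !is.na(out$p_adj) & out$p_adj < alpha &
    !is.na(sign_ok) & sign_ok
  if (!is.null(predictions)) {
    key <- paste(predictions$mirna_id, predictions$gene_id, sep = "\r")
    out$co_predicted <- paste(out$mirna_id1, out$mrna_id, sep = "\r") %in% key
    if (two_mir) {
      out$co_predicted <- out$co_predicted |
        paste(out$mirna_id2, out$mrna_id, sep = "\r") %in% key
    }
  } else {
    out$co_predicted <- NA
  }
  ord <- order(out$p_adj, out$p_raw, out$mirna_id1, out$mrna_id, na.last = TRUE)
  out <- out[ord, c("mrna_id", "mirna_id1", "mirna_id2", "family", "formula",
                    "beta0", "beta1", "beta2", "beta3", "se1", "se2", "se3",
                    "p_raw", "p_adj", "r2", "aic", "direction", "significant",
                    "co_predicted", "converged", "degenerate", "error")]
  rownames(out) <- NULL
  n_sig <- sum(out$significant)
  n_cop <- if (is.null(predictions)) NA_integer_ else
    sum(out$significant & out$co_predicted)
  attr(out, "summary") <- list(
    n_pairs = nrow(out), n_significant = n_sig,
    n_co_predicted = n_cop,
    pct_co_predicted = if (!is.na(n_cop) && n_sig > 0)
      round(100 * n_cop / n_sig, 2) else NA_real_
  )
  class(out) <- c("part1_report", "data.frame")
  out
}
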