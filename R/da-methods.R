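#' @title Per-taxon differential-abundance tests
#' @description Six testing procedures built on the sign transforms:
#' marginal and conditional logistic regression on S-signs, marginal and
#' conditional probabilistic index models on R-signs, and
#' regression-imputation (RI) estimators of the marginal odds ratio (S) and
#' marginal probabilistic index (R). All tests are two-sided Wald tests of
#' the group coefficient.
#' @name da_methods
NULL

check_alignment <- function(counts, meta) {
  if (!identical(colnames(counts), meta$sample_id)) {
    stop("metadata sample order does not match the count table; ",
         "use read_metadata() to align")
  }
}

result_row <- function(taxon, method, estimate = NA_real_, se = NA_real_,
                       z = NA_real_, p = NA_real_, effect_size = NA_real_,
                       effect_scale = NA_character_, converged = FALSE,
                       firth_used = FALSE, rf_flag = FALSE) {
  data.frame(taxon_id = taxon, method = method, estimate = estimate,
             se = se, z = z, p = p, effect_size = effect_size,
             effect_scale = effect_scale, converged = converged,
             firth_used = firth_used, rf_flag = rf_flag,
             stringsAsFactors = FALSE)
}

glm_wald <- function(fit, coef) {
  b <- fit$coefficients[[coef]]
  se <- sqrt(fit$vcov[coef, coef])
  z <- if (b == 0) 0 else b / se
  list(estimate = b, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# design for S-sign logistic fits: intercept + A + internally standardized
# numeric covariates (zero-variance columns dropped, recorded as attribute)
s_design <- function(meta, covariates) {
  X <- cbind("(Intercept)" = 1, A = meta$group)
  dropped <- character(0)
  for (nm in covariates) {
    if (!nm %in% colnames(meta)) stop("unknown covariate '", nm, "'")
    v <- as.numeric(meta[[nm]])
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, nm)
    } else {
      X <- cbind(X, (v - mean(v)) / s)
      colnames(X)[ncol(X)] <- nm
    }
  }
  attr(X, "dropped") <- dropped
  X
}

#' @rdname da_methods
#' @param counts Validated (and typically prevalence-trimmed) count matrix.
#' @param meta Sample metadata from [read_metadata()].
#' @param rf A `reference_frame`.
#' @param taxon Target taxon identifier.
#' @param firth Firth policy for S-sign fits, see [fit_logistic_auto()].
#' @return For the `test_*` functions, a one-row data frame with columns
#'   `taxon_id, method, estimate, se, z, p, effect_size, effect_scale,
#'   converged, firth_used, rf_flag`; the estimate is the group coefficient
#'   (log odds ratio for S-methods, logit probabilistic index for R-model
#'   tests) and `effect_size` its interpretable transform.
#' @export
test_marginal_s <- function(counts, meta, rf, taxon, firth = "auto") {
  check_alignment(counts, meta)
  aref <- adjusted_reference(counts, rf, taxon)
  y <- s_sign(counts[taxon, ], aref)
  if (length(unique(y)) == 1L) {
    return(result_row(taxon, "s-marg", p = 1, converged = FALSE))
  }
  X <- s_design(meta, character(0))
  fit <- fit_logistic_auto(y, X, firth = firth)
  if (!fit$converged) {
    return(result_row(taxon, "s-marg", converged = FALSE,
                      firth_used = fit$firth_used))
  }
  w <- glm_wald(fit, "A")
  result_row(taxon, "s-marg", w$estimate, w$se, w$z, w$p,
             effect_size = exp(w$estimate), effect_scale = "odds_ratio",
             converged = TRUE, firth_used = fit$firth_used)
}

#' @rdname da_methods
#' @param covariates Metadata columns used as regressors in addition to the
#'   group indicator; conditional and RI methods default to the library size.
#' @export
test_conditional_s <- function(counts, meta, rf, taxon,
                               covariates = "library_size", firth = "auto") {
  check_alignment(counts, meta)
  aref <- adjusted_reference(counts, rf, taxon)
  y <- s_sign(counts[taxon, ], aref)
  if (length(unique(y)) == 1L) {
    return(result_row(taxon, "s-cond", p = 1, converged = FALSE))
  }
  X <- s_design(meta, covariates)
  fit <- fit_logistic_auto(y, X, firth = firth)
  if (!fit$converged) {
    return(result_row(taxon, "s-cond", converged = FALSE,
                      firth_used = fit$firth_used))
  }
  w <- glm_wald(fit, "A")
  result_row(taxon, "s-cond", w$estimate, w$se, w$z, w$p,
             effect_size = exp(w$estimate), effect_scale = "odds_ratio",
             converged = TRUE, firth_used = fit$firth_used)
}

#' @rdname da_methods
#' @export
test_marginal_r <- function(counts, meta, rf, taxon) {
  check_alignment(counts, meta)
  rs <- r_sign_matrix(counts[taxon, ], rf$r[colnames(counts)])
  design <- build_pim_design(rs, meta, marginal_only = TRUE)
  fit <- fit_pim(design)
  if (!fit$converged) {
    return(result_row(taxon, "r-marg", estimate = fit$coefficients[["dA"]],
                      effect_size = expit(fit$coefficients[["dA"]]),
                      effect_scale = "prob_index", converged = FALSE))
  }
  w <- pim_wald_test(fit, "dA")
  result_row(taxon, "r-marg", w$estimate, w$se, w$z, w$p,
             effect_size = expit(w$estimate), effect_scale = "prob_index",
             converged = TRUE)
}

#' @rdname da_methods
#' @export
test_conditional_r <- function(counts, meta, rf, taxon,
                               covariates = "library_size") {
  check_alignment(counts, meta)
  rs <- r_sign_matrix(counts[taxon, ], rf$r[colnames(counts)])
  design <- build_pim_design(rs, meta, covariate_names = covariates,
                             marginal_only = FALSE)
  fit <- fit_pim(design)
  if (!fit$converged) {
    return(result_row(taxon, "r-cond", estimate = fit$coefficients[["dA"]],
                      effect_size = expit(fit$coefficients[["dA"]]),
                      effect_scale = "prob_index", converged = FALSE))
  }
  w <- pim_wald_test(fit, "dA")
  result_row(taxon, "r-cond", w$estimate, w$se, w$z, w$p,
             effect_size = expit(w$estimate), effect_scale = "prob_index",
             converged = TRUE)
}

#' Regression-imputation estimator on S-signs
#'
#' Standardized (marginal) odds-ratio estimator using covariates as
#' auxiliary information: a conditional logistic model
#' \eqn{\hat p(A, L) = \mathrm{expit}(\hat\beta_0 + \hat\beta_A A +
#' \hat\beta_L L)} is fitted to the S-signs, counterfactual probabilities
#' are averaged over the empirical covariate distribution,
#' \eqn{\hat\pi(a) = n^{-1} \sum_i \hat p(a, L_i)}, and the marginal log
#' odds ratio is \eqn{\hat\beta_A^{RI} =
#' \log\{[\hat\pi(1)/(1-\hat\pi(1))] / [\hat\pi(0)/(1-\hat\pi(0))]\}}.
#' The variance is the empirical second moment of the influence curve,
#' \eqn{\hat\sigma_A^2 = n^{-2}\sum_i IC_i^2}, where each arm of
#' \eqn{IC_i} combines the inverse-probability residual
#' \eqn{(A_i/\delta)(I_i^S - \hat p(1, L_i))} with the standardization
#' residual \eqn{\hat p(1, L_i) - \hat\pi(1)}, weighted by
#' \eqn{1/\{\hat\pi(a)(1-\hat\pi(a))\}}, and \eqn{\delta} is the group-1
#' fraction. Validity requires group assignment independent of the
#' auxiliary covariates; for the library size alone this holds because
#' sequencing depth is a technical quantity.
#'
#' @inheritParams test_conditional_s
#' @param bootstrap Number of nonparametric bootstrap resamples for an
#'   alternative SE (0 = analytic IC variance only).
#' @param seed Optional seed for the bootstrap.
#' @return A list of class `ri_estimate_s`: `beta_RI` (marginal log odds
#'   ratio), `sigma` (IC-based SE), `boot_se` (or `NA`), `pi0`, `pi1`,
#'   `delta`, `ic`, `z`, `p`, `firth_used`.
#' @export
ri_s <- function(counts, meta, rf, taxon, covariates = "library_size",
                 bootstrap = 0L, seed = NULL, firth = "auto") {
  check_alignment(counts, meta)
  aref <- adjusted_reference(counts, rf, taxon)
  y <- s_sign(counts[taxon, ], aref)
  est <- ri_s_core(y, meta, covariates, firth)
  boot_se <- NA_real_
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(y)
    bvals <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(meta$group[idx])) < 2L) return(NA_real_)
      tryCatch(ri_s_core(y[idx], meta[idx, , drop = FALSE],
                         covariates, firth)$beta_RI,
               error = function(e) NA_real_)
    }, numeric(1))
    boot_se <- stats::sd(bvals, na.rm = TRUE)
  }
  est$boot_se <- boot_se
  class(est) <- "ri_estimate_s"
  est
}

ri_s_core <- function(y, meta, covariates, firth) {
  if (length(unique(y)) == 1L) stop("degenerate S-signs: all values equal")
  X <- s_design(meta, covariates)
  fit <- fit_logistic_auto(y, X, firth = firth)
  A <- meta$group
  delta <- mean(A)
  if (delta <= 0 || delta >= 1) stop("both groups must be present")
  X1 <- X; X1[, "A"] <- 1
  X0 <- X; X0[, "A"] <- 0
  p1 <- expit(drop(X1 %*% fit$coefficients))
  p0 <- expit(drop(X0 %*% fit$coefficients))
  pi1 <- mean(p1); pi0 <- mean(p0)
  if (pi1 <= 0 || pi1 >= 1 || pi0 <= 0 || pi0 >= 1) {
    stop("standardized probability on the boundary; RI estimator undefined")
  }
  beta_RI <- log((pi1 / (1 - pi1)) / (pi0 / (1 - pi0)))
  n <- length(y)
  ic <- 1 / (pi1 * (1 - pi1)) *
          (A / delta * (y - p1) + p1 - pi1) -
        1 / (pi0 * (1 - pi0)) *
          ((1 - A) / (1 - delta) * (y - p0) + p0 - pi0)
  sigma <- sqrt(sum(ic^2) / n^2)
  z <- beta_RI / sigma
  list(beta_RI = beta_RI, sigma = sigma, pi0 = pi0, pi1 = pi1,
       delta = delta, ic = ic, z = z, p = 2 * stats::pnorm(-abs(z)),
       firth_used = fit$firth_used)
}

#' Regression-imputation estimator on R-signs
#'
#' Standardized estimator of the marginal probabilistic index
#' \eqn{P\{N/R \preceq N^*/R^* \mid A = 0, A^* = 1\}}. A conditional PIM
#' \eqn{\hat p(L_1, L_2) = \mathrm{expit}(\hat\beta_A +
#' \hat\beta_L (L_2 - L_1))} is fitted to the R-signs, and the marginal
#' index is the average of its predictions over all ordered sample pairs,
#' \eqn{\hat\beta_A^{RI} = [n(n-1)]^{-1} \sum_i \sum_{j \ne i}
#' \hat p(L_j, L_i)}. The variance is the empirical second moment of the
#' influence curve, which combines group-weighted pair averages of the
#' R-signs, the centering term \eqn{-2\hat\beta_A^{RI}}, and an
#' \eqn{(A_i - \delta)} correction built from the model predictions. The
#' Wald statistic is \eqn{(\hat\beta_A^{RI} - 0.5)/\hat\sigma}.
#'
#' @inheritParams ri_s
#' @return A list of class `ri_estimate_r`: `beta_RI` (marginal
#'   probabilistic index, in (0,1)), `sigma`, `boot_se`, `delta`, `ic`,
#'   `z`, `p`.
#' @export
ri_r <- function(counts, meta, rf, taxon, covariates = "library_size",
                 bootstrap = 0L, seed = NULL) {
  check_alignment(counts, meta)
  r <- rf$r[colnames(counts)]
  N <- counts[taxon, ]
  est <- ri_r_core(N, r, meta, covariates)
  boot_se <- NA_real_
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(N)
    bvals <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(meta$group[idx])) < 2L) return(NA_real_)
      tryCatch(ri_r_core(N[idx], r[idx], meta[idx, , drop = FALSE],
                         covariates)$beta_RI,
               error = function(e) NA_real_)
    }, numeric(1))
    boot_se <- stats::sd(bvals, na.rm = TRUE)
  }
  est$boot_se <- boot_se
  class(est) <- "ri_estimate_r"
  est
}

ri_r_core <- function(N, r, meta, covariates) {
  rs <- r_sign_matrix(N, r)
  design <- build_pim_design(rs, meta, covariate_names = covariates,
                             marginal_only = FALSE)
  fit <- fit_pim(design)
  if (!fit$converged) stop("conditional PIM for the RI estimator diverged")
  A <- meta$group
  n <- length(A)
  delta <- mean(A)
  if (delta <= 0 || delta >= 1) stop("both groups must be present")
  betaA <- fit$coefficients[["dA"]]
  co <- fit$coefficients
  # linear predictor offset from covariates: eta[i, j] for p-hat(L_i, L_j)
  # = expit(betaA + sum_c beta_c (c_j - c_i))
  eta <- matrix(betaA, n, n)
  for (nm in setdiff(names(co), "dA")) {
    v <- as.numeric(meta[[nm]])
    eta <- eta + co[[nm]] * outer(v, v, function(a, b) b - a)
  }
  P <- expit(eta)                     # P[i, j] = p-hat(L_i, L_j)
  diag(P) <- NA
  off <- !is.na(P)
  # beta_RI = mean over ordered pairs of p-hat(L_j, L_i) = mean of t(P)
  beta_RI <- mean(P[off])             # symmetric in (i,j) enumeration
  # influence curve
  sum_AI <- vapply(seq_len(n), function(i) {
    sum(A[-i] * rs[i, -i])
  }, numeric(1))
  sum_negA_Iji <- vapply(seq_len(n), function(i) {
    sum((1 - A[-i]) * rs[-i, i])
  }, numeric(1))
  corr <- vapply(seq_len(n), function(i) {
    sum(P[i, -i] / (1 - delta) - P[-i, i] / delta)
  }, numeric(1))
  ic <- (1 - A) / (1 - delta) * (sum_AI / ((n - 1) * delta)) +
        A / delta * (sum_negA_Iji / ((n - 1) * (1 - delta))) -
        2 * beta_RI +
        (A - delta) * corr / (n - 1)
  sigma <- sqrt(sum(ic^2) / n^2)
  z <- (beta_RI - 0.5) / sigma
  list(beta_RI = beta_RI, sigma = sigma, delta = delta, ic = ic, z = z,
       p = 2 * stats::pnorm(-abs(z)), dropped = fit$dropped)
}

#' Effect-size conversions
#'
#' `or_from_beta()` maps a log odds ratio to the odds-ratio scale;
#' `pi_from_beta()` maps a logit-scale group contrast to the probabilistic
#' index \eqn{\mathrm{expit}(\beta)}.
#'
#' @param beta Finite coefficient value.
#' @return The odds ratio `exp(beta)` or probabilistic index `expit(beta)`.
#' @export
or_from_beta <- function(beta) {
  stopifnot(is.finite(beta))
  exp(beta)
}

#' @rdname or_from_beta
#' @export
pi_from_beta <- function(beta) {
  stopifnot(is.finite(beta))
  expit(beta)
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, monotone in the raw p-values).
#' Missing values pass through as missing and do not count toward the family
#' size.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run one DA method on every (non-reference) taxon
#'
#' Applies the chosen procedure to each taxon outside the reference frame,
#' adjusts the raw p-values with Benjamini–Hochberg within the run, and
#' flags discoveries at `p_adj <= alpha`. A failing taxon is recorded with
#' missing statistics and excluded from the BH family; the run continues.
#' Reference-frame taxa are excluded by default because testing a taxon
#' against a reference containing itself biases the comparison.
#'
#' @inheritParams test_conditional_s
#' @param method One of `"s-marg"`, `"s-cond"`, `"s-ri"`, `"r-marg"`,
#'   `"r-cond"`, `"r-ri"`.
#' @param covariates Covariates for conditional/RI methods (default library
#'   size; ignored by the marginal methods).
#' @param alpha Nominal FDR level for the discovery flag. Default 0.05.
#' @param seed Optional seed (used by RI bootstrap only).
#' @param include_rf Also test reference-frame taxa (flagged in `rf_flag`).
#' @return A data frame (one row per tested taxon) with columns
#'   `taxon_id, method, estimate, se, z, p, p_adj, effect_size,
#'   effect_scale, converged, firth_used, rf_flag, discovery`, sorted by
#'   `p_adj` then `taxon_id`.
#' @export
run_all_taxa <- function(counts, meta, rf,
                         method = c("s-marg", "s-cond", "s-ri",
                                    "r-marg", "r-cond", "r-ri"),
                         covariates = "library_size", alpha = 0.05,
                         seed = NULL, include_rf = FALSE, firth = "auto") {
  method <- match.arg(method)
  check_alignment(counts, meta)
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  taxa <- rownames(counts)
  if (!include_rf) taxa <- setdiff(taxa, rf$taxa)
  if (length(taxa) == 0L) stop("no taxa left to test outside the RF")
  rows <- vector("list", length(taxa))
  for (k in seq_along(taxa)) {
    tx <- taxa[k]
    row <- tryCatch(
      switch(method,
        "s-marg" = test_marginal_s(counts, meta, rf, tx, firth = firth),
        "s-cond" = test_conditional_s(counts, meta, rf, tx,
                                      covariates = covariates,
                                      firth = firth),
        "s-ri" = ri_row(ri_s(counts, meta, rf, tx, covariates = covariates,
                             firth = firth), tx, "s-ri"),
        "r-marg" = test_marginal_r(counts, meta, rf, tx),
        "r-cond" = test_conditional_r(counts, meta, rf, tx,
                                      covariates = covariates),
        "r-ri" = ri_row(ri_r(counts, meta, rf, tx,
                             covariates = covariates), tx, "r-ri")
      ),
      error = function(e) result_row(tx, method)
    )
    row$rf_flag <- tx %in% rf$taxa
    rows[[k]] <- row
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$discovery <- !is.na(res$p_adj) & res$p_adj <= alpha
  ord <- order(res$p_adj, res$taxon_id, na.last = TRUE)
  res <- res[ord, c("taxon_id", "method", "estimate", "se", "z", "p",
                    "p_adj", "effect_size", "effect_scale", "converged",
                    "firth_used", "rf_flag", "discovery")]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "rf_taxa") <- rf$taxa
  res
}

# flatten an RI estimate into a result row
ri_row <- function(est, taxon, method) {
  if (method == "s-ri") {
    result_row(taxon, method, estimate = est$beta_RI, se = est$sigma,
               z = est$z, p = est$p, effect_size = exp(est$beta_RI),
               effect_scale = "odds_ratio", converged = TRUE,
               firth_used = isTRUE(est$firth_used))
  } else {
    result_row(taxon, method, estimate = est$beta_RI, se = est$sigma,
               z = est$z, p = est$p, effect_size = est$beta_RI,
               effect_scale = "prob_index", converged = TRUE)
  }
}
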