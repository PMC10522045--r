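#' Build a probabilistic-index-model design from R-signs
#'
#' Turns an R-sign matrix into pairwise pseudo-observations for a
#' probabilistic index model (PIM) with logit link. Each unordered sample
#' pair is retained once, oriented `i < j` by sample index; the reverse
#' orientation is redundant because the pseudo-observation and pair
#' covariates are antisymmetric (\eqn{I_{ji} = 1 - I_{ij}},
#' \eqn{Z_{ji} = -Z_{ij}}), which leaves the logit-linear estimating
#' equations unchanged. Pair covariates are differences
#' \eqn{Z_{ij} = (A_j - A_i, L_j - L_i, X_j - X_i)}.
#'
#' For the purely marginal model (`marginal_only = TRUE`) same-group pairs
#' carry zero covariates and zero score, and are skipped for speed; in
#' conditional models they inform the library-size and covariate
#' coefficients and are retained. Covariate columns that are identically
#' zero across pairs (a constant covariate) are dropped with a record in
#' `$dropped`.
#'
#' @param rsigns R-sign matrix from [r_sign_matrix()], sample order matching
#'   `meta`.
#' @param meta Sample metadata (see [read_metadata()]).
#' @param covariate_names Metadata columns to difference into pair
#'   covariates (e.g. `"library_size"`).
#' @param marginal_only Keep only between-group pairs (marginal model).
#' @return A list of class `pim_design`: `pairs` (2-column index matrix),
#'   `y` (pseudo-observations), `Z` (pair covariate matrix with `dA` first),
#'   `n` (number of samples), `dropped` (names of dropped constant
#'   covariates).
#' @export
build_pim_design <- function(rsigns, meta, covariate_names = character(0),
                             marginal_only = length(covariate_names) == 0L) {
  n <- nrow(rsigns)
  if (nrow(meta) != n) stop("metadata and sign matrix sample counts differ")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  A <- meta$group
  dA <- A[j] - A[i]
  if (marginal_only) {
    keep <- dA != 0
    if (!any(keep)) stop("no between-group pairs: is the design two-group?")
    i <- i[keep]; j <- j[keep]; dA <- dA[keep]
  }
  Z <- cbind(dA = dA)
  dropped <- character(0)
  for (nm in covariate_names) {
    if (!nm %in% colnames(meta)) stop("unknown covariate '", nm, "'")
    v <- as.numeric(meta[[nm]])
    dz <- v[j] - v[i]
    if (all(dz == 0)) {
      dropped <- c(dropped, nm)
    } else {
      Z <- cbind(Z, dz)
      colnames(Z)[ncol(Z)] <- nm
    }
  }
  if (all(Z == 0)) stop("all pair covariates are zero; model is degenerate")
  y <- rsigns[cbind(i, j)]
  structure(list(pairs = cbind(i = i, j = j), y = as.numeric(y), Z = Z,
                 n = n, group = A, dropped = dropped),
            class = "pim_design")
}

#' Fit a probabilistic index model
#'
#' Solves the PIM estimating equations
#' \eqn{U(\beta) = \sum_{(i,j)} Z_{ij} (I_{ij} - \mathrm{expit}(Z_{ij}^T
#' \beta)) = 0} by Newton iteration from \eqn{\beta = 0}. The covariance is
#' the U-statistic sandwich \eqn{A^{-1} B A^{-T}} with
#' \eqn{A = \sum Z Z^T \mathrm{expit}'} and \eqn{B} the sum of residual
#' score cross-products over all couples of pairs sharing at least one
#' sample index (including each pair with itself), which is consistent under
#' the dependence induced by overlapping pairs. Because the per-sample score
#' sums are centered by the estimating equation, their empirical second
#' moment carries a finite-sample unbiased-divisor correction
#' \eqn{n_g/(n_g - 1)} within each treatment group (the same convention as
#' DeLong-type two-sample probabilistic-index variances); it vanishes as the
#' group sizes grow. Covariate columns are standardized internally for
#' conditioning and coefficients reported on the original scale.
#'
#' A degenerate probabilistic index of 0 or 1 (pseudo-observations all equal
#' on informative pairs) makes the estimate diverge; it is then capped at
#' \eqn{\pm 15} on the logit scale with `converged = FALSE`.
#'
#' @param design A `pim_design` from [build_pim_design()].
#' @param max_iter,tol Newton iteration controls.
#' @return A list of class `signda_pim`: `coefficients`, `vcov`,
#'   `converged`, `n_iter`, `dropped`.
#' @export
fit_pim <- function(design, max_iter = 50L, tol = 1e-8) {
  Z <- design$Z
  y <- design$y
  scl <- apply(Z, 2L, function(z) {
    s <- stats::sd(z)
    if (!is.finite(s) || s == 0) 1 else s
  })
  Zs <- sweep(Z, 2L, scl, "/")
  if (qr(Zs)$rank < ncol(Zs)) stop("pair covariates are collinear")
  k <- ncol(Zs)
  beta <- rep(0, k)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    eta <- drop(Zs %*% beta)
    p <- expit(eta)
    score <- drop(crossprod(Zs, y - p))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    A <- crossprod(Zs * w, Zs)
    step <- tryCatch(drop(solve(A, score)), error = function(e) NULL)
    if (is.null(step)) break
    # dampen huge steps so a degenerate PI walks, not jumps, to the cap
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 30) break
  }
  beta_orig <- beta / scl
  capped <- abs(beta_orig) > 15
  if (any(capped)) {
    beta_orig[capped] <- sign(beta_orig[capped]) * 15
    converged <- FALSE
    beta <- beta_orig * scl
  }
  eta <- drop(Zs %*% beta)
  p <- expit(eta)
  w <- p * (1 - p)
  A <- crossprod(Zs * w, Zs)
  V <- Zs * (y - p)                         # per-pair score contributions
  grp <- c(design$pairs[, 1L], design$pairs[, 2L])
  S <- rowsum(rbind(V, V), group = grp)     # per-sample sums of contributions
  # finite-sample correction: per-sample score sums are centered by the
  # estimating equation, so their second moment uses the unbiased divisor
  # n_g/(n_g - 1) within each treatment group (the DeLong convention for
  # two-sample probabilistic-index variance components)
  samp <- sort(unique(grp))
  gsz <- table(design$group[samp])
  cfac <- as.numeric(gsz[as.character(design$group[samp])])
  cfac <- ifelse(cfac > 1, cfac / (cfac - 1), 1)
  B <- crossprod(S * sqrt(cfac)) - crossprod(V)  # couples sharing >= 1 index
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  vcov_s <- if (is.null(Ainv)) matrix(NA_real_, k, k)
            else Ainv %*% B %*% t(Ainv)
  D <- diag(1 / scl, k)
  vcov <- D %*% vcov_s %*% D
  names(beta_orig) <- colnames(Z)
  dimnames(vcov) <- list(colnames(Z), colnames(Z))
  structure(list(coefficients = beta_orig, vcov = vcov,
                 converged = converged, n_iter = n_iter,
                 dropped = design$dropped),
            class = "signda_pim")
}

#' Wald test for a PIM coefficient
#'
#' @param fit A `signda_pim` fit.
#' @param coef Coefficient name (default `"dA"`, the group contrast).
#' @return List with `estimate`, `se`, `z` and two-sided normal `p`.
#' @export
pim_wald_test <- function(fit, coef = "dA") {
  if (!fit$converged) stop("PIM fit did not converge; Wald test unavailable")
  if (!coef %in% names(fit$coefficients)) stop("unknown coefficient: ", coef)
  b <- fit$coefficients[[coef]]
  se <- sqrt(fit$vcov[coef, coef])
  z <- if (b == 0) 0 else b / se
  list(estimate = b, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
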