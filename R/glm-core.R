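#' Logistic regression engine for S-sign outcomes
#'
#' Newton–Raphson maximum-likelihood and Firth bias-reduced logistic
#' regression accepting fractional responses in \[0, 1\]. S-signs take values
#' in \{0, 0.5, 1\}; ties (0.5) enter the Bernoulli log-likelihood at their
#' fractional value, which preserves the estimating-equation mean structure
#' \eqn{E[I^S] = p}. Firth's penalty \eqn{\frac{1}{2}\log\det I(\beta)} keeps
#' estimates finite under complete or quasi-complete separation.
#'
#' Iteration starts from \eqn{\beta = 0} with step-halving, and converges when
#' the maximum absolute score (penalized score for Firth) drops below `tol`.
#' The covariance is the inverse (penalized) Fisher information at the
#' estimate.
#'
#' @param y Responses in \[0, 1\].
#' @param design Design matrix including the intercept column; must have full
#'   column rank.
#' @param firth Logical; apply Firth's penalty.
#' @param max_iter Maximum Newton iterations (default 50).
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @return A list of class `signda_glm`: `coefficients`, `vcov`, `fitted`,
#'   `converged`, `firth_used`, `n_iter`, `separated`.
#' @name glm_core
NULL

expit <- function(x) stats::plogis(x)

logistic_loglik <- function(y, p) {
  eps <- 1e-12
  sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

fit_logistic <- function(y, design, firth = FALSE, max_iter = 50L,
                         tol = 1e-8) {
  X <- as.matrix(design)
  y <- as.numeric(y)
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  if (nrow(X) != length(y)) stop("design and response dimensions differ")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  beta <- rep(0, ncol(X))
  obj_at <- function(beta) {
    p <- expit(drop(X %*% beta))
    ll <- logistic_loglik(y, p)
    if (firth) {
      w <- p * (1 - p)
      info <- crossprod(X * w, X)
      d <- determinant(info, logarithm = TRUE)
      ll <- ll + 0.5 * as.numeric(d$modulus)
    }
    ll
  }
  converged <- FALSE
  n_iter <- 0L
  obj <- obj_at(beta)
  for (it in seq_len(max_iter)) {
    n_iter <- it
    p <- expit(drop(X %*% beta))
    w <- p * (1 - p)
    info <- crossprod(X * w, X)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break  # information singular: fitted values degenerate
    if (firth) {
      # hat diagonal of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
      h <- rowSums((X %*% inv) * X) * w
      score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    } else {
      score <- drop(crossprod(X, y - p))
    }
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    step <- drop(inv %*% score)
    # step-halving on the (penalized) log-likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      cobj <- obj_at(cand)
      if (is.finite(cobj) && cobj >= obj - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    beta <- beta + lambda * step
    obj <- obj_at(beta)
  }
  p <- expit(drop(X %*% beta))
  w <- p * (1 - p)
  info <- crossprod(X * w, X)
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  names(beta) <- colnames(X)
  if (!is.null(colnames(X)) && !anyNA(vcov)) {
    dimnames(vcov) <- list(colnames(X), colnames(X))
  }
  sep <- is_separated(beta, p, y)
  structure(list(coefficients = beta, vcov = vcov, fitted = p,
                 converged = converged, firth_used = firth,
                 n_iter = n_iter, separated = sep),
            class = "signda_glm")
}

is_separated <- function(beta, fitted, y) {
  if (any(abs(beta) > 15)) return(TRUE)
  disc <- y != 0.5  # discordant (non-tie) points
  if (!any(disc)) return(FALSE)
  all(pmin(fitted[disc], 1 - fitted[disc]) < 1e-8)
}

#' @rdname glm_core
#' @export
fit_logistic_ml <- function(y, design, max_iter = 50L, tol = 1e-8) {
  fit_logistic(y, design, firth = FALSE, max_iter = max_iter, tol = tol)
}

#' @rdname glm_core
#' @export
fit_logistic_firth <- function(y, design, max_iter = 100L, tol = 1e-8) {
  fit <- fit_logistic(y, design, firth = TRUE, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    stop("Firth fit did not converge within ", max_iter, " iterations")
  }
  fit
}

#' Detect separation in a logistic fit
#'
#' Flags complete or quasi-complete separation: the maximum-likelihood path
#' diverges, recognizable by a coefficient exceeding 15 on the linear scale or
#' by fitted probabilities within 1e-8 of 0/1 at every non-tied observation.
#'
#' @inheritParams glm_core
#' @return `TRUE` when the ML fit is separated or fails to converge with a
#'   diverging coefficient path.
#' @export
detect_separation <- function(y, design) {
  fit <- fit_logistic(y, design, firth = FALSE)
  fit$separated || !fit$converged
}

#' Fit with Firth fallback policy
#'
#' Fits by maximum likelihood first; on detected separation or
#' non-convergence refits with Firth's penalty (`firth = "auto"`, the
#' default). `"always"` and `"never"` force either path.
#'
#' @inheritParams glm_core
#' @param firth One of `"auto"`, `"always"`, `"never"`.
#' @return A `signda_glm` fit; `$firth_used` records whether the penalized
#'   fit was returned.
#' @export
fit_logistic_auto <- function(y, design,
                              firth = c("auto", "always", "never")) {
  firth <- match.arg(firth)
  if (firth == "always") return(fit_logistic(y, design, firth = TRUE,
                                             max_iter = 100L))
  fit <- fit_logistic(y, design, firth = FALSE)
  if (firth == "auto" && (fit$separated || !fit$converged)) {
    fit <- fit_logistic(y, design, firth = TRUE, max_iter = 100L)
  }
  fit
}
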