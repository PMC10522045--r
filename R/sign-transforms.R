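#' Half-open comparison indicator
#'
#' The tie-aware indicator \eqn{I\{a \preceq b\} = I\{a < b\} + 0.5\, I\{a = b\}}
#' underlying both sign transforms and the probabilistic index: 1 when
#' `a < b`, 0.5 on a tie, 0 when `a > b`. Vectorized with recycling.
#'
#' @param a,b Finite numeric vectors.
#' @return Numeric vector of values in \{0, 0.5, 1\}.
#' @export
half_indicator <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("half_indicator requires finite arguments")
  }
  (a < b) + 0.5 * (a == b)
}

#' S-sign transform
#'
#' Per-sample indicator that the target taxon's count lies below (1), ties
#' with (0.5) or exceeds (0) the adjusted per-sample reference. No ratios or
#' logarithms are involved, so zero counts need no pseudocounts.
#'
#' @param target_counts Per-sample counts of the target taxon.
#' @param adjusted_ref Per-sample adjusted reference, see
#'   [adjusted_reference()].
#' @return Numeric vector in \{0, 0.5, 1\}, one value per sample.
#' @export
s_sign <- function(target_counts, adjusted_ref) {
  if (length(target_counts) != length(adjusted_ref)) {
    stop("target_counts and adjusted_ref must have equal length")
  }
  half_indicator(as.numeric(target_counts), as.numeric(adjusted_ref))
}

#' R-sign matrix
#'
#' Pairwise between-sample comparison of reference-scaled abundances:
#' entry \eqn{(i, j)} indicates whether \eqn{N_i / R_i \preceq N_j / R_j}.
#' The comparison is evaluated in the cross-multiplied form
#' \eqn{I\{R_j N_i \preceq R_i N_j\}}, which involves no division: zero
#' counts and exact ties are handled exactly. The diagonal is 0.5 and the
#' matrix satisfies \eqn{I + I^T = 1} (antisymmetry under the tie
#' convention). Any taxon-specific rescaling of the reference cancels in the
#' pairwise ratios, so R-signs use the raw reference \eqn{R_i}.
#'
#' @param target_counts Per-sample counts of the target taxon.
#' @param ref Per-sample reference values \eqn{R_i} (from a
#'   `reference_frame`).
#' @return An n-by-n numeric matrix with values in \{0, 0.5, 1\},
#'   row/column names taken from the sample names of `target_counts` or
#'   `ref`.
#' @export
r_sign_matrix <- function(target_counts, ref) {
  n <- length(target_counts)
  if (length(ref) != n) stop("target_counts and ref must have equal length")
  N <- as.numeric(target_counts)
  R <- as.numeric(ref)
  lhs <- outer(N, R)            # [i, j] = N_i * R_j
  rhs <- outer(R, N)            # [i, j] = R_i * N_j
  m <- (lhs < rhs) + 0.5 * (lhs == rhs)
  nm <- names(target_counts)
  if (is.null(nm)) nm <- names(ref)
  dimnames(m) <- list(nm, nm)
  m
}
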