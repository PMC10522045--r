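#' Reference frames
#'
#' A reference frame (RF) is a set of approximately invariant taxa whose
#' per-sample median count \eqn{R_i} serves as the reference against which
#' target taxa are compared. `select_reference_frame()` picks one from the
#' data; `user_reference_frame()` builds one from a user-supplied taxon list
#' (e.g. prior knowledge of stable taxa).
#'
#' The automatic selector is a simplified invariance criterion: candidate
#' taxa must be present in at least `prevalence_threshold` of samples with a
#' mean count above `min_mean_count` (defaults 80% and 5). For every candidate
#' pair the variance of the between-sample log-ratio is computed over samples
#' where both counts are positive (no pseudocounts are ever added); pairs
#' whose ratio variance falls below the `ratio_var_quantile` quantile of all
#' candidate-pair variances are connected in a graph, and the largest
#' connected component of size at least `min_size` becomes the RF. A truly
#' invariant subset (counts proportional to library size) has ratio variance
#' zero on all its pairs and forms a clique. The procedure is deterministic;
#' ties between equally large components are broken by smallest taxon index.
#' Any external RF selection method can be used instead via
#' `user_reference_frame()`.
#'
#' @param counts Validated count matrix (ideally after [trim_low_prevalence()]).
#' @param prevalence_threshold Minimum fraction of samples a candidate must be
#'   present in. Lower this (e.g. to 0.6) for very sparse data.
#' @param min_mean_count Candidates must have mean count strictly greater than
#'   this.
#' @param ratio_var_quantile Quantile of candidate-pair log-ratio variances
#'   below which a pair is connected. Default 0.25.
#' @param min_size Minimum RF size. Default 3.
#' @return An object of class `reference_frame`: a list with `taxa` (character
#'   vector, members of the RF), `r` (named numeric, per-sample reference
#'   \eqn{R_i} = median of RF counts in sample \eqn{i}) and `source`
#'   (`"auto"` or `"user"`).
#' @export
select_reference_frame <- function(counts, prevalence_threshold = 0.8,
                                   min_mean_count = 5,
                                   ratio_var_quantile = 0.25, min_size = 3) {
  stopifnot(prevalence_threshold >= 0, prevalence_threshold <= 1,
            ratio_var_quantile > 0, ratio_var_quantile <= 1, min_size >= 1)
  prev <- rowMeans(counts > 0)
  mn <- rowMeans(counts)
  cand <- which(prev >= prevalence_threshold & mn > min_mean_count)
  if (length(cand) < min_size) {
    stop("only ", length(cand), " candidate reference taxa pass the filter ",
         "(need >= ", min_size, "); consider lowering prevalence_threshold ",
         "(e.g. 0.8 -> 0.6 for sparse data)")
  }
  sub <- counts[cand, , drop = FALSE]
  k <- nrow(sub)
  logc <- log(sub)
  logc[sub == 0] <- NA_real_  # log-ratio variance over doubly-positive samples
  vmat <- matrix(NA_real_, k, k)
  for (a in seq_len(k - 1L)) {
    d <- logc[rep(a, k - a), , drop = FALSE] -
      logc[(a + 1L):k, , drop = FALSE]
    v <- apply(d, 1L, stats::var, na.rm = TRUE)
    vmat[a, (a + 1L):k] <- v
    vmat[(a + 1L):k, a] <- v
  }
  vals <- vmat[upper.tri(vmat)]
  if (all(is.na(vals))) stop("no candidate pair shares positive counts")
  thr <- stats::quantile(vals, ratio_var_quantile, na.rm = TRUE, names = FALSE)
  thr <- max(thr, 1e-10)  # exactly proportional pairs carry fp-noise variance
  adj <- !is.na(vmat) & vmat <= thr
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # deterministic tie-break: component containing the smallest taxon index
    first_member <- vapply(best, function(b) min(which(comp$membership == b)),
                           integer(1))
    best <- best[which.min(first_member)]
  }
  members <- cand[comp$membership == best]
  if (length(members) < min_size) {
    stop("largest invariant component has ", length(members),
         " taxa (need >= ", min_size, "); consider lowering ",
         "prevalence_threshold or raising ratio_var_quantile")
  }
  new_reference_frame(counts, rownames(counts)[members], source = "auto")
}

#' @rdname select_reference_frame
#' @param taxa Character vector of taxon identifiers to use as the RF.
#' @export
user_reference_frame <- function(counts, taxa) {
  taxa <- as.character(taxa)
  unknown <- setdiff(taxa, rownames(counts))
  if (length(unknown)) {
    stop("reference taxa not found in count table: ",
         paste(unknown, collapse = ", "))
  }
  if (length(taxa) < 1L) stop("reference frame must contain at least one taxon")
  new_reference_frame(counts, taxa, source = "user")
}

#' Read a reference-taxon list (one taxon identifier per line)
#'
#' @param path Plain-text file, one taxon ID per line; blank lines and lines
#'   starting with `#` are skipped.
#' @param counts Validated count matrix.
#' @return A `reference_frame` (see [select_reference_frame()]).
#' @export
read_reference_frame <- function(path, counts) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  user_reference_frame(counts, lines)
}

new_reference_frame <- function(counts, taxa, source) {
  sub <- counts[taxa, , drop = FALSE]
  r <- apply(sub, 2L, stats::median)
  structure(list(taxa = taxa, r = r, source = source),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("Reference frame (", x$source, "): ", length(x$taxa), " taxa\n",
      sep = "")
  cat("  ", paste(utils::head(x$taxa, 10L), collapse = ", "),
      if (length(x$taxa) > 10L) ", ..." else "", "\n", sep = "")
  cat("  per-sample reference R: median ", stats::median(x$r),
      ", range [", min(x$r), ", ", max(x$r), "]\n", sep = "")
  invisible(x)
}

#' Taxon-adjusted reference
#'
#' The raw reference \eqn{R_i} is typically much larger than the counts of an
#' individual (possibly rare) taxon, which would make almost every S-sign
#' equal to 1. The reference is therefore rescaled per target taxon by
#' `median(target counts) / median(R)`, computed over all samples (both groups
#' pooled). When the target's median is zero (majority-zero taxon) the
#' arithmetic mean of the target's counts is used as the numerator instead,
#' and the result is flagged; a zero adjusted reference would make every
#' S-sign 0 or 0.5.
#'
#' @param counts Validated count matrix.
#' @param rf A `reference_frame`.
#' @param taxon Target taxon identifier.
#' @return Numeric vector of per-sample adjusted reference values, with
#'   attributes `factor` (the shared adjustment factor) and `fallback`
#'   (`TRUE` when the mean-based numerator was used).
#' @export
adjusted_reference <- function(counts, rf, taxon) {
  if (!taxon %in% rownames(counts)) stop("unknown taxon: ", taxon)
  r <- rf$r[colnames(counts)]
  if (anyNA(r)) stop("reference frame does not cover all samples")
  med_r <- stats::median(r)
  if (med_r == 0) {
    stop("degenerate reference frame: median reference count is zero")
  }
  target <- counts[taxon, ]
  med_t <- stats::median(target)
  fallback <- med_t == 0
  fac <- (if (fallback) mean(target) else med_t) / med_r
  structure(r * fac, factor = fac, fallback = fallback)
}
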