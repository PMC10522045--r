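# shared fixture builders; everything is generated in code

make_counts <- function(m, taxa = NULL, samples = NULL) {
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  validate_counts(m)
}

make_meta <- function(counts, group, library_size = NULL, ...) {
  df <- data.frame(sample_id = colnames(counts), group = as.integer(group),
                   library_size = if (is.null(library_size))
                     as.numeric(colSums(counts)) else library_size,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# NB dataset with a built-in invariant reference block (first `n_rf` taxa
# proportional to an underlying per-sample scale) plus NB-noise taxa
make_nb_dataset <- function(n_per_group = 15, n_taxa = 12, n_rf = 3,
                            mu = 30, size = 2, seed = 1,
                            constant_lib = FALSE) {
  set.seed(seed)
  n <- 2L * n_per_group
  scale <- if (constant_lib) rep(1, n) else runif(n, 0.5, 2)
  m <- matrix(0L, n_taxa, n)
  for (t in seq_len(n_rf)) {
    m[t, ] <- as.integer(round(50 * t * scale))
  }
  for (t in (n_rf + 1L):n_taxa) {
    m[t, ] <- as.integer(rnbinom(n, mu = mu * scale, size = size))
  }
  counts <- make_counts(m)
  meta <- make_meta(counts, group = rep(0:1, each = n_per_group),
                    library_size = if (constant_lib) rep(5000, n) else NULL)
  rf <- user_reference_frame(counts, rownames(counts)[seq_len(n_rf)])
  list(counts = counts, meta = meta, rf = rf)
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
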