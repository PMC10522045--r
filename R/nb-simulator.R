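#' Synthetic negative-binomial parameter pool
#'
#' Generates a pool of per-taxon (mean, overdispersion) pairs and a library
#' size pool for the NB simulator, emulating the empirical features such
#' pools have when estimated from real 16S data: log-means from a
#' heavy-tailed distribution spanning roughly four orders of magnitude,
#' overdispersion linked to the mean through a decreasing trend plus noise
#' (so a mean-dispersion relationship exists and its rank correlation is
#' negative), and log-normal library sizes around a configurable median. In
#' `simulate_dataset()` mean/dispersion pairs are always drawn jointly (same
#' pool entry), preserving the relationship. An importer hook
#' ([read_parameter_pool()]) accepts pools estimated from user data instead.
#'
#' @param n_taxa Number of pool entries. Default 250.
#' @param seed Optional seed.
#' @param median_library Median of the library-size pool. Default 10000.
#' @param library_sdlog Log-scale SD of library sizes. Default 0.6.
#' @param n_libraries Size of the library pool. Default 500.
#' @return A list of class `nb_pool`: `mean`, `dispersion` (parallel numeric
#'   vectors) and `libraries` (positive integers).
#' @export
default_parameter_pool <- function(n_taxa = 250L, seed = NULL,
                                   median_library = 1e4,
                                   library_sdlog = 0.6,
                                   n_libraries = 500L) {
  if (!is.null(seed)) set.seed(seed)
  # log10-means: heavy-tailed (t with 3 df), clamped to ~4 orders of magnitude
  x <- 0.5 + 0.8 * stats::rt(n_taxa, df = 3)
  x <- pmin(pmax(x, -1.5), 2.5)
  mu <- 10^x
  # overdispersion decreasing in the mean, with log-normal noise
  phi <- exp(0.5 - 0.5 * log(mu) + stats::rnorm(n_taxa, 0, 0.5))
  lib <- pmax(round(stats::rlnorm(n_libraries, log(median_library),
                                  library_sdlog)), 100)
  structure(list(mean = mu, dispersion = phi, libraries = as.numeric(lib)),
            class = "nb_pool")
}

#' Read a user-estimated parameter pool
#'
#' @param path TSV with columns `taxon`, `mean`, `dispersion` (one pool entry
#'   per row).
#' @param libraries Numeric vector of library sizes to resample from.
#' @return An `nb_pool`.
#' @export
read_parameter_pool <- function(path, libraries) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (nm in c("mean", "dispersion")) {
    if (!nm %in% colnames(df)) stop("pool file lacks column '", nm, "'")
  }
  if (any(df$mean <= 0) || any(df$dispersion < 0)) {
    stop("pool means must be > 0 and dispersions >= 0")
  }
  structure(list(mean = df$mean, dispersion = df$dispersion,
                 libraries = as.numeric(libraries)),
            class = "nb_pool")
}

#' Simulate a two-group negative-binomial microbiome dataset
#'
#' Per taxon a (mean, overdispersion) pair is drawn with replacement from
#' the pool (jointly, from the same entry). `round(da_fraction * n_taxa)`
#' taxa are marked differentially abundant and their group-1 means
#' multiplied by `fold_change`, with direction (up/down) randomized 50/50
#' per taxon. Per-sample library sizes are resampled with replacement from
#' the library pool; the expected count of taxon \eqn{t} in sample \eqn{i}
#' of group \eqn{g} is \eqn{L_i \pi_{g,t}}, where the group proportions
#' \eqn{\pi_{g,t}} are renormalized to sum to one when
#' `compositional_renorm = TRUE` (so raising the differentially abundant
#' taxa suppresses all the rest - the compositional effect) and are raw
#' scaled means otherwise. Counts are negative binomial with variance
#' \eqn{\mu + \phi \mu^2} (Poisson when \eqn{\phi = 0}). Deterministic
#' given `seed`.
#'
#' @param n_taxa Number of taxa. Default 250.
#' @param n_per_group Samples per group.
#' @param fold_change Fold change applied to differentially abundant taxa
#'   (> 0). Default 1.
#' @param da_fraction Fraction of taxa differentially abundant, in \[0, 1\].
#'   Default 0.
#' @param prop_up Probability that a differentially abundant taxon goes up in
#'   group 1 (default 0.5, a symmetric mix). Values near 0 or 1 create a
#'   strong compositional compensation effect: under renormalization a
#'   one-sided shift of the affected taxa displaces every null taxon in the
#'   opposite direction.
#' @param pool An `nb_pool`; a default pool is generated when `NULL`.
#' @param compositional_renorm Renormalize group proportions (default TRUE).
#' @param seed Optional seed.
#' @return A list of class `sim_dataset`: `counts` (validated matrix),
#'   `meta` (metadata with `group` 0/1 and library sizes of the generated
#'   table), `truth` (named logical, TRUE for DA taxa), `da_direction`
#'   (named, +1/-1 for DA taxa, 0 otherwise).
#' @export
simulate_dataset <- function(n_taxa = 250L, n_per_group,
                             fold_change = 1, da_fraction = 0,
                             prop_up = 0.5, pool = NULL,
                             compositional_renorm = TRUE, seed = NULL) {
  stopifnot(n_taxa >= 1L, n_per_group >= 2L, fold_change > 0,
            da_fraction >= 0, da_fraction <= 1, prop_up >= 0, prop_up <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- default_parameter_pool(n_taxa)
  stopifnot(inherits(pool, "nb_pool"), length(pool$mean) >= 1L,
            length(pool$libraries) >= 1L)

  pick <- sample.int(length(pool$mean), n_taxa, replace = TRUE)
  mu <- pool$mean[pick]
  phi <- pool$dispersion[pick]

  n_da <- round(da_fraction * n_taxa)
  truth <- rep(FALSE, n_taxa)
  direction <- rep(0L, n_taxa)
  if (n_da > 0L) {
    da_idx <- sample.int(n_taxa, n_da)
    truth[da_idx] <- TRUE
    direction[da_idx] <- sample(c(-1L, 1L), n_da, replace = TRUE,
                                prob = c(1 - prop_up, prop_up))
  }
  fc_vec <- fold_change^direction
  mu1 <- mu * fc_vec

  scale0 <- sum(mu)
  p0 <- mu / scale0
  p1 <- if (compositional_renorm) mu1 / sum(mu1) else mu1 / scale0

  n <- 2L * n_per_group
  group <- rep(c(0L, 1L), each = n_per_group)
  L <- pool$libraries[sample.int(length(pool$libraries), n, replace = TRUE)]

  counts <- matrix(0L, n_taxa, n)
  for (i in seq_len(n)) {
    m_i <- L[i] * (if (group[i] == 0L) p0 else p1)
    pois <- phi == 0
    x <- numeric(n_taxa)
    if (any(pois)) x[pois] <- stats::rpois(sum(pois), m_i[pois])
    if (any(!pois)) {
      x[!pois] <- stats::rnbinom(sum(!pois), mu = m_i[!pois],
                                 size = 1 / phi[!pois])
    }
    counts[, i] <- as.integer(x)
  }
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  samples <- sprintf("sample_%03d", seq_len(n))
  dimnames(counts) <- list(taxa, samples)
  names(truth) <- names(direction) <- taxa
  meta <- data.frame(sample_id = samples, group = group,
                     library_size = as.numeric(colSums(counts)),
                     stringsAsFactors = FALSE)
  attr(meta, "group_levels") <- c("0", "1")
  params <- data.frame(taxon_id = taxa, mean = mu, dispersion = phi,
                       prop_group0 = p0, prop_group1 = p1,
                       stringsAsFactors = FALSE)
  structure(list(counts = validate_counts(counts), meta = meta,
                 truth = truth, da_direction = direction, params = params),
            class = "sim_dataset")
}

#' Score a result table against simulation truth
#'
#' Discoveries are taxa with BH-adjusted p at or below `alpha`. Sensitivity
#' is TP/(TP+FN) among truly differentially abundant taxa, the false
#' discovery proportion is FP/max(1, discoveries) (zero discoveries give
#' FDR 0), and the type-I error rate is the fraction of true-null taxa with
#' raw p at or below `alpha` (failed fits excluded).
#'
#' @param results Result table from [run_all_taxa()].
#' @param truth Named logical vector of true DA status (must cover every
#'   tested taxon).
#' @param alpha Significance / FDR level. Default 0.05.
#' @return A list: `sensitivity`, `fdr`, `type1`, `n_discoveries`,
#'   `n_tested`.
#' @export
evaluate <- function(results, truth, alpha = 0.05) {
  if (is.null(names(truth)) || !all(results$taxon_id %in% names(truth))) {
    stop("truth must be a named vector covering every tested taxon")
  }
  tr <- truth[results$taxon_id]
  disc <- !is.na(results$p_adj) & results$p_adj <= alpha
  tp <- sum(disc & tr)
  fp <- sum(disc & !tr)
  n_da <- sum(tr)
  sens <- if (n_da == 0L) NA_real_ else tp / n_da
  fdr <- fp / max(1L, sum(disc))
  null_p <- results$p[!tr]
  type1 <- if (all(tr)) NA_real_ else mean(null_p <= alpha, na.rm = TRUE)
  list(sensitivity = sens, fdr = fdr, type1 = type1,
       n_discoveries = sum(disc), n_tested = nrow(results))
}

#' Simulation scenario description
#'
#' @param n_taxa,n_per_group,fold_change,da_fraction,prop_up,compositional_renorm
#'   Passed to [simulate_dataset()].
#' @param name Scenario label used in benchmark output.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_taxa = 250L, n_per_group = 25L, fold_change = 1,
                         da_fraction = 0, prop_up = 0.5,
                         compositional_renorm = TRUE, name = NULL) {
  if (is.null(name)) {
    name <- sprintf("t%d_n%d_fc%g_da%g", n_taxa, n_per_group, fold_change,
                    da_fraction)
  }
  structure(list(n_taxa = n_taxa, n_per_group = n_per_group,
                 fold_change = fold_change, da_fraction = da_fraction,
                 prop_up = prop_up,
                 compositional_renorm = compositional_renorm, name = name),
            class = "sim_scenario")
}

#' Benchmark DA methods over simulated scenarios
#'
#' For every scenario/method combination, simulates `n_replicates` datasets
#' (replicate seeds derived deterministically from `seed`), applies the 5%
#' prevalence trim, selects a reference frame per replicate (automatic
#' selection with a 0.6 prevalence fallback, or an oracle RF of true-null
#' taxa when `rf = "oracle"`), runs the method over all non-RF taxa with BH
#' adjustment, and aggregates sensitivity, FDR and type-I error with
#' Monte-Carlo standard errors.
#'
#' @param scenarios A `sim_scenario` or list of them.
#' @param methods Character vector of method names (see [run_all_taxa()]).
#' @param n_replicates Replicates per scenario. Default 10.
#' @param seed Base seed for the replicate seed schedule.
#' @param pool Optional shared `nb_pool` (a fresh default pool per replicate
#'   when `NULL`).
#' @param alpha Nominal level. Default 0.05.
#' @param rf `"auto"` (selected per replicate) or `"oracle"` (true-null taxa
#'   passing the candidate filter).
#' @param keep_replicates Also return the per-replicate metric table.
#' @return A data frame with one row per (scenario, method): mean
#'   sensitivity/FDR/type-I error, their Monte-Carlo SEs, mean RF size, mean
#'   number of DA taxa inside the RF, and replicate failure count. With
#'   `keep_replicates = TRUE` the per-replicate table is attached as
#'   `attr(, "replicates")`.
#' @export
run_benchmark <- function(scenarios, methods, n_replicates = 10L,
                          seed = 1L, pool = NULL, alpha = 0.05,
                          rf = c("auto", "oracle"),
                          keep_replicates = FALSE) {
  rf <- match.arg(rf)
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  stopifnot(n_replicates >= 1L)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, n_replicates)

  rep_rows <- list()
  for (sc in scenarios) {
    for (r in seq_len(n_replicates)) {
      sim <- tryCatch(replicate_run(sc, methods, rep_seeds[r], pool, alpha,
                                    rf),
                      error = function(e) e)
      if (inherits(sim, "error")) {
        for (m in methods) {
          rep_rows[[length(rep_rows) + 1L]] <-
            data.frame(scenario = sc$name, method = m, replicate = r,
                       sensitivity = NA_real_, fdr = NA_real_,
                       type1 = NA_real_, rf_size = NA_real_,
                       rf_da = NA_real_, failed = TRUE,
                       stringsAsFactors = FALSE)
        }
      } else {
        sim$replicate <- r
        rep_rows[[length(rep_rows) + 1L]] <- sim
      }
    }
  }
  reps <- do.call(rbind, rep_rows)
  mc_se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  agg <- do.call(rbind, lapply(split(reps, list(reps$scenario, reps$method),
                                     drop = TRUE), function(d) {
    data.frame(scenario = d$scenario[1L], method = d$method[1L],
               n_replicates = nrow(d),
               sensitivity = mean(d$sensitivity, na.rm = TRUE),
               sensitivity_se = mc_se(d$sensitivity),
               fdr = mean(d$fdr, na.rm = TRUE), fdr_se = mc_se(d$fdr),
               type1 = mean(d$type1, na.rm = TRUE),
               type1_se = mc_se(d$type1),
               rf_size = mean(d$rf_size, na.rm = TRUE),
               rf_da = mean(d$rf_da, na.rm = TRUE),
               n_failed = sum(d$failed), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (keep_replicates) attr(agg, "replicates") <- reps
  agg
}

replicate_run <- function(sc, methods, rep_seed, pool, alpha, rf_mode) {
  sim <- simulate_dataset(n_taxa = sc$n_taxa, n_per_group = sc$n_per_group,
                          fold_change = sc$fold_change,
                          da_fraction = sc$da_fraction,
                          prop_up = sc$prop_up, pool = pool,
                          compositional_renorm = sc$compositional_renorm,
                          seed = rep_seed)
  trimmed <- trim_low_prevalence(sim$counts)
  rf <- select_rf_with_fallback(trimmed, sim, rf_mode)
  rows <- lapply(methods, function(m) {
    res <- run_all_taxa(trimmed, sim$meta, rf, method = m, alpha = alpha,
                        seed = rep_seed)
    ev <- evaluate(res, sim$truth, alpha = alpha)
    data.frame(scenario = sc$name, method = m,
               sensitivity = ev$sensitivity, fdr = ev$fdr,
               type1 = ev$type1, rf_size = length(rf$taxa),
               rf_da = sum(sim$truth[rf$taxa]), failed = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

select_rf_with_fallback <- function(trimmed, sim, rf_mode) {
  if (rf_mode == "oracle") {
    prev <- rowMeans(trimmed > 0)
    mn <- rowMeans(trimmed)
    cand <- rownames(trimmed)[prev >= 0.8 & mn > 5 &
                                !sim$truth[rownames(trimmed)]]
    if (length(cand) < 3L) stop("oracle RF has fewer than 3 taxa")
    return(user_reference_frame(trimmed, cand))
  }
  tryCatch(select_reference_frame(trimmed),
           error = function(e) {
             select_reference_frame(trimmed, prevalence_threshold = 0.6)
           })
}
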