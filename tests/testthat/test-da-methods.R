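test_that("effect-size conversions map coefficients to odds ratios and probabilistic indices", {
  # the printed coefficient -3.135 is itself rounded, so the odds ratio is
  # reproduced to within one unit in the last printed digit
  expect_equal(or_from_beta(-3.135), 0.044, tolerance = 0.001 / 0.044)
  expect_equal(round(or_from_beta(-2.841), 3), 0.058)
  expect_equal(or_from_beta(0), 1)
  expect_equal(round(pi_from_beta(0.511), 3), 0.625)
  expect_equal(round(pi_from_beta(0.433), 2), 0.61)
  expect_equal(pi_from_beta(0), 0.5)
  # an odds ratio of ~0.044 is a 96% reduction in the odds
  expect_equal(round(100 * (1 - or_from_beta(-3.135))), 96)
  expect_equal(round(100 * (1 - 0.044)), 96)
})

test_that("BH adjustment is the step-up procedure, monotone and capped", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(61)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))  # nondecreasing in p
  # NA p-values pass through without joining the family
  p2 <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p2), c(0.02, NA, 0.04))
})

test_that("conditional and RI estimators collapse to the marginal ones when L is constant", {
  d <- make_nb_dataset(n_per_group = 15, seed = 62, constant_lib = TRUE)
  tx <- "t08"
  ms <- test_marginal_s(d$counts, d$meta, d$rf, tx)
  cs <- test_conditional_s(d$counts, d$meta, d$rf, tx)
  ris <- ri_s(d$counts, d$meta, d$rf, tx)
  expect_equal(cs$estimate, ms$estimate, tolerance = 1e-9)
  expect_equal(ris$beta_RI, ms$estimate, tolerance = 1e-9)
  mr <- test_marginal_r(d$counts, d$meta, d$rf, tx)
  cr <- test_conditional_r(d$counts, d$meta, d$rf, tx)
  rir <- ri_r(d$counts, d$meta, d$rf, tx)
  expect_equal(cr$estimate, mr$estimate, tolerance = 1e-9)
  expect_equal(rir$beta_RI, plogis(mr$estimate), tolerance = 1e-9)
  # influence values average to ~0 at the RI-S solution
  expect_lt(abs(mean(ris$ic)), 1e-6)
})

test_that("a strong constructed effect is detected with the right sign", {
  set.seed(63)
  n <- 20
  m <- matrix(0L, 5, 2 * n)
  for (t in 1:3) m[t, ] <- as.integer(sample(40:60, 2 * n, replace = TRUE))
  m[4, ] <- c(as.integer(rnbinom(n, mu = 20, size = 1)),
              as.integer(rnbinom(n, mu = 250, size = 1)))
  m[5, ] <- as.integer(rpois(2 * n, 50))
  counts <- make_counts(m)
  meta <- make_meta(counts, group = rep(0:1, each = n))
  rf <- user_reference_frame(counts, c("t01", "t02", "t03"))
  # group 1 well above the adjusted reference: P{N <= R} drops, beta_A < 0
  s <- test_marginal_s(counts, meta, rf, "t04")
  expect_lt(s$estimate, 0)
  expect_lt(s$p, 0.001)
  r <- test_marginal_r(counts, meta, rf, "t04")
  expect_gt(plogis(r$estimate), 0.8)
  expect_lt(r$p, 0.001)
  # the null taxon is quiet
  r0 <- test_marginal_r(counts, meta, rf, "t05")
  expect_gt(r0$p, 0.05)
})

test_that("separation in the S-sign fit triggers the Firth fallback", {
  n <- 8
  m <- matrix(0L, 4, 2 * n)
  for (t in 1:3) m[t, ] <- as.integer(sample(40:44, 2 * n, replace = TRUE))
  m[4, ] <- c(rep(1L, n), rep(400L, n))  # complete separation across groups
  counts <- make_counts(m)
  meta <- make_meta(counts, group = rep(0:1, each = n))
  rf <- user_reference_frame(counts, c("t01", "t02", "t03"))
  res <- test_marginal_s(counts, meta, rf, "t04")
  expect_true(res$firth_used)
  expect_true(res$converged)
  expect_true(is.finite(res$estimate))
})

test_that("run_all_taxa keeps bookkeeping, ordering and determinism", {
  d <- make_nb_dataset(n_per_group = 12, n_taxa = 10, seed = 64)
  res <- run_all_taxa(d$counts, d$meta, d$rf, method = "r-marg")
  expect_equal(nrow(res), nrow(d$counts) - length(d$rf$taxa))
  expect_false(any(res$taxon_id %in% d$rf$taxa))
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  o <- order(res$p_adj, res$taxon_id, na.last = TRUE)
  expect_equal(o, seq_len(nrow(res)))
  res2 <- run_all_taxa(d$counts, d$meta, d$rf, method = "r-marg")
  expect_identical(res, res2)
  # include_rf tests everything and flags RF members
  all_res <- run_all_taxa(d$counts, d$meta, d$rf, method = "r-marg",
                          include_rf = TRUE)
  expect_equal(nrow(all_res), nrow(d$counts))
  expect_equal(sum(all_res$rf_flag), length(d$rf$taxa))
})

test_that("methods are invariant to taxon permutation and deletion of untested taxa", {
  d <- make_nb_dataset(n_per_group = 12, n_taxa = 10, seed = 65)
  tx <- "t07"
  base <- list(
    s = test_marginal_s(d$counts, d$meta, d$rf, tx),
    r = test_marginal_r(d$counts, d$meta, d$rf, tx),
    ris = ri_s(d$counts, d$meta, d$rf, tx)$beta_RI,
    rir = ri_r(d$counts, d$meta, d$rf, tx)$beta_RI)
  set.seed(66)
  perm <- d$counts[sample(nrow(d$counts)), ]
  rf_p <- user_reference_frame(perm, d$rf$taxa)
  expect_equal(test_marginal_s(perm, d$meta, rf_p, tx), base$s)
  expect_equal(test_marginal_r(perm, d$meta, rf_p, tx), base$r)
  sub <- d$counts[c(d$rf$taxa, tx), ]
  rf_s <- user_reference_frame(sub, d$rf$taxa)
  expect_equal(test_marginal_s(sub, d$meta, rf_s, tx), base$s)
  expect_equal(test_marginal_r(sub, d$meta, rf_s, tx), base$r)
  expect_equal(ri_s(sub, d$meta, rf_s, tx)$beta_RI, base$ris)
  expect_equal(ri_r(sub, d$meta, rf_s, tx)$beta_RI, base$rir)
})

test_that("degenerate S-signs yield p = 1 with a flag and failures stay in the table", {
  # an all-zero taxon ties its (zero) adjusted reference in every sample
  m <- rbind(rep(50L, 10), rep(49L, 10), rep(51L, 10),
             rep(0L, 10))
  counts <- make_counts(m)
  meta <- make_meta(counts, group = rep(0:1, each = 5))
  rf <- user_reference_frame(counts, c("t01", "t02", "t03"))
  res <- test_marginal_s(counts, meta, rf, "t04")
  expect_equal(res$p, 1)
  expect_false(res$converged)
})
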