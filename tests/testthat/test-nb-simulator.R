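test_that("parameter pools are valid, reproducible, with a negative mean-dispersion trend", {
  p1 <- default_parameter_pool(1000, seed = 71)
  p2 <- default_parameter_pool(1000, seed = 71)
  expect_identical(p1, p2)
  expect_true(all(p1$mean > 0))
  expect_true(all(p1$dispersion >= 0))
  expect_true(all(p1$libraries > 0))
  expect_lt(cor(p1$mean, p1$dispersion, method = "spearman"), 0)
  # spans several orders of magnitude
  expect_gt(log10(max(p1$mean) / min(p1$mean)), 2.5)
})

test_that("simulated datasets respect the configuration exactly", {
  sim <- simulate_dataset(n_taxa = 250, n_per_group = 10,
                          fold_change = 5, da_fraction = 0.10, seed = 72)
  expect_equal(sum(sim$truth), 25L)
  expect_equal(sum(sim$da_direction != 0), 25L)
  expect_equal(dim(sim$counts), c(250L, 20L))
  expect_equal(sim$meta$library_size, unname(colSums(sim$counts)))
  sim2 <- simulate_dataset(n_taxa = 250, n_per_group = 10,
                           fold_change = 5, da_fraction = 0.10, seed = 72)
  expect_identical(sim2$counts, sim$counts)
  # null configuration: no DA truth and identical group proportions
  null <- simulate_dataset(n_taxa = 50, n_per_group = 10, seed = 73)
  expect_false(any(null$truth))
})

test_that("simulated counts match the negative-binomial moments", {
  pool <- structure(list(mean = c(50, 200, 10, 400, 90),
                         dispersion = c(0.3, 0.1, 0.4, 0.05, 0.2),
                         libraries = 1e4), class = "nb_pool")
  sim <- simulate_dataset(n_taxa = 5, n_per_group = 2500, fold_change = 1,
                          da_fraction = 0, pool = pool, seed = 74)
  # with a fixed library the expected count is L * mu_t / sum(mu drawn)
  mu_t <- 1e4 * sim$params$prop_group0
  phi_t <- sim$params$dispersion
  for (t in which(mu_t >= 10)) {
    x <- as.numeric(sim$counts[t, ])
    expect_equal(mean(x), mu_t[t], tolerance = 0.05)
    expect_equal(var(x), mu_t[t] + phi_t[t] * mu_t[t]^2, tolerance = 0.05)
  }
})

test_that("evaluation metrics follow the stated conventions", {
  taxa <- sprintf("x%02d", 1:100)
  truth <- setNames(c(rep(TRUE, 25), rep(FALSE, 75)), taxa)
  p_adj <- rep(1, 100)
  p_adj[c(1:18, 26, 27)] <- 0.01       # 18 true + 2 false discoveries
  res <- data.frame(taxon_id = taxa, p = p_adj, p_adj = p_adj)
  ev <- evaluate(res, truth)
  expect_equal(ev$sensitivity, 18 / 25)
  expect_equal(ev$fdr, 2 / 20)
  # zero discoveries: FDR 0 by the max(1, .) convention
  res0 <- data.frame(taxon_id = taxa, p = rep(0.9, 100),
                     p_adj = rep(0.9, 100))
  ev0 <- evaluate(res0, truth)
  expect_equal(ev0$fdr, 0)
  expect_equal(ev0$sensitivity, 0)
  # perfect discovery
  resp <- data.frame(taxon_id = taxa, p = c(rep(0.001, 25), rep(0.9, 75)),
                     p_adj = c(rep(0.004, 25), rep(0.9, 75)))
  evp <- evaluate(resp, truth)
  expect_equal(evp$sensitivity, 1)
  expect_equal(evp$fdr, 0)
  expect_error(evaluate(data.frame(taxon_id = "zz", p = 0.5, p_adj = 0.5),
                        truth), "covering")
})

test_that("the benchmark aggregates per scenario and method, reproducibly", {
  scens <- list(sim_scenario(n_taxa = 60, n_per_group = 10, name = "null"),
                sim_scenario(n_taxa = 60, n_per_group = 10, fold_change = 5,
                             da_fraction = 0.10, name = "fc5"))
  b <- run_benchmark(scens, "r-marg", n_replicates = 2, seed = 75,
                     keep_replicates = TRUE)
  expect_equal(nrow(b), 2L)
  expect_setequal(b$scenario, c("null", "fc5"))
  expect_equal(nrow(attr(b, "replicates")), 4L)
  expect_true(all(c("sensitivity", "fdr", "type1", "type1_se") %in%
                    colnames(b)))
  b2 <- run_benchmark(scens, "r-marg", n_replicates = 2, seed = 75)
  expect_equal(b$fdr, b2$fdr)
  expect_equal(b$type1, b2$type1)
})

test_that("power increases with fold change", {
  scens <- list(sim_scenario(n_per_group = 25, fold_change = 1.5,
                             da_fraction = 0.10, name = "fc1.5"),
                sim_scenario(n_per_group = 25, fold_change = 5,
                             da_fraction = 0.10, name = "fc5"))
  b <- run_benchmark(scens, "r-marg", n_replicates = 3, seed = 76)
  sens <- setNames(b$sensitivity, b$scenario)
  expect_gt(sens["fc5"], sens["fc1.5"])
})
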