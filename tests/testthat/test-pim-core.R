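test_that("pair designs enumerate each unordered pair once with differenced covariates", {
  rs <- matrix(0.5, 4, 4)
  meta <- data.frame(sample_id = paste0("s", 1:4), group = c(0L, 0L, 1L, 1L),
                     library_size = c(100, 200, 250, 300))
  d <- build_pim_design(rs, meta, marginal_only = FALSE)
  expect_equal(nrow(d$pairs), choose(4, 2))
  # same-group pairs have zero group difference
  dm <- build_pim_design(rs, meta, marginal_only = TRUE)
  expect_equal(nrow(dm$pairs), 4L)  # 2 x 2 between-group pairs
  expect_true(all(dm$Z[, "dA"] != 0))
  # conditional covariates by differencing: pair (s1, s3)
  dc <- build_pim_design(rs, meta, covariate_names = "library_size",
                         marginal_only = FALSE)
  row13 <- which(dc$pairs[, "i"] == 1 & dc$pairs[, "j"] == 3)
  expect_equal(unname(dc$Z[row13, ]), c(1, 150))
  # single-group data has no informative pairs for the marginal model
  meta1 <- meta; meta1$group <- 0L
  expect_error(build_pim_design(rs, meta1, marginal_only = TRUE),
               "between-group")
})

test_that("the marginal PIM equals the Mann-Whitney proportion exactly", {
  # toy: g0 = (1,2,3), g1 = (2,4,5); 9 between pairs, one tie at (2,2)
  cnt <- make_counts(rbind(c(1L, 2L, 3L, 2L, 4L, 5L), rep(1L, 6)))
  meta <- make_meta(cnt, group = rep(0:1, each = 3))
  rf <- user_reference_frame(cnt, "t02")
  res <- test_marginal_r(cnt, meta, rf, "t01")
  expect_equal(plogis(res$estimate), 7.5 / 9, tolerance = 1e-9)
  expect_equal(res$estimate, log(7.5 / 1.5), tolerance = 1e-8)

  # brute force over random small datasets
  set.seed(51)
  for (k in 1:100) {
    n0 <- sample(3:6, 1); n1 <- sample(3:6, 1)
    N <- rnbinom(n0 + n1, mu = 6, size = 0.8)
    R <- sample(1:9, n0 + n1, replace = TRUE)
    meta <- data.frame(sample_id = as.character(seq_len(n0 + n1)),
                       group = rep(0:1, c(n0, n1)),
                       library_size = rep(1, n0 + n1))
    I <- r_sign_matrix(N, R)
    d <- build_pim_design(I, meta, marginal_only = TRUE)
    fit <- fit_pim(d)
    mw <- mean(outer(seq_len(n0), n0 + seq_len(n1),
                     Vectorize(function(i, j) I[i, j])))
    if (mw > 0 && mw < 1) {
      expect_equal(plogis(fit$coefficients[["dA"]]), mw, tolerance = 1e-8)
    } else {
      expect_false(fit$converged)
    }
  }
})

test_that("identical group value multisets give a zero estimate and p = 1", {
  vals <- c(3L, 8L, 1L, 3L, 8L, 1L)
  cnt <- make_counts(rbind(vals, rep(2L, 6)))
  meta <- make_meta(cnt, group = rep(0:1, each = 3))
  rf <- user_reference_frame(cnt, "t02")
  res <- test_marginal_r(cnt, meta, rf, "t01")
  expect_equal(res$estimate, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
})

test_that("the fit is invariant to pair orientation", {
  set.seed(52)
  N <- rnbinom(10, mu = 10, size = 1)
  meta <- data.frame(sample_id = as.character(1:10),
                     group = rep(0:1, each = 5),
                     library_size = runif(10, 500, 1500))
  I <- r_sign_matrix(N, rep(1, 10))
  d <- build_pim_design(I, meta, covariate_names = "library_size",
                        marginal_only = FALSE)
  fit <- fit_pim(d)
  flip <- seq(1, nrow(d$pairs), by = 2)
  d2 <- d
  d2$y[flip] <- 1 - d2$y[flip]
  d2$Z[flip, ] <- -d2$Z[flip, ]
  fit2 <- fit_pim(d2)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit$vcov, fit2$vcov, tolerance = 1e-8)
})

test_that("a degenerate probabilistic index is capped and flagged", {
  cnt <- make_counts(rbind(c(1L, 2L, 3L, 10L, 11L, 12L), rep(1L, 6)))
  meta <- make_meta(cnt, group = rep(0:1, each = 3))
  rf <- user_reference_frame(cnt, "t02")
  I <- r_sign_matrix(cnt["t01", ], rf$r)
  d <- build_pim_design(I, meta, marginal_only = TRUE)
  fit <- fit_pim(d)
  expect_false(fit$converged)
  expect_equal(abs(fit$coefficients[["dA"]]), 15)
  expect_error(pim_wald_test(fit), "converge")
})

test_that("the sandwich variance tracks the analytic Mann-Whitney variance", {
  # tie-free null data at n = 100: Var(p-hat) = (n0 + n1 + 1) / (12 n0 n1);
  # compare the average delta-method sandwich variance by Monte Carlo
  set.seed(53)
  n0 <- n1 <- 50
  analytic <- (n0 + n1 + 1) / (12 * n0 * n1)
  meta <- data.frame(sample_id = as.character(1:(n0 + n1)),
                     group = rep(0:1, c(n0, n1)),
                     library_size = rep(1, n0 + n1))
  vars <- vapply(1:150, function(k) {
    x <- rexp(n0 + n1)                      # continuous: no ties
    I <- r_sign_matrix(x, rep(1, n0 + n1))
    fit <- fit_pim(build_pim_design(I, meta, marginal_only = TRUE))
    b <- fit$coefficients[["dA"]]
    p <- plogis(b)
    fit$vcov["dA", "dA"] * (p * (1 - p))^2  # back to the proportion scale
  }, numeric(1))
  expect_lt(abs(mean(vars) - analytic) / analytic, 0.10)
})

test_that("Wald p-values are two-sided normal tails", {
  cnt <- make_counts(rbind(c(1L, 2L, 3L, 2L, 4L, 5L), rep(1L, 6)))
  meta <- make_meta(cnt, group = rep(0:1, each = 3))
  rf <- user_reference_frame(cnt, "t02")
  I <- r_sign_matrix(cnt["t01", ], rf$r)
  fit <- fit_pim(build_pim_design(I, meta, marginal_only = TRUE))
  w <- pim_wald_test(fit)
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_equal(w$z, w$estimate / w$se)
})
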