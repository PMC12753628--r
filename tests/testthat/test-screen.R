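test_that("the species t-test is calibrated under the null", {
  # direct check of our vectorized implementation against stats::t.test
  spec <- small_spec(n_features = 6L, divergent_idx = integer(0),
                     informative_idx = integer(0),
                     low_icc_idx = integer(0), block_rho = 0)
  sim <- simulate_feature_tables(spec, seed = 42)
  tt <- species_ttest(sim$human, sim$monkey)
  h <- analysis_rows(sim$human)
  m <- analysis_rows(sim$monkey)
  for (f in tt$feature[1:3]) {
    ref <- t.test(h[[f]], m[[f]], var.equal = TRUE)
    row <- tt[tt$feature == f, ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, ref$p.value, tolerance = 1e-10)
  }
  # null features rejected at about the nominal 5% rate
  spec_null <- small_spec(n_features = 400L, n_human = 200L,
                          n_monkey = 100L, n_pos_human = 50L,
                          n_pos_monkey = 30L,
                          divergent_idx = integer(0),
                          informative_idx = integer(0),
                          low_icc_idx = integer(0), block_rho = 0)
  sim_null <- simulate_feature_tables(spec_null, seed = 43)
  tt_null <- species_ttest(sim_null$human, sim_null$monkey)
  expect_gt(mean(!tt_null$keep), 0.02)
  expect_lt(mean(!tt_null$keep), 0.09)
})

test_that("planted species shifts are excluded with near-certain power", {
  spec <- synthetic_spec(n_features = 50L, divergent_idx = 1:10,
                         delta_s = 1.5, informative_idx = integer(0),
                         low_icc_idx = integer(0))
  sim <- simulate_feature_tables(spec, seed = 44)
  tt <- species_ttest(sim$human, sim$monkey)
  expect_true(all(!tt$keep[sim$truth$divergent]))
})

test_that("degenerate and mismatched inputs are rejected", {
  spec <- small_spec(n_features = 4L, divergent_idx = integer(0),
                     informative_idx = integer(0),
                     low_icc_idx = integer(0))
  sim <- simulate_feature_tables(spec, seed = 45)
  h <- sim$human
  m <- sim$monkey
  f1 <- feature_columns(h)[1]
  h[[f1]] <- 3
  m[[f1]] <- 3
  tt <- species_ttest(h, m)
  expect_true(tt$degenerate[tt$feature == f1])
  expect_false(tt$keep[tt$feature == f1])
  m2 <- m
  names(m2)[names(m2) == feature_columns(m)[2]] <- "other_feature"
  expect_error(species_ttest(h, m2), "different feature columns")
})

test_that("the inverted LASSO zeros noise and keeps the separator out", {
  withr::with_seed(46, {
    n1 <- 300L; n2 <- 100L
    species <- rep(c("human", "monkey"), c(n1, n2))
    x <- cbind(sep = c(rnorm(n1, 0, 0.3), rnorm(n2, 4, 0.3)),
               matrix(rnorm((n1 + n2) * 50), n1 + n2, 50))
    colnames(x) <- c("sep", paste0("noise", 1:50))
  })
  res <- species_lasso_screen(x, species, seed = 47)
  expect_false(res$reproducible[["sep"]])
  expect_gte(mean(res$reproducible[-1]), 0.9)
  expect_false(res$degenerate_lambda)
  expect_error(species_lasso_screen(x[, 0, drop = FALSE], species),
               "empty")
  expect_error(species_lasso_screen(x, rep("human", nrow(x))),
               "two levels")
})

test_that("the composed screen is monotone and deterministic", {
  spec <- small_spec(n_human = 200L, n_monkey = 100L, n_pos_human = 50L,
                     n_pos_monkey = 30L)
  sim <- simulate_feature_tables(spec, seed = 48)
  res1 <- run_species_screen(sim$human, sim$monkey, seed = 49)
  res2 <- run_species_screen(sim$human, sim$monkey, seed = 49)
  expect_identical(res1$per_feature, res2$per_feature)

  per <- res1$per_feature
  # reproducible => survived the t-test; B is a subset of survivors
  expect_true(all(per$keep_ttest[per$reproducible]))
  expect_true(all(res1$feature_set_b %in% per$feature[per$keep_ttest]))
  expect_equal(unname(res1$counts["n_reproducible"]),
               length(res1$feature_set_b))
  # coefficient exactly zero defines reproducibility among survivors
  surv <- per[per$keep_ttest, ]
  expect_equal(surv$reproducible, surv$lasso_coef == 0)
})
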