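test_that("z-scoring fits, transports and inverts exactly", {
  withr::with_seed(51, {
    x <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
  })
  fit <- zscore_fit(x)
  z <- zscore_apply(fit, x)
  expect_equal(unname(colMeans(z)), rep(0, 4))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4))
  # a shifted copy lands at shift / sd
  z2 <- zscore_apply(fit, x + 6)
  expect_equal(unname(colMeans(z2)), unname(6 / fit$scale))
  expect_equal(zscore_invert(fit, z), x, tolerance = 1e-12)
  xc <- cbind(x, const = 7)
  expect_warning(fitc <- zscore_fit(xc), "zero-variance")
  expect_false("const" %in% fitc$features)
})

test_that("MI estimates separate dependence from independence", {
  withr::with_seed(52, {
    n <- 1000L
    y <- rep(0:1, each = n / 2)
    x <- cbind(independent = rnorm(n),
               informative = y + rnorm(n) * 0.02)
  })
  mi <- mutual_info_scores(x, y, seed = 53)
  expect_lt(mi[["independent"]], 0.05)
  # discrete plug-in oracle on the binarized informative feature:
  # perfect association of two balanced binaries has MI = ln 2
  xb <- as.integer(x[, "informative"] > 0.5)
  pj <- table(xb, y) / n
  px <- rowSums(pj); py <- colSums(pj)
  oracle <- sum(pj[pj > 0] * log(pj[pj > 0] /
                                   outer(px, py)[pj > 0]))
  expect_equal(oracle, log(2), tolerance = 1e-12)
  expect_gt(mi[["informative"]], 0.5)
  expect_lt(abs(mi[["informative"]] - oracle), 0.1)
})

test_that("MI is approximately invariant under monotone transforms", {
  withr::with_seed(54, {
    n <- 1500L
    y <- rbinom(n, 1, 0.4)
    x <- y * 0.8 + rnorm(n)
  })
  m1 <- mutual_info_scores(cbind(f = x), y, seed = 55)
  m2 <- mutual_info_scores(cbind(f = exp(x)), y, seed = 55)
  expect_lt(abs(m1 - m2), 0.02)
})

test_that("cross-validated LASSO keeps signal and rejects noise", {
  withr::with_seed(56, {
    n <- 575L
    y <- rbinom(n, 1, 139 / 575)
    x <- cbind(signal = y * 2 + rnorm(n),
               matrix(rnorm(n * 20), n, 20))
    colnames(x) <- c("signal", paste0("noise", 1:20))
    xs <- scale(x)
  })
  sel <- cv_lasso_select(xs, y, seed = 57)
  expect_true("signal" %in% sel$selected)
  expect_gt(sel$coefficients[["signal"]], 0)

  # shuffled labels: selection collapses in at least 80% of seeds
  hits <- 0L
  for (s in 1:20) {
    ys <- withr::with_seed(60 + s, sample(y))
    sel0 <- cv_lasso_select(xs, ys, seed = 70 + s)
    if (length(sel0$selected) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 16L)

  empty <- cv_lasso_select(xs[, 0, drop = FALSE], y)
  expect_length(empty$selected, 0)
})

test_that("reduction is a monotone filter with sign-faithful weights", {
  spec <- small_spec(n_human = 300L, n_pos_human = 75L,
                     divergent_idx = integer(0), informative_idx = 1:5,
                     delta_d = 2, low_icc_idx = integer(0))
  sim <- simulate_feature_tables(spec, seed = 58)
  feats <- feature_columns(sim$human)
  red <- reduce_features(sim$human, feats, seed = 59)
  expect_true(all(red$selected %in% red$mi_survivors))
  expect_true(all(red$mi_survivors %in% feats))
  informative <- sim$truth$feature_names[sim$truth$informative]
  expect_true(all(informative %in% red$selected))
  expect_true(all(red$coefficients[informative] > 0))
  # null features mostly fail the MI gate
  null_feats <- setdiff(feats, informative)
  expect_gt(mean(red$mi[null_feats] <= 0.1), 0.9)

  empty <- reduce_features(sim$human, character(0))
  expect_length(empty$selected, 0)
  expect_error(reduce_features(sim$human, "no_such_feature"),
               "not in table")
})
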