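test_that("confusion metric identities hold on random matrices", {
  withr::with_seed(71, {
    for (i in 1:50) {
      tp <- sample(0:50, 1); fp <- sample(0:50, 1)
      tn <- sample(0:50, 1); fn <- sample(0:50, 1)
      if (tp + fn == 0 || tn + fp == 0) next
      m <- confusion_metrics(tp, fp, tn, fn)
      expect_equal(unname(m["accuracy"]),
                   (tp + tn) / (tp + fp + tn + fn))
      if (2 * tp + fp + fn > 0)
        expect_equal(unname(m["f1"]), 2 * tp / (2 * tp + fp + fn))
      expect_equal(unname(m["sensitivity"]), tp / (tp + fn))
      expect_equal(unname(m["specificity"]), tn / (tn + fp))
    }
  })
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  withr::with_seed(72, {
    for (i in 1:20) {
      n <- sample(20:100, 1)
      scores <- sample(1:12, n, replace = TRUE)  # heavy ties
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) == 0 || sum(labels) == n) next
      r <- rank(scores)
      n1 <- sum(labels == 1); n0 <- sum(labels == 0)
      mw <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
      expect_equal(auc_trapezoid(scores, labels), mw,
                   tolerance = 1e-12)
      # ROC symmetry under score negation
      expect_equal(auc_trapezoid(-scores, labels), 1 - mw,
                   tolerance = 1e-12)
    }
  })
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(auc_trapezoid(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(perfect$tpr[length(perfect$tpr)], 1)
})

test_that("published-table confusion arithmetic is self-consistent", {
  r <- reconstruct_confusion(1.0, 1.0, 45, 100)
  expect_equal(unname(r$counts), c(45, 0, 100, 0))
  expect_equal(unname(r$metrics["accuracy"]), 1)
  r2 <- reconstruct_confusion(0.022, 1.000, 45, 100)
  expect_equal(unname(r2$counts[c("tp", "fp")]), c(1, 0))
  expect_equal(unname(r2$metrics["f1"]), 2 / 46)
  expect_error(reconstruct_confusion(1.2, 0.5, 10, 10), "\\[0, 1\\]")
})

test_that("all five models fit separable data and predict reproducibly", {
  withr::with_seed(73, {
    n <- 120L
    y <- rep(0:1, each = n / 2)
    x <- cbind(a = y * 4 + rnorm(n, sd = 0.3),
               b = -2 * y + rnorm(n, sd = 0.3))
  })
  bundle <- train_models(x, y, seed = 74)
  expect_named(bundle$models,
               c("svm", "decision_tree", "random_forest",
                 "logistic_regression", "naive_bayes"))
  scores <- score_models(bundle, x)
  for (mod in colnames(scores))
    expect_equal(mean((scores[, mod] >= 0.5) == (y == 1)), 1,
                 info = mod)
  # same seed, same predictions
  bundle2 <- train_models(x, y, seed = 74)
  expect_equal(score_models(bundle2, x), scores)
  expect_error(train_models(x, rep(0L, n)), "single class")
  expect_error(score_models(bundle, x[, 1, drop = FALSE]), "missing")
})

test_that("label-shuffled training gives chance-level test AUC", {
  withr::with_seed(75, {
    xtr <- matrix(rnorm(200 * 5), 200, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
    ytr <- sample(rep(0:1, each = 100))
    xte <- matrix(rnorm(400 * 5), 400, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
    yte <- rbinom(400, 1, 0.5)
  })
  bundle <- train_models(xtr, ytr, seed = 76)
  ev <- evaluate_models(bundle, xte, yte)
  expect_true(all(ev$metrics$auc > 0.4 & ev$metrics$auc < 0.6))
  # confusion identities on the report
  expect_true(all(ev$metrics$tp + ev$metrics$fn == ev$n_pos))
  expect_true(all(ev$metrics$tn + ev$metrics$fp == ev$n_neg))
})

test_that("the comparison report carries both lineages consistently", {
  withr::with_seed(77, {
    y <- rep(0:1, each = 40)
    x <- cbind(a = y * 3 + rnorm(80), b = rnorm(80))
    xte <- cbind(a = rbinom(60, 1, 0.5) * 3 + rnorm(60), b = rnorm(60))
  })
  yte <- as.integer(xte[, "a"] > 1.5)
  if (sum(yte) == 0 || sum(yte) == 60) yte[1:5] <- 1L
  bundle <- train_models(x, y, seed = 78)
  ev <- evaluate_models(bundle, xte, yte)
  rep2 <- build_report(ev, ev)
  expect_equal(nrow(rep2), 10L)  # 5 models x 2 feature sets
  halves <- split(rep2, rep2$feature_set)
  expect_equal(halves$A2$f1, halves$B2$f1)
  # emitted metrics recompute from emitted confusion counts
  for (i in seq_len(nrow(rep2))) {
    m <- confusion_metrics(rep2$tp[i], rep2$fp[i], rep2$tn[i],
                           rep2$fn[i])
    expect_equal(rep2$accuracy[i], round(unname(m["accuracy"]), 3))
    expect_equal(rep2$sensitivity[i], round(unname(m["sensitivity"]), 3))
  }
})

test_that("trapezoidal AUC agrees with an established ROC package", {
  skip_if_not_installed("pROC")
  withr::with_seed(79, {
    scores <- rnorm(150)
    labels <- rbinom(150, 1, 0.35)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        levels = c(0, 1),
                                        direction = "<")))
  expect_equal(auc_trapezoid(scores, labels), ref, tolerance = 1e-12)
})
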