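# Cross-species model training and evaluation.
#
# Five classifiers with their library-default hyperparameters are trained
# on the balanced human training set and evaluated on the monkey test
# set. The positive class is the degenerated disc (label 1); confusion
# metrics use a 0.5 probability threshold and the ROC is swept over all
# score thresholds with trapezoidal AUC.

.MODEL_NAMES <- c("svm", "decision_tree", "random_forest",
                  "logistic_regression", "naive_bayes")

#' Train the five classifiers
#'
#' SVM (RBF kernel, probability model enabled), decision tree, random
#' forest (500 trees), logistic regression and Gaussian naive Bayes, all
#' at library defaults, trained on identical rows and columns.
#' Deterministic given the seed.
#'
#' @param x numeric training matrix with named columns.
#' @param y binary label (0/1).
#' @param seed training seed (SVM probability calibration and random
#'   forest bootstrap draw from it).
#' @return A list of class `"model_bundle"`: `models` (named list),
#'   `features`, `seed`.
#' @export
train_models <- function(x, y, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  yf <- factor(y, levels = c(0L, 1L))
  if (any(table(yf) == 0)) stop("training data has a single class")
  df <- data.frame(x, check.names = FALSE)
  df_glm <- data.frame(x)  # syntactic names for the formula interface
  colnames(df_glm) <- make.names(colnames(x))
  df_glm$.label <- yf
  models <- withr::with_seed(as.integer(seed), list(
    svm = e1071::svm(x, yf, probability = TRUE),
    decision_tree = rpart::rpart(
      .label ~ ., data = df_glm, method = "class"),
    random_forest = randomForest::randomForest(x, yf),
    logistic_regression = suppressWarnings(
      stats::glm(.label ~ ., data = df_glm, family = stats::binomial())),
    naive_bayes = e1071::naiveBayes(x, yf)))
  structure(list(models = models, features = colnames(x),
                 seed = as.integer(seed)),
            class = "model_bundle")
}

#' Predicted probabilities of degeneration for each model
#'
#' @param bundle a [train_models()] result.
#' @param x numeric matrix with the bundle's feature columns.
#' @return Numeric matrix, one column per model, of class-1
#'   probabilities.
#' @export
score_models <- function(bundle, x) {
  stopifnot(inherits(bundle, "model_bundle"))
  missing <- setdiff(bundle$features, colnames(x))
  if (length(missing) > 0)
    stop("test columns missing: ", paste(missing, collapse = ", "))
  x <- x[, bundle$features, drop = FALSE]
  df_glm <- data.frame(x)
  colnames(df_glm) <- make.names(colnames(x))
  m <- bundle$models
  p_svm <- attr(stats::predict(m$svm, x, probability = TRUE),
                "probabilities")[, "1"]
  p_tree <- stats::predict(m$decision_tree, newdata = df_glm,
                           type = "prob")[, "1"]
  p_rf <- stats::predict(m$random_forest, x, type = "prob")[, "1"]
  p_glm <- stats::predict(m$logistic_regression, newdata = df_glm,
                          type = "response")
  p_nb <- stats::predict(m$naive_bayes, newdata = x, type = "raw")[, "1"]
  out <- cbind(svm = p_svm, decision_tree = p_tree, random_forest = p_rf,
               logistic_regression = p_glm, naive_bayes = p_nb)
  rownames(out) <- NULL
  out
}

#' ROC curve by threshold sweep
#'
#' Scores are swept from high to low (ties grouped), giving one
#' (FPR, TPR) point per distinct score plus the (0,0) and (1,1)
#' endpoints.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("need both classes to sweep a ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each distinct score (ties collapsed)
  idx <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l == 1L)[idx]
  fp <- cumsum(l == 0L)[idx]
  data.frame(threshold = c(Inf, s[idx]),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Equivalent to the normalized Mann-Whitney U statistic with ties
#' counted half.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1L) +
                        utils::tail(rc$tpr, -1L)) / 2)
}

#' Confusion counts and threshold metrics
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return Named numeric vector: sensitivity, specificity, precision,
#'   f1, accuracy (full precision; round only at report time).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
         else NA_real_,
    accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Evaluate a model bundle on a test set
#'
#' @param bundle a [train_models()] result.
#' @param x_test numeric test matrix.
#' @param y_test binary test labels.
#' @param threshold probability threshold for the confusion matrix.
#' @return A list of class `"eval_report"`: `metrics` (data frame with
#'   one row per model: confusion counts, sensitivity, specificity,
#'   precision, f1, accuracy, auc), `roc` (named list of ROC point data
#'   frames), `scores`, `n_pos`, `n_neg`, `threshold`.
#' @export
evaluate_models <- function(bundle, x_test, y_test, threshold = 0.5) {
  if (length(y_test) == 0) stop("empty test set")
  scores <- score_models(bundle, x_test)
  y <- as.integer(y_test)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  rows <- lapply(colnames(scores), function(mod) {
    sc <- scores[, mod]
    pred <- as.integer(sc >= threshold)
    tp <- sum(pred == 1L & y == 1L)
    fp <- sum(pred == 1L & y == 0L)
    tn <- sum(pred == 0L & y == 0L)
    fn <- sum(pred == 0L & y == 1L)
    met <- confusion_metrics(tp, fp, tn, fn)
    data.frame(model = mod, tp = tp, fp = fp, tn = tn, fn = fn,
               t(met), auc = auc_trapezoid(sc, y),
               stringsAsFactors = FALSE)
  })
  roc <- lapply(stats::setNames(colnames(scores), colnames(scores)),
                function(mod) roc_curve(scores[, mod], y))
  structure(list(metrics = do.call(rbind, rows), roc = roc,
                 scores = scores, n_pos = n_pos, n_neg = n_neg,
                 threshold = threshold),
            class = "eval_report")
}

#' Reconstruct a confusion matrix from printed rates
#'
#' Given reported sensitivity and specificity and the test-class sizes,
#' recovers the integer confusion counts (`tp = round(sens * n_pos)`,
#' `tn = round(spec * n_neg)`) and the metrics they imply. Useful for
#' checking the arithmetic of published performance tables.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_pos,n_neg test-set class sizes.
#' @return A list: `counts` (tp, fp, tn, fn) and `metrics`
#'   ([confusion_metrics()] output).
#' @export
#' @examples
#' reconstruct_confusion(0.822, 0.949, 45, 100)$metrics["accuracy"]
reconstruct_confusion <- function(sensitivity, specificity, n_pos,
                                  n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 ||
      specificity > 1)
    stop("rates must lie in [0, 1]")
  stopifnot(n_pos > 0, n_neg > 0)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  fn <- n_pos - tp
  fp <- n_neg - tn
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       metrics = confusion_metrics(tp, fp, tn, fn))
}

#' Combine two lineage evaluations into a comparison report
#'
#' @param report_a2,report_b2 [evaluate_models()] results for the models
#'   trained on feature sets A2 and B2.
#' @param digits rounding applied to the report (default 3); internal
#'   values keep full precision.
#' @return Data frame: one row per model x feature set with F1,
#'   accuracy, precision, sensitivity, specificity, AUC and class
#'   counts.
#' @export
build_report <- function(report_a2, report_b2, digits = 3L) {
  one <- function(rep, set) {
    m <- rep$metrics
    data.frame(model = m$model, feature_set = set,
               f1 = round(m$f1, digits),
               accuracy = round(m$accuracy, digits),
               precision = round(m$precision, digits),
               sensitivity = round(m$sensitivity, digits),
               specificity = round(m$specificity, digits),
               auc = round(m$auc, digits),
               n_pos = rep$n_pos, n_neg = rep$n_neg,
               tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(report_a2, "A2"), one(report_b2, "B2"))
  out <- out[order(out$model, out$feature_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
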