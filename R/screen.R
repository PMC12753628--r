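# Interspecies reproducibility screen.
#
# Two stages: (1) a per-feature independent-samples t-test between the
# human and monkey cohorts; features with p < alpha show a significant
# species difference and are excluded. (2) an "inverted" LASSO: an
# L1-penalized species classifier over the t-test survivors; features
# whose coefficient the solver shrinks exactly to zero contribute little
# to telling the species apart and are declared reproducible across
# species (feature set B).

#' Per-feature independent-samples t-test between species
#'
#' Pooled-variance Student's t by default (`var_equal = FALSE` gives
#' Welch). Features with zero variance in both cohorts are flagged
#' degenerate and not kept: with no variance there is no evidence of
#' reproducibility.
#'
#' @param human,monkey feature tables sharing a feature column set; if
#'   replicate metadata is present only the analysis rows are used.
#' @param alpha significance level; `keep` is `p >= alpha`.
#' @param var_equal pool variances (Student) or not (Welch).
#' @return Data frame with columns `feature`, `statistic`, `p_value`,
#'   `degenerate`, `keep`.
#' @export
species_ttest <- function(human, monkey, alpha = 0.05, var_equal = TRUE) {
  feats <- feature_columns(human)
  if (!identical(sort(feats), sort(feature_columns(monkey))))
    stop("human and monkey tables have different feature columns")
  if (length(feats) == 0) stop("empty feature table")
  x1 <- feature_matrix(analysis_rows(human), feats)
  x2 <- feature_matrix(analysis_rows(monkey), feats)
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 rows per species")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2L, m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(feats))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degenerate <- v1 == 0 & v2 == 0
  tstat <- ifelse(se > 0, (m1 - m2) / se, ifelse(m1 == m2, 0, Inf))
  p <- ifelse(degenerate, NA_real_, 2 * stats::pt(-abs(tstat), df))
  data.frame(feature = feats, statistic = tstat, p_value = p,
             degenerate = degenerate,
             keep = !degenerate & !is.na(p) & p >= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Inverted species LASSO screen
#'
#' L1-penalized logistic regression of the species label on the t-test
#' survivors, standardized over the combined cohorts. The penalty weight
#' is chosen by stratified k-fold cross-validated deviance; features with
#' a coefficient of exactly zero at the chosen lambda are the
#' species-reproducible set.
#'
#' @param x numeric matrix (rows = discs of both species, columns =
#'   surviving features).
#' @param species factor or character with two levels
#'   (human / monkey).
#' @param nfolds number of cross-validation folds.
#' @param seed fold-assignment seed.
#' @param lambda_rule `"min"` (minimum mean deviance) or `"1se"`.
#' @return A list: per-feature `coefficients`, logical `reproducible`
#'   (coefficient exactly zero), `lambda`, `lambda_rule`, `nonzero`
#'   count, `degenerate_lambda` flag (all coefficients shrunk to zero),
#'   and the cross-validation curve (`lambda_grid`, `cvm`).
#' @export
species_lasso_screen <- function(x, species, nfolds = 5L, seed = 1L,
                                 lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(dim(x)) || ncol(x) == 0) stop("empty survivor set")
  y <- factor(species)
  if (nlevels(y) != 2) stop("species label must have exactly two levels")
  if (min(table(y)) < 2) stop("need at least 2 rows per species")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  foldid <- stratified_folds(y, nfolds, seed)
  cv <- glmnet::cv.glmnet(xs, y, family = "binomial", foldid = foldid,
                          standardize = FALSE)
  lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = lambda))[-1L]
  names(beta) <- colnames(x)
  reproducible <- beta == 0
  list(coefficients = beta, reproducible = reproducible,
       lambda = lambda, lambda_rule = lambda_rule,
       nonzero = sum(beta != 0),
       degenerate_lambda = all(beta == 0),
       lambda_grid = cv$lambda, cvm = cv$cvm, seed = as.integer(seed))
}

#' Run the full two-stage species screen
#'
#' Composes [species_ttest()] and [species_lasso_screen()]: feature set B
#' is the set of t-test survivors whose species-LASSO coefficient is
#' exactly zero. Deterministic given the seed.
#'
#' @inheritParams species_ttest
#' @inheritParams species_lasso_screen
#' @return A list of class `"screen_result"`: `per_feature` data frame
#'   (`feature`, `statistic`, `p_value`, `keep_ttest`, `lasso_coef`,
#'   `reproducible`), `feature_set_b`, `lambda`, `counts`
#'   (`n_features`, `n_after_ttest`, `n_reproducible`), `alpha`, `seed`.
#' @export
run_species_screen <- function(human, monkey, alpha = 0.05, nfolds = 5L,
                               seed = 1L, var_equal = TRUE,
                               lambda_rule = "min") {
  tt <- species_ttest(human, monkey, alpha = alpha, var_equal = var_equal)
  survivors <- tt$feature[tt$keep]
  per <- data.frame(feature = tt$feature, statistic = tt$statistic,
                    p_value = tt$p_value, keep_ttest = tt$keep,
                    lasso_coef = NA_real_, reproducible = FALSE,
                    stringsAsFactors = FALSE)
  lasso <- NULL
  if (length(survivors) > 0) {
    xh <- feature_matrix(analysis_rows(human), survivors)
    xm <- feature_matrix(analysis_rows(monkey), survivors)
    x <- rbind(xh, xm)
    species <- rep(c("human", "monkey"), c(nrow(xh), nrow(xm)))
    lasso <- species_lasso_screen(x, species, nfolds = nfolds,
                                  seed = seed, lambda_rule = lambda_rule)
    idx <- match(survivors, per$feature)
    per$lasso_coef[idx] <- lasso$coefficients
    per$reproducible[idx] <- lasso$reproducible
  }
  structure(list(
    per_feature = per,
    feature_set_b = per$feature[per$reproducible],
    lambda = if (is.null(lasso)) NA_real_ else lasso$lambda,
    lasso = lasso, alpha = alpha, seed = as.integer(seed),
    counts = c(n_features = nrow(per),
               n_after_ttest = length(survivors),
               n_reproducible = sum(per$reproducible))),
    class = "screen_result")
}
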