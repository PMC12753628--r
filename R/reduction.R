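# Dimensionality reduction: z-scoring, mutual-information filtering and
# cross-validated LASSO retention.
#
# Mutual information between each continuous feature and the binary
# degeneration label is estimated with the nearest-neighbour estimator
# for continuous-discrete pairs (Ross 2014), the convention behind the
# usual feature-selection tooling: values are in nats and the filter
# threshold (default 0.1 nats) is applied as printed. MI is computed on
# the human training rows only; using the monkey test rows would leak.

#' Fit / apply / invert a z-score standardization
#'
#' `zscore_fit` learns per-feature means and standard deviations on the
#' fitting rows; `zscore_apply` standardizes any matrix with the same
#' columns; `zscore_invert` undoes it. Zero-variance features are dropped
#' at fit time with a warning.
#'
#' @param x numeric matrix with named columns.
#' @param fit a `"zscore_fit"` object.
#' @param z standardized matrix.
#' @return `zscore_fit`: an object with `center`, `scale`, `features`;
#'   `zscore_apply` / `zscore_invert`: transformed matrices.
#' @export
zscore_fit <- function(x) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop("all features are constant on the fitting rows")
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped: ",
            paste(utils::head(colnames(x)[!keep], 5L), collapse = ", "))
  structure(list(center = ctr[keep], scale = scl[keep],
                 features = colnames(x)[keep]),
            class = "zscore_fit")
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(fit, x) {
  stopifnot(inherits(fit, "zscore_fit"))
  missing <- setdiff(fit$features, colnames(x))
  if (length(missing) > 0)
    stop("columns missing from input: ", paste(missing, collapse = ", "))
  x <- x[, fit$features, drop = FALSE]
  sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(fit, z) {
  stopifnot(inherits(fit, "zscore_fit"))
  z <- z[, fit$features, drop = FALSE]
  sweep(sweep(z, 2L, fit$scale, "*"), 2L, fit$center, "+")
}

# Nearest-neighbour MI estimate for one continuous feature x and a
# discrete label y (Ross 2014):
#   I = psi(N) - <psi(N_c)> + <psi(k_c)> - <psi(m_i)>
# where, for sample i of class c, the radius is the distance to its k-th
# nearest neighbour within class c and m_i counts all samples strictly
# inside that radius (the sample itself included). Classes with a single
# member are excluded. A tiny seeded jitter breaks ties.
.mi_cd_one <- function(x, y, k) {
  cls <- split(seq_along(x), y)
  cls <- cls[vapply(cls, length, 1L) > 1L]
  if (length(cls) < 2) return(0)
  idx <- unlist(cls, use.names = FALSE)
  n <- length(idx)
  xs_all <- sort(x[idx])
  psi_m <- numeric(0)
  psi_k <- numeric(0)
  psi_nc <- numeric(0)
  for (members in cls) {
    xv <- x[members]
    nc <- length(xv)
    kc <- min(k, nc - 1L)
    ord <- order(xv)
    xs <- xv[ord]
    # k-th nearest neighbour distance in 1D via the sorted window
    d <- vapply(seq_len(nc), function(i) {
      lo <- max(1L, i - kc)
      hi <- min(nc, i + kc)
      nb <- abs(xs[lo:hi] - xs[i])
      sort(nb[-(i - lo + 1L)], partial = kc)[kc]
    }, 0)
    # shrink the radius just below the k-th neighbour distance, then
    # count all samples in [x - r, x + r] (the sample itself included)
    r <- d * (1 - 1e-12)
    m <- findInterval(xs + r, xs_all) -
      findInterval(xs - r, xs_all, left.open = TRUE)
    psi_m <- c(psi_m, digamma(pmax(m, 1)))
    psi_k <- c(psi_k, rep(digamma(kc), nc))
    psi_nc <- c(psi_nc, rep(digamma(nc), nc))
  }
  digamma(n) - mean(psi_nc) + mean(psi_k) - mean(psi_m)
}

#' Mutual information between features and a binary label
#'
#' kNN estimator for continuous features against a discrete label;
#' estimates are in nats and clamped at zero. A tiny seeded jitter
#' (1e-10 of the feature scale) breaks ties, as is conventional for this
#' estimator.
#'
#' @param x numeric matrix (rows = samples, named columns = features).
#' @param y discrete label vector with at least 2 classes present.
#' @param k neighbour count (default 3).
#' @param seed jitter seed.
#' @return Named numeric vector of MI estimates (nats).
#' @export
mutual_info_scores <- function(x, y, k = 3L, seed = 1L) {
  stopifnot(is.matrix(x))
  if (length(unique(y)) < 2) stop("label has a single class")
  if (nrow(x) != length(y)) stop("row/label length mismatch")
  p <- ncol(x)
  if (p == 0) return(stats::setNames(numeric(0), character(0)))
  jitter <- withr::with_seed(as.integer(seed),
                             matrix(stats::rnorm(length(x)), nrow(x), p))
  out <- vapply(seq_len(p), function(j) {
    scale <- max(1, stats::sd(x[, j]))
    .mi_cd_one(x[, j] + 1e-10 * scale * jitter[, j], y, k)
  }, 0)
  stats::setNames(pmax(out, 0), colnames(x))
}

#' Cross-validated LASSO feature retention
#'
#' L1-penalized logistic regression of the label on standardized
#' features over the solver's lambda path; lambda is chosen by stratified
#' k-fold cross-validated deviance and the features with nonzero
#' coefficients at that lambda are retained, with their coefficients as
#' weights.
#'
#' @param x standardized numeric matrix with named columns.
#' @param y binary label (0/1).
#' @param nfolds folds for cross-validation.
#' @param seed fold-assignment seed.
#' @param lambda_rule `"min"` or `"1se"`.
#' @return A list: `selected` (character), `coefficients` (named, nonzero
#'   entries only), `intercept`, `lambda`, `lambda_grid`, `cvm`,
#'   `lambda_rule`. An empty input yields an explicit empty selection.
#' @export
cv_lasso_select <- function(x, y, nfolds = 5L, seed = 1L,
                            lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(dim(x)) || ncol(x) == 0)
    return(list(selected = character(0), coefficients = numeric(0),
                intercept = NA_real_, lambda = NA_real_,
                lambda_grid = numeric(0), cvm = numeric(0),
                lambda_rule = lambda_rule))
  if (length(unique(y)) < 2) stop("label has a single class")
  foldid <- stratified_folds(y, nfolds, seed)
  if (ncol(x) == 1L) {
    # the solver needs >= 2 columns; duplicate and keep the first
    cv <- glmnet::cv.glmnet(cbind(x, x), y, family = "binomial",
                            foldid = foldid, standardize = FALSE)
    b <- as.numeric(stats::coef(cv, s = cv[[paste0("lambda.",
                                                   lambda_rule)]]))
    beta <- stats::setNames(b[2L] + b[3L], colnames(x))
    lam <- cv[[paste0("lambda.", lambda_rule)]]
    sel <- names(beta)[beta != 0]
    return(list(selected = sel, coefficients = beta[beta != 0],
                intercept = b[1L], lambda = lam,
                lambda_grid = cv$lambda, cvm = cv$cvm,
                lambda_rule = lambda_rule))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          standardize = FALSE)
  lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  b <- as.numeric(stats::coef(cv, s = lambda))
  beta <- stats::setNames(b[-1L], colnames(x))
  nz <- beta[beta != 0]
  list(selected = names(nz), coefficients = nz, intercept = b[1L],
       lambda = lambda, lambda_grid = cv$lambda, cvm = cv$cvm,
       lambda_rule = lambda_rule)
}

#' Reduce a feature set on the human training rows
#'
#' Standardizes the candidate features (fit on the human analysis rows),
#' drops features with label MI at or below the threshold, then retains
#' the nonzero-coefficient features of a cross-validated LASSO. Applied
#' to feature set A1 this yields A2, to B1 it yields B2.
#'
#' @param train a human feature table (training cohort); analysis rows
#'   are used.
#' @param feature_set candidate features, a subset of the table columns.
#' @param mi_threshold MI retention threshold in nats (default 0.1).
#' @param mi_k MI estimator neighbour count.
#' @param nfolds LASSO cross-validation folds.
#' @param seed seed for the MI jitter and fold assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @return A list of class `"reduction_result"`: `mi` (named vector),
#'   `mi_survivors`, `selected`, `coefficients`, `lambda`, `cv`
#'   (lambda grid and mean deviance), `zscore` (the fitted
#'   standardization), `seed`.
#' @export
reduce_features <- function(train, feature_set,
                            mi_threshold = 0.1, mi_k = 3L,
                            nfolds = 5L, seed = 1L,
                            lambda_rule = "min") {
  if (length(feature_set) == 0)
    return(structure(list(mi = numeric(0), mi_survivors = character(0),
                          selected = character(0),
                          coefficients = numeric(0), lambda = NA_real_,
                          cv = list(lambda_grid = numeric(0),
                                    cvm = numeric(0)),
                          zscore = NULL, seed = as.integer(seed)),
                     class = "reduction_result"))
  missing <- setdiff(feature_set, feature_columns(train))
  if (length(missing) > 0)
    stop("feature set not in table: ", paste(missing, collapse = ", "))
  rows <- analysis_rows(train)
  y <- rows$meta_binary_label
  x <- feature_matrix(rows, feature_set)
  fit <- zscore_fit(x)
  z <- zscore_apply(fit, x)
  mi <- mutual_info_scores(z, y, k = mi_k, seed = seed)
  survivors <- names(mi)[mi > mi_threshold]
  lasso <- cv_lasso_select(z[, survivors, drop = FALSE], y,
                           nfolds = nfolds, seed = offset_seed(seed, 1L),
                           lambda_rule = lambda_rule)
  structure(list(mi = mi, mi_survivors = survivors,
                 selected = lasso$selected,
                 coefficients = lasso$coefficients,
                 intercept = lasso$intercept, lambda = lasso$lambda,
                 cv = list(lambda_grid = lasso$lambda_grid,
                           cvm = lasso$cvm),
                 zscore = fit, seed = as.integer(seed)),
            class = "reduction_result")
}
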