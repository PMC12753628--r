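# SMOTE class balancing.
#
# Synthetic minority oversampling: each synthetic sample is an
# interpolation x_i + u (x_nn - x_i) between a minority sample and one of
# its k nearest minority neighbours (Euclidean metric on standardized
# features), with u ~ Uniform(0, 1). Applied to the training split only,
# after standardization and dimensionality reduction, to a 1:1 ratio.

#' Generate SMOTE synthetic minority samples
#'
#' @param minority numeric matrix of minority-class rows.
#' @param majority_count size of the majority class; `majority_count -
#'   nrow(minority)` synthetic rows are generated.
#' @param k number of nearest minority neighbours (default 5). The
#'   minority class must have more than `k` members.
#' @param seed sampling seed; identical seeds give identical rows.
#' @return Matrix of synthetic rows (possibly 0-row).
#' @export
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' nrow(smote(x, 50, seed = 1))  # 30
smote <- function(minority, majority_count, k = 5L, seed = 1L) {
  minority <- as.matrix(minority)
  n_min <- nrow(minority)
  if (!all(is.finite(minority))) stop("minority matrix must be numeric")
  n_syn <- majority_count - n_min
  if (n_syn < 0)
    stop("minority class already exceeds the majority count")
  if (n_syn == 0)
    return(minority[0, , drop = FALSE])
  if (n_min <= k)
    stop("SMOTE needs more than k = ", k, " minority samples, got ",
         n_min)
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  withr::with_seed(as.integer(seed), {
    base <- sample.int(n_min, n_syn, replace = TRUE)
    pick <- sample.int(k, n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
  })
  nb <- nn[cbind(base, pick)]
  syn <- minority[base, , drop = FALSE] +
    u * (minority[nb, , drop = FALSE] - minority[base, , drop = FALSE])
  rownames(syn) <- NULL
  syn
}

#' Balance a training set to a 1:1 class ratio
#'
#' Oversamples the minority class with [smote()] until both classes have
#' equal counts. Only ever applied to training rows; the interface never
#' sees the test split.
#'
#' @param x numeric matrix of training features.
#' @param y binary label vector (0/1) aligned with `x`.
#' @param k SMOTE neighbour count.
#' @param seed SMOTE seed.
#' @return A list of class `"balanced_training_set"`: `x`, `y` (original
#'   rows first, then synthetic), logical `synthetic` flag, `k`, `seed`.
#' @export
balance_training <- function(x, y, k = 5L, seed = 1L) {
  stopifnot(nrow(x) == length(y))
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (counts[1L] == counts[2L]) {
    return(structure(list(x = x, y = y,
                          synthetic = rep(FALSE, length(y)),
                          k = as.integer(k), seed = as.integer(seed)),
                     class = "balanced_training_set"))
  }
  minority_class <- as.integer(names(counts)[which.min(counts)])
  syn <- smote(x[y == minority_class, , drop = FALSE],
               max(counts), k = k, seed = seed)
  structure(list(x = rbind(x, syn),
                 y = c(y, rep(minority_class, nrow(syn))),
                 synthetic = c(rep(FALSE, length(y)),
                               rep(TRUE, nrow(syn))),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "balanced_training_set")
}
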