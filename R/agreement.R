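# Segmentation-agreement filtering.
#
# Each feature's stability under re-segmentation is measured by the
# single-measure intraclass correlation under a two-way random-effects
# model with absolute agreement, ICC(2,1): discs are subjects, the
# segmentation passes are raters. Absolute agreement penalizes a
# systematic rater offset, which a consistency-type ICC would forgive.

#' Single-measure two-way random-effects ICC with absolute agreement
#'
#' Computed from the two-way ANOVA mean squares of an n-subject x k-rater
#' matrix:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#' with `MSR`, `MSC`, `MSE` the subject, rater and residual mean squares.
#' Negative values are possible and returned as-is. A matrix with zero
#' total variance has no defined ICC and returns `NA` (treated as a
#' failure by [icc_filter()], never propagated as NaN arithmetic).
#'
#' @param m numeric matrix, subjects in rows (>= 2), raters in columns
#'   (>= 2), no missing cells.
#' @return The ICC value, or `NA` for a zero-variance matrix.
#' @export
#' @examples
#' icc_2way_absolute(cbind(1:8, 1:8))        # 1: identical raters
#' icc_2way_absolute(cbind(1:8, 1:8 + 2))    # < 1: systematic offset
icc_2way_absolute <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(m)) stop("rating matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (stats::var(as.vector(m)) == 0) return(NA_real_)
  grand <- mean(m)
  rmean <- rowMeans(m)
  cmean <- colMeans(m)
  msr <- k * sum((rmean - grand)^2) / (n - 1)
  msc <- n * sum((cmean - grand)^2) / (k - 1)
  resid <- m - outer(rmean, rep(1, k)) - outer(rep(1, n), cmean) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Vectorized ICC(2,1) for the two-rater case across many features:
# A and B are n x p matrices of the two raters' values.
.icc2_pairs <- function(A, B) {
  n <- nrow(A)
  R <- (A + B) / 2
  ca <- colMeans(A)
  cb <- colMeans(B)
  grand <- (ca + cb) / 2
  msr <- 2 * colSums(sweep(R, 2L, grand)^2) / (n - 1)
  msc <- n * ((ca - grand)^2 + (cb - grand)^2)
  resid <- sweep((A - B) / 2, 2L, (ca - cb) / 2)
  mse <- 2 * colSums(resid^2) / (n - 1)
  denom <- msr + mse + 2 * (msc - mse) / n
  total_var <- apply(rbind(A, B), 2L, stats::var)
  out <- (msr - mse) / denom
  out[total_var == 0] <- NA_real_
  out
}

#' Filter features by intra- and interobserver ICC in both species
#'
#' For each feature and species, the intraobserver ICC compares observer
#' 1's two segmentation passes and the interobserver ICC compares
#' observer 1's second pass (the analysis pass) with observer 2's. A
#' feature passes only if all four ICCs (intra, inter) x (human, monkey)
#' exceed the threshold; undefined (`NA`) ICCs fail. Applied to feature
#' set A this yields A1, to feature set B it yields B1.
#'
#' @param human,monkey feature tables with replicate rows (observer 1
#'   passes 1 and 2, observer 2 pass 1).
#' @param features features to assess (default: all feature columns).
#' @param threshold pass threshold (default 0.75).
#' @param pooled compute ICC on the pooled species rows instead of per
#'   species (off by default).
#' @return A list of class `"icc_result"`: `table` (long data frame:
#'   `feature`, `species`, `intra_icc`, `inter_icc`), `pass` (named
#'   logical), `survivors`, `threshold`.
#' @export
icc_filter <- function(human, monkey, features = NULL, threshold = 0.75,
                       pooled = FALSE) {
  if (is.null(features)) features <- feature_columns(human)
  if (length(features) == 0)
    return(structure(list(table = data.frame(), pass = logical(0),
                          survivors = character(0), threshold = threshold),
                     class = "icc_result"))
  pass_mats <- function(tab) {
    need <- c("meta_disc_id", "meta_observer_id", "meta_replicate_id")
    if (!all(need %in% names(tab)))
      stop("replicate metadata (disc/observer/replicate ids) is required")
    pick <- function(obs, rep) {
      rows <- tab[tab$meta_observer_id == obs &
                    tab$meta_replicate_id == rep, , drop = FALSE]
      rows <- rows[order(rows$meta_disc_id), , drop = FALSE]
      feature_matrix(rows, features)
    }
    o1r1 <- pick(1L, 1L); o1r2 <- pick(1L, 2L); o2r1 <- pick(2L, 1L)
    if (nrow(o1r1) != nrow(o1r2) || nrow(o1r2) != nrow(o2r1))
      stop("incomplete replicate structure")
    list(o1r1 = o1r1, o1r2 = o1r2, o2r1 = o2r1)
  }
  species_tabs <- if (pooled)
    list(pooled = rbind(human, monkey))
  else list(human = human, monkey = monkey)

  table_rows <- lapply(names(species_tabs), function(sp) {
    m <- pass_mats(species_tabs[[sp]])
    data.frame(feature = features, species = sp,
               intra_icc = .icc2_pairs(m$o1r1, m$o1r2),
               inter_icc = .icc2_pairs(m$o1r2, m$o2r1),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, table_rows)
  ok <- !is.na(long$intra_icc) & long$intra_icc > threshold &
    !is.na(long$inter_icc) & long$inter_icc > threshold
  pass <- tapply(ok, factor(long$feature, levels = features), all)
  pass <- stats::setNames(as.logical(pass), features)
  structure(list(table = long, pass = pass,
                 survivors = features[pass], threshold = threshold),
            class = "icc_result")
}
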