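# Internal helpers shared across modules.

# Derive a child seed from a base seed; keeps values inside 32-bit range.
offset_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# Stratified fold assignment: each class is split as evenly as possible
# across folds. Returns an integer vector of fold ids aligned with y.
stratified_folds <- function(y, nfolds, seed) {
  stopifnot(nfolds >= 2)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  fold
}

# Population (1/N) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Feature columns of a feature table
#'
#' Metadata columns of a feature table are prefixed `meta_`; everything
#' else is a feature.
#'
#' @param table a feature table (data frame).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  names(table)[!startsWith(names(table), "meta_")]
}

#' Analysis rows of a feature table
#'
#' The segmentation pass that feeds screening, reduction and modelling is
#' observer 1's second pass; the remaining passes exist for agreement
#' analysis. Tables without replicate metadata are returned unchanged.
#'
#' @param table a feature table.
#' @return The sub-table of analysis rows.
#' @export
analysis_rows <- function(table) {
  if (!all(c("meta_observer_id", "meta_replicate_id") %in% names(table)))
    return(table)
  table[table$meta_observer_id == 1L & table$meta_replicate_id == 2L, ,
        drop = FALSE]
}

#' Feature sub-matrix of a feature table
#'
#' @param table a feature table.
#' @param features feature columns to keep (default: all).
#' @return Numeric matrix, rows aligned with the table.
#' @export
feature_matrix <- function(table, features = feature_columns(table)) {
  as.matrix(table[, features, drop = FALSE])
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}
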