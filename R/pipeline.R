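# End-to-end pipeline: simulate -> screen-species -> icc-filter ->
# reduce -> balance -> train-eval -> report, run for both feature-set
# lineages. Lineage A skips the species screen (A -> A1 -> A2); lineage B
# applies it (A -> B -> B1 -> B2). Models are always trained on the
# balanced human training rows and evaluated on the monkey cohort.

#' Pipeline configuration
#'
#' Collects every stage parameter with its conventional default: t-test
#' alpha 0.05, ICC threshold 0.75, MI threshold 0.1 nats, 5
#' cross-validation folds, SMOTE to a 1:1 ratio with k = 5, probability
#' threshold 0.5. All stage seeds are derived from the single `seed`.
#'
#' @param synthetic a [synthetic_spec()] describing the cohorts.
#' @param seed master seed.
#' @param alpha species t-test significance level.
#' @param var_equal pooled-variance t-test (Welch if `FALSE`).
#' @param lambda_rule lambda selection rule for both LASSO stages.
#' @param icc_threshold agreement pass threshold.
#' @param mi_threshold,mi_k MI filter parameters.
#' @param nfolds cross-validation folds.
#' @param smote_k SMOTE neighbour count.
#' @param prob_threshold confusion-matrix probability threshold.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(), seed = 20211L,
                            alpha = 0.05, var_equal = TRUE,
                            lambda_rule = "min", icc_threshold = 0.75,
                            mi_threshold = 0.1, mi_k = 3L, nfolds = 5L,
                            smote_k = 5L, prob_threshold = 0.5) {
  structure(list(synthetic = synthetic, seed = as.integer(seed),
                 alpha = alpha, var_equal = var_equal,
                 lambda_rule = lambda_rule,
                 icc_threshold = icc_threshold,
                 mi_threshold = mi_threshold, mi_k = as.integer(mi_k),
                 nfolds = as.integer(nfolds),
                 smote_k = as.integer(smote_k),
                 prob_threshold = prob_threshold,
                 schema_version = 1L),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return Character vector of issues; empty if the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)
  if (!inherits(config, "pipeline_config"))
    return("not a pipeline_config object")
  if (!inherits(config$synthetic, "synthetic_spec"))
    note("synthetic: not a synthetic_spec")
  if (is.null(config$seed) || is.na(config$seed))
    note("seed: an explicit seed is required")
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    note("alpha: must lie in (0, 1)")
  if (!is.numeric(config$icc_threshold) || config$icc_threshold <= 0)
    note("icc_threshold: must be positive")
  if (!is.numeric(config$mi_threshold) || config$mi_threshold < 0)
    note("mi_threshold: must be non-negative")
  if (!config$lambda_rule %in% c("min", "1se"))
    note("lambda_rule: must be 'min' or '1se'")
  if (config$nfolds < 2) note("nfolds: need at least 2 folds")
  if (config$smote_k < 1) note("smote_k: need at least 1 neighbour")
  if (!is.numeric(config$prob_threshold) || config$prob_threshold <= 0 ||
      config$prob_threshold >= 1)
    note("prob_threshold: must lie in (0, 1)")
  issues
}

# One lineage: reduce -> balance -> train -> evaluate.
.run_lineage <- function(human, monkey, feature_set, config, seed) {
  red <- reduce_features(human, feature_set,
                         mi_threshold = config$mi_threshold,
                         mi_k = config$mi_k, nfolds = config$nfolds,
                         seed = seed, lambda_rule = config$lambda_rule)
  out <- list(reduction = red, selected = red$selected)
  if (length(red$selected) == 0) {
    out$balanced <- NULL
    out$bundle <- NULL
    out$evaluation <- NULL
    return(out)
  }
  train_rows <- analysis_rows(human)
  test_rows <- analysis_rows(monkey)
  ztr <- zscore_apply(red$zscore,
                      feature_matrix(train_rows, red$zscore$features))
  zte <- zscore_apply(red$zscore,
                      feature_matrix(test_rows, red$zscore$features))
  xtr <- ztr[, red$selected, drop = FALSE]
  xte <- zte[, red$selected, drop = FALSE]
  bal <- balance_training(xtr, train_rows$meta_binary_label,
                          k = config$smote_k,
                          seed = offset_seed(seed, 10L))
  bundle <- train_models(bal$x, bal$y, seed = offset_seed(seed, 20L))
  out$balanced <- bal
  out$bundle <- bundle
  out$evaluation <- evaluate_models(bundle, xte,
                                    test_rows$meta_binary_label,
                                    threshold = config$prob_threshold)
  out
}

#' Run the full cross-species pipeline
#'
#' Executes both feature-set lineages on a simulated cohort pair and, if
#' `out_dir` is given, writes every artifact (resolved configuration,
#' screen and ICC tables, reduction summaries, balanced training table,
#' model-comparison report, per-model ROC points, run record).
#' Reruns with the same configuration produce byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @return A list of class `"pipeline_run"`: `record` (feature-set sizes
#'   along both lineages, seeds, config hash, stage timings), `sets`
#'   (named list of feature-name vectors A, B, A1, B1, A2, B2), `screen`,
#'   `icc`, `lineage_a`, `lineage_b`, `report`, `sim`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  issues <- validate_config(config)
  if (length(issues) > 0)
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "))
  seed <- config$seed
  timings <- c()
  tic <- function(expr, label) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[label]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  sim <- tic(simulate_feature_tables(config$synthetic, seed = seed),
             "simulate")
  set_a <- sim$truth$feature_names

  screen <- tic(run_species_screen(sim$human, sim$monkey,
                                   alpha = config$alpha,
                                   nfolds = config$nfolds,
                                   seed = offset_seed(seed, 1L),
                                   var_equal = config$var_equal,
                                   lambda_rule = config$lambda_rule),
                "screen_species")
  set_b <- screen$feature_set_b

  icc <- tic(icc_filter(sim$human, sim$monkey, features = set_a,
                        threshold = config$icc_threshold),
             "icc_filter")
  set_a1 <- icc$survivors
  set_b1 <- intersect(set_b, icc$survivors)

  lin_a <- tic(.run_lineage(sim$human, sim$monkey, set_a1, config,
                            offset_seed(seed, 100L)), "lineage_a")
  lin_b <- tic(.run_lineage(sim$human, sim$monkey, set_b1, config,
                            offset_seed(seed, 200L)), "lineage_b")

  report <- if (!is.null(lin_a$evaluation) && !is.null(lin_b$evaluation))
    build_report(lin_a$evaluation, lin_b$evaluation) else NULL

  sets <- list(A = set_a, B = set_b, A1 = set_a1, B1 = set_b1,
               A2 = lin_a$selected, B2 = lin_b$selected)
  record <- list(
    sizes = vapply(sets, length, 1L),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    lambda = c(species_screen = screen$lambda,
               lasso_a = lin_a$reduction$lambda,
               lasso_b = lin_b$reduction$lambda),
    defaults = list(alpha = config$alpha,
                    t_test = if (config$var_equal) "student" else "welch",
                    lambda_rule = config$lambda_rule,
                    icc_threshold = config$icc_threshold,
                    mi_threshold = config$mi_threshold,
                    smote_k = config$smote_k,
                    prob_threshold = config$prob_threshold),
    timings = timings)

  run <- structure(list(record = record, sets = sets, screen = screen,
                        icc = icc, lineage_a = lin_a, lineage_b = lin_b,
                        report = report, sim = sim),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run_artifacts(run, config, out_dir)
  run
}

#' Write the artifacts of a pipeline run
#'
#' @param run a [run_pipeline()] result.
#' @param config the configuration that produced it.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_run_artifacts <- function(run, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg$synthetic <- unclass(cfg$synthetic)
  write_json_file(cfg, file.path(out_dir, "config.json"))

  utils::write.csv(run$screen$per_feature,
                   file.path(out_dir, "screen_species.csv"),
                   row.names = FALSE)
  write_json_file(list(alpha = run$screen$alpha,
                       lambda = run$screen$lambda,
                       seed = run$screen$seed,
                       counts = as.list(run$screen$counts)),
                  file.path(out_dir, "screen_species.json"))

  icc_tab <- run$icc$table
  icc_tab$pass <- run$icc$pass[icc_tab$feature]
  utils::write.csv(icc_tab, file.path(out_dir, "icc.csv"),
                   row.names = FALSE)

  for (lin in c("a", "b")) {
    red <- run[[paste0("lineage_", lin)]]$reduction
    write_json_file(list(mi = as.list(red$mi),
                         mi_survivors = red$mi_survivors,
                         lambda = red$lambda,
                         selected = red$selected,
                         coefficients = as.list(red$coefficients)),
                    file.path(out_dir,
                              sprintf("reduction_%s2.json", lin)))
    if (length(red$selected) > 0) {
      utils::write.csv(
        data.frame(feature = red$selected,
                   weight = as.numeric(red$coefficients),
                   stringsAsFactors = FALSE),
        file.path(out_dir, sprintf("weights_%s2.csv", lin)),
        row.names = FALSE)
    }
    bal <- run[[paste0("lineage_", lin)]]$balanced
    if (!is.null(bal)) {
      bt <- data.frame(bal$x, check.names = FALSE)
      bt$meta_binary_label <- bal$y
      bt$meta_synthetic <- bal$synthetic
      utils::write.csv(bt,
                       file.path(out_dir,
                                 sprintf("balanced_train_%s2.csv", lin)),
                       row.names = FALSE)
    }
    ev <- run[[paste0("lineage_", lin)]]$evaluation
    if (!is.null(ev)) {
      for (mod in names(ev$roc))
        utils::write.csv(ev$roc[[mod]],
                         file.path(out_dir,
                                   sprintf("roc_%s2_%s.csv", lin, mod)),
                         row.names = FALSE)
    }
  }

  if (!is.null(run$report))
    utils::write.csv(run$report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)

  rec <- run$record
  rec$timings <- NULL  # wall-clock noise would break byte-identity
  rec$sizes <- as.list(rec$sizes)
  rec$lambda <- as.list(rec$lambda)
  write_json_file(rec, file.path(out_dir, "run_record.json"))
  invisible(out_dir)
}
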