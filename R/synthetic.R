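# Synthetic cohort generator.
#
# The study's MRI cohorts are not publicly available, so every downstream
# stage is exercised on simulated feature tables whose structure mirrors
# the real design: two species cohorts (575 human and 145 monkey discs by
# default), a binary degeneration label dichotomized from the Pfirrmann
# grade (I-II = 0, III-V = 1; 436/139 and 100/45 by default), and three
# segmentation passes per disc (observer 1 twice, at least a week apart in
# the real protocol, plus observer 2 once) whose added noise controls the
# per-feature intraclass correlation.

#' Dichotomize a Pfirrmann grade
#'
#' Grades I-II are coded healthy (0), grades III-V degenerated (1).
#'
#' @param grade integer vector of Pfirrmann grades in 1..5.
#' @return Integer vector of 0/1 labels.
#' @export
dichotomize_grade <- function(grade) {
  stopifnot(all(grade %in% 1:5))
  as.integer(grade >= 3L)
}

#' Observer noise level for a target intraclass correlation
#'
#' Under a one-way decomposition (subject variance `s^2`, independent
#' observer noise with standard deviation `sigma`), the expected ICC is
#' `s^2 / (s^2 + sigma^2)`. Inverting gives
#' `sigma = s * sqrt((1 - icc) / icc)`.
#'
#' @param target_icc target ICC in (0, 1].
#' @param subject_sd between-subject standard deviation (> 0).
#' @return The observer noise standard deviation.
#' @export
#' @examples
#' observer_noise_for_icc(0.5, 1)   # 1
#' observer_noise_for_icc(1.0, 2)   # 0
observer_noise_for_icc <- function(target_icc, subject_sd) {
  stopifnot(is.numeric(target_icc), length(target_icc) >= 1,
            is.numeric(subject_sd), all(subject_sd > 0))
  if (any(target_icc <= 0) || any(target_icc > 1))
    stop("target_icc must lie in (0, 1]")
  subject_sd * sqrt((1 - target_icc) / target_icc)
}

#' Specification of a synthetic two-species radiomics cohort
#'
#' Features are Gaussian with planted structure. Three planted categories
#' (possibly overlapping) drive the pipeline stages:
#' * species-divergent features carry a mean shift of `delta_s` SD units in
#'   the monkey cohort (the species screen should exclude them);
#' * degeneration-informative features carry a within-species label mean
#'   difference of `delta_d` SD units (the reduction stage should retain
#'   them);
#' * low-ICC features receive inflated observer noise tuned by
#'   [observer_noise_for_icc()] to a target ICC (the agreement filter
#'   should drop them).
#'
#' Features that are both divergent and informative model the failure mode
#' of naive cross-species transfer: the monkey shift is applied with a
#' negative sign, pushing degenerated monkey discs toward the healthy side
#' of a human-trained decision boundary. Divergent-only features alternate
#' shift sign. An optional block-equicorrelation structure (default
#' correlation 0.3 in blocks of 10) keeps the LASSO stages honest: fully
#' independent features would make sparse selection trivially well behaved.
#'
#' @param n_human,n_monkey number of discs per cohort.
#' @param n_pos_human,n_pos_monkey number of degenerated (label 1) discs.
#' @param n_features number of features in the table.
#' @param divergent_idx indices of species-divergent features.
#' @param delta_s species mean shift in SD units.
#' @param informative_idx indices of degeneration-informative features.
#' @param delta_d degeneration effect in SD units.
#' @param low_icc_idx indices of low-agreement features.
#' @param icc_low target ICC for low-agreement features.
#' @param icc_default target ICC for all other features.
#' @param base_sd between-disc standard deviation of every feature.
#' @param block_size,block_rho equicorrelated block size and within-block
#'   correlation (`block_rho = 0` gives independent features).
#' @param seed default generation seed used by
#'   [simulate_feature_tables()].
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_human = 575L, n_monkey = 145L,
                           n_pos_human = 139L, n_pos_monkey = 45L,
                           n_features = 300L,
                           divergent_idx = 1:120, delta_s = 1.5,
                           informative_idx = 107:126, delta_d = 1.5,
                           low_icc_idx = 271:300, icc_low = 0.5,
                           icc_default = 0.95,
                           base_sd = 1, block_size = 10L, block_rho = 0.3,
                           seed = 20211L) {
  stopifnot(n_human >= 2, n_monkey >= 2, n_features >= 1,
            n_pos_human >= 1, n_pos_human < n_human,
            n_pos_monkey >= 1, n_pos_monkey < n_monkey,
            base_sd > 0, block_size >= 1,
            block_rho >= 0, block_rho < 1,
            is.finite(delta_s), is.finite(delta_d))
  if (length(divergent_idx) > 0)
    stopifnot(all(divergent_idx %in% seq_len(n_features)))
  if (length(informative_idx) > 0)
    stopifnot(all(informative_idx %in% seq_len(n_features)))
  if (length(low_icc_idx) > 0)
    stopifnot(all(low_icc_idx %in% seq_len(n_features)))
  if (icc_low <= 0 || icc_low > 1 || icc_default <= 0 || icc_default > 1)
    stop("target ICC values must lie in (0, 1]")
  structure(list(
    n_human = as.integer(n_human), n_monkey = as.integer(n_monkey),
    n_pos_human = as.integer(n_pos_human),
    n_pos_monkey = as.integer(n_pos_monkey),
    n_features = as.integer(n_features),
    divergent_idx = as.integer(divergent_idx), delta_s = delta_s,
    informative_idx = as.integer(informative_idx), delta_d = delta_d,
    low_icc_idx = as.integer(low_icc_idx), icc_low = icc_low,
    icc_default = icc_default, base_sd = base_sd,
    block_size = as.integer(block_size), block_rho = block_rho,
    seed = as.integer(seed)), class = "synthetic_spec")
}

# Subject-level feature draws with block-equicorrelation.
.draw_subject_matrix <- function(n, p, base_sd, block_size, rho) {
  e <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0 && block_size > 1) {
    block <- ((seq_len(p) - 1L) %/% block_size) + 1L
    g <- matrix(stats::rnorm(n * max(block)), n, max(block))
    e <- sqrt(rho) * g[, block, drop = FALSE] + sqrt(1 - rho) * e
  }
  e * base_sd
}

.simulate_cohort <- function(spec, species, truth) {
  n <- if (species == "human") spec$n_human else spec$n_monkey
  n_pos <- if (species == "human") spec$n_pos_human else spec$n_pos_monkey
  p <- spec$n_features

  label <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  grade <- ifelse(label == 1L, sample(3:5, n, replace = TRUE),
                  sample(1:2, n, replace = TRUE))

  true_vals <- .draw_subject_matrix(n, p, spec$base_sd,
                                    spec$block_size, spec$block_rho)
  if (length(spec$informative_idx) > 0)
    true_vals[, spec$informative_idx] <-
      true_vals[, spec$informative_idx] +
      outer(label, rep(spec$delta_d * spec$base_sd,
                       length(spec$informative_idx)))
  if (species == "monkey")
    true_vals <- sweep(true_vals, 2L, truth$species_shift, "+")

  # Three segmentation passes per disc: observer 1 pass 1, observer 1
  # pass 2 (the analysis pass), observer 2 pass 1.
  passes <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L))
  sigma <- truth$sigma_obs
  obs <- lapply(passes, function(pr) {
    noise <- matrix(stats::rnorm(n * p), n, p)
    noise <- sweep(noise, 2L, sigma, "*")
    true_vals + noise
  })

  discs_per_subject <- if (species == "human") 7L else 9L
  disc_id <- sprintf("%s_disc_%03d", species, seq_len(n))
  subject_id <- sprintf("%s_subj_%03d", species,
                        ((seq_len(n) - 1L) %/% discs_per_subject) + 1L)
  segments <- c("T12/L1", "L1/2", "L2/3", "L3/4", "L4/5", "L5/S1", "T11/12")
  segment <- segments[((seq_len(n) - 1L) %% length(segments)) + 1L]

  tabs <- lapply(seq_along(passes), function(i) {
    vals <- as.data.frame(obs[[i]])
    names(vals) <- truth$feature_names
    cbind(data.frame(meta_disc_id = disc_id, meta_subject_id = subject_id,
                     meta_species = species, meta_segment = segment,
                     meta_pfirrmann_grade = grade,
                     meta_binary_label = label,
                     meta_observer_id = passes[[i]][1L],
                     meta_replicate_id = passes[[i]][2L],
                     stringsAsFactors = FALSE),
          vals)
  })
  out <- do.call(rbind, tabs)
  out <- out[order(out$meta_disc_id, out$meta_observer_id,
                   out$meta_replicate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate human and monkey radiomics feature tables
#'
#' Draws the two cohorts described by a [synthetic_spec()]: disc-level
#' "true" feature values with planted species and degeneration effects,
#' then three observed segmentation passes per disc with per-feature
#' observer noise. Output is deterministic given the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return A list with elements `human` and `monkey` (feature tables whose
#'   metadata columns are prefixed `meta_`) and `truth`, the realized
#'   ground truth (feature names, per-feature category flags, the applied
#'   species shift and observer noise vectors).
#' @export
#' @examples
#' sim <- simulate_feature_tables(synthetic_spec(
#'   n_human = 40, n_monkey = 20, n_pos_human = 10, n_pos_monkey = 6,
#'   n_features = 12, divergent_idx = 1:3, informative_idx = 4:5,
#'   low_icc_idx = 11:12))
#' table(analysis_rows(sim$human)$meta_binary_label)
simulate_feature_tables <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_features

  manifest <- build_manifest()
  if (p <= nrow(manifest)) {
    idx <- unique(round(seq(1L, nrow(manifest), length.out = p)))
    feature_names <- manifest$name[idx]
  } else {
    feature_names <- sprintf("T2_original_firstorder_Synthetic%04d",
                             seq_len(p))
  }

  divergent <- seq_len(p) %in% spec$divergent_idx
  informative <- seq_len(p) %in% spec$informative_idx
  low_icc <- seq_len(p) %in% spec$low_icc_idx

  # Species shift: overlap (divergent & informative) features push the
  # monkey cohort toward the healthy side (negative sign); divergent-only
  # features alternate sign.
  species_shift <- numeric(p)
  div_only <- which(divergent & !informative)
  species_shift[div_only] <-
    spec$delta_s * spec$base_sd * rep_len(c(1, -1), length(div_only))
  species_shift[divergent & informative] <- -spec$delta_s * spec$base_sd

  sigma_obs <- rep(observer_noise_for_icc(spec$icc_default, spec$base_sd), p)
  sigma_obs[low_icc] <- observer_noise_for_icc(spec$icc_low, spec$base_sd)

  truth <- list(spec = spec, feature_names = feature_names,
                divergent = divergent, informative = informative,
                low_icc = low_icc, species_shift = species_shift,
                label_effect = ifelse(informative,
                                      spec$delta_d * spec$base_sd, 0),
                sigma_obs = sigma_obs, seed = as.integer(seed))

  withr::with_seed(as.integer(seed), {
    human <- .simulate_cohort(spec, "human", truth)
    monkey <- .simulate_cohort(spec, "monkey", truth)
  })
  stopifnot(all(human$meta_binary_label ==
                  dichotomize_grade(human$meta_pfirrmann_grade)),
            all(monkey$meta_binary_label ==
                  dichotomize_grade(monkey$meta_pfirrmann_grade)))
  list(human = human, monkey = monkey, truth = truth)
}

#' Write a feature table and ground truth to disk
#'
#' The table is written as CSV (metadata columns keep their `meta_`
#' prefix); the ground truth as a JSON sidecar.
#'
#' @param sim result of [simulate_feature_tables()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_feature_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(human = file.path(dir, "features_human.csv"),
             monkey = file.path(dir, "features_monkey.csv"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(sim$human, paths[["human"]], row.names = FALSE)
  utils::write.csv(sim$monkey, paths[["monkey"]], row.names = FALSE)
  truth <- sim$truth
  truth$spec <- unclass(truth$spec)
  write_json_file(truth, paths[["truth"]])
  invisible(paths)
}
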