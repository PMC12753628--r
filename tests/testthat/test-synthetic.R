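test_that("label dichotomization follows the Pfirrmann convention", {
  expect_equal(dichotomize_grade(1:5), c(0L, 0L, 1L, 1L, 1L))
  sim <- simulate_feature_tables(small_spec(), seed = 11)
  for (tab in list(sim$human, sim$monkey))
    expect_equal(tab$meta_binary_label,
                 dichotomize_grade(tab$meta_pfirrmann_grade))
})

test_that("generation is deterministic and structured as expected", {
  spec <- small_spec()
  a <- simulate_feature_tables(spec, seed = 5)
  b <- simulate_feature_tables(spec, seed = 5)
  expect_identical(a, b)
  c <- simulate_feature_tables(spec, seed = 6)
  expect_false(identical(a$human, c$human))

  # three segmentation passes per disc; analysis rows = one per disc
  expect_equal(nrow(a$human), 3L * spec$n_human)
  expect_equal(nrow(analysis_rows(a$human)), spec$n_human)
  expect_equal(table(analysis_rows(a$human)$meta_binary_label)[["1"]],
               spec$n_pos_human)
  expect_true(all(table(a$monkey$meta_disc_id) == 3L))
  expect_false(anyNA(a$human))
  # feature columns come from the manifest namespace
  expect_true(all(feature_columns(a$human) %in% build_manifest()$name))
})

test_that("default cohort sizes match the study design", {
  spec <- synthetic_spec()
  expect_equal(spec$n_human, 575L)
  expect_equal(spec$n_pos_human, 139L)
  expect_equal(spec$n_monkey, 145L)
  expect_equal(spec$n_pos_monkey, 45L)
})

test_that("planted species shifts appear and null features stay flat", {
  spec <- small_spec(n_human = 300L, n_monkey = 150L, n_pos_human = 75L,
                     n_pos_monkey = 45L, delta_s = 1.5, block_rho = 0)
  sim <- simulate_feature_tables(spec, seed = 21)
  h <- feature_matrix(analysis_rows(sim$human))
  m <- feature_matrix(analysis_rows(sim$monkey))
  diff <- abs(colMeans(h) - colMeans(m))
  expect_true(all(diff[sim$truth$divergent] > 1.0))
  null_idx <- !sim$truth$divergent & !sim$truth$informative
  expect_lt(mean(diff[null_idx]), 0.25)
})

test_that("observer noise closed form hits the target ICC", {
  expect_equal(observer_noise_for_icc(1.0, 3), 0)
  expect_equal(observer_noise_for_icc(0.5, 1.0), 1.0)
  expect_equal(observer_noise_for_icc(0.75, 2.0), 2 * sqrt(1 / 3))
  expect_error(observer_noise_for_icc(0, 1), "\\(0, 1\\]")

  # simulation recovery at 5000 subjects
  withr::with_seed(99, {
    subj <- rnorm(5000, sd = 2)
    sig <- observer_noise_for_icc(0.75, 2)
    m <- cbind(subj + rnorm(5000, sd = sig), subj + rnorm(5000, sd = sig))
  })
  expect_lt(abs(icc_2way_absolute(m) - 0.75), 0.05)
})

test_that("synthetic disc images are deterministic and grade-graded", {
  a <- simulate_disc_image("human", 3, seed = 4)
  b <- simulate_disc_image("human", 3, seed = 4)
  expect_identical(a, b)
  roi_mean <- vapply(1:5, function(g) {
    img <- simulate_disc_image("human", g, seed = 4)
    mean(img$image[img$mask == 1])
  }, 0)
  expect_true(all(diff(roi_mean) < 0))
  v1 <- with(simulate_disc_image("human", 1, seed = 4),
             var(image[mask == 1]))
  v5 <- with(simulate_disc_image("human", 5, seed = 4),
             var(image[mask == 1]))
  expect_gt(v5, v1)
  # monkey field of view is smaller
  expect_lt(sum(simulate_disc_image("monkey", 1, seed = 4)$mask),
            sum(simulate_disc_image("human", 1, seed = 4)$mask))
})

test_that("disc images round-trip through NIfTI", {
  img <- simulate_disc_image("monkey", 2, seed = 9, size = 32)
  tmp <- withr::local_tempdir()
  write_disc_image(img, file.path(tmp, "img.nii.gz"),
                   file.path(tmp, "mask.nii.gz"))
  back <- read_disc_image(file.path(tmp, "img.nii.gz"),
                          file.path(tmp, "mask.nii.gz"))
  expect_equal(back$image, img$image, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$mask, img$mask, ignore_attr = TRUE)
})

test_that("feature tables and ground truth serialize to CSV + JSON", {
  sim <- simulate_feature_tables(small_spec(n_features = 10L,
                                            divergent_idx = 1:2,
                                            informative_idx = 3:4,
                                            low_icc_idx = 9:10),
                                 seed = 2)
  tmp <- withr::local_tempdir()
  paths <- write_feature_tables(sim, tmp)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["human"]], check.names = FALSE)
  expect_equal(nrow(back), nrow(sim$human))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$feature_names, sim$truth$feature_names)
})
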