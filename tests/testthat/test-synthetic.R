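test_that("generated tables have the contracted shape and are deterministic", {
  cfg <- synthetic_config(n_compounds = 100, n_models = 3, seed = 7)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$table), 100)
  expect_equal(sum(grepl("^pred_", names(ds$table))), 3)
  expect_equal(sum(grepl("^std_", names(ds$table))), 3)
  expect_equal(sum(grepl("^in_ad_", names(ds$table))), 3)
  expect_false(anyDuplicated(ds$table$compound_id) > 0)

  ds2 <- generate_dataset(cfg)
  expect_identical(ds, ds2)
})

test_that("config validation rejects out-of-range and non-finite values", {
  expect_error(synthetic_config(n_compounds = 0), "n_compounds")
  expect_error(synthetic_config(error_correlation = 1.2), "error_correlation")
  expect_error(synthetic_config(outlier_fraction = -0.1), "outlier_fraction")
  expect_error(synthetic_config(error_sd_base = NaN), "error_sd_base")
  expect_error(
    synthetic_config(activity_mixture = list(weights = c(0.5, 0.4),
                                             means = c(0, 50),
                                             sds = c(10, 10))),
    "sum to 1")
})

test_that("activities stay inside the assay range and cluster at low values", {
  ds <- generate_dataset(synthetic_config(n_compounds = 3000, seed = 3))
  expect_true(all(ds$table$y_exp >= -41.6 & ds$table$y_exp <= 110.9))
  # the bulk of the mixture sits in the low-activity region
  expect_gt(mean(ds$table$y_exp >= -10 & ds$table$y_exp <= 40), 0.5)
})

test_that("planted-outlier count is binomial around its expectation", {
  ds <- generate_dataset(synthetic_config(n_compounds = 2000,
                                          outlier_fraction = 0.05,
                                          seed = 5))
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.05) # central 99% interval
  n_out <- sum(ds$truth$is_outlier)
  expect_gte(n_out, bounds[1])
  expect_lte(n_out, bounds[2])
})

test_that("planted outliers have elevated error but baseline uncertainty", {
  cfg <- synthetic_config(n_compounds = 2000, seed = 9)
  ds <- generate_dataset(cfg)
  err <- abs(ds$table$y_exp - ds$table$pred_m1)
  out <- ds$truth$is_outlier
  expect_gte(mean(err[out]) - mean(err[!out]), cfg$outlier_error_shift / 2)
  # Consensus-STD distribution of outliers is not elevated
  expect_lt(mean(ds$table$std_m1[out]), mean(ds$table$std_m1) * 1.5)
})

test_that("model error vectors carry the configured pairwise correlation", {
  cfg <- synthetic_config(n_compounds = 20000, outlier_fraction = 0,
                          seed = 11)
  ds <- generate_dataset(cfg)
  err <- sapply(paste0("pred_m", 1:9),
                function(cl) ds$table$y_exp - ds$table[[cl]])
  cc <- cor(err)[upper.tri(diag(9))]
  expect_true(all(abs(cc - cfg$error_correlation) <= 0.05))
})

test_that("std columns are exactly the sample SD of the stored sub-models", {
  ds <- generate_dataset(small_config())
  sub <- ds$truth$submodel_preds
  for (m in 1:3) {
    expect_equal(ds$table[[paste0("std_m", m)]],
                 apply(sub[, m, ], 1, sd))
  }
})

test_that("AD flags cover the configured fraction per model", {
  cfg <- synthetic_config(n_compounds = 1000,
                          ad_coverage_per_model = c(rep(0.6, 4), rep(0.9, 5)),
                          seed = 2)
  ds <- generate_dataset(cfg)
  cov <- sapply(paste0("in_ad_m", 1:9), function(cl) mean(ds$table[[cl]]))
  expect_equal(unname(cov), cfg$ad_coverage_per_model, tolerance = 0.005)
})

test_that("planted substructure bits scale the local error", {
  cfg <- small_config(n_compounds = 1500,
                      planted_effect_bits = list(list(bit = 3, multiplier = 2,
                                                      support = 300)))
  ds <- generate_dataset(cfg)
  carriers <- ds$substructure[, 3] == 1
  expect_equal(sum(carriers), 300)
  expect_equal(unique(ds$truth$error_scale[carriers]), 2)
  err <- abs(ds$table$y_exp - ds$table$pred_m1)
  expect_gt(sqrt(mean(err[carriers]^2)), sqrt(mean(err[!carriers]^2)) * 1.3)
})

test_that("split assignment reproduces the published set proportions exactly", {
  ds <- generate_dataset(synthetic_config(n_compounds = 1512, seed = 1))
  sp <- split_dataset(ds, c(1012, 200, 300) / 1512, seed = 4)
  counts <- table(sp$table$split)
  expect_lte(abs(counts[["train"]] - 1012), 1)
  expect_lte(abs(counts[["leaderboard"]] - 200), 1)
  expect_lte(abs(counts[["test"]] - 300), 1)

  sp2 <- split_dataset(ds, c(1012, 200, 300) / 1512, seed = 4)
  expect_identical(sp$table$split, sp2$table$split)

  all_train <- split_dataset(ds, c(1, 0, 0), seed = 4)
  expect_true(all(all_train$table$split == "train"))

  expect_error(split_dataset(ds, c(0.5, 0.2, 0.2)), "sum to 1")
})
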