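toy_table <- function(preds, ad = NULL, y = 0) {
  tab <- data.frame(compound_id = "c1", y_exp = y, split = "test")
  for (i in seq_along(preds)) tab[[paste0("pred_m", i)]] <- preds[i]
  if (!is.null(ad)) {
    for (i in seq_along(ad)) tab[[paste0("in_ad_m", i)]] <- ad[i]
  }
  tab
}

test_that("mode I averages all predictions with their cross-model SD", {
  res <- build_consensus(toy_table(c(10, 20, 30)))
  expect_equal(res$consensus, 20)
  expect_equal(res$consensus_std, sd(c(10, 20, 30)))
  expect_equal(res$n_models_used, 3)

  single <- build_consensus(toy_table(17))
  expect_equal(single$consensus, 17)
  expect_true(is.na(single$consensus_std))
})

test_that("mode II averages only covering models and honours min_models", {
  tab <- toy_table(c(10, 20, 30), ad = c(1, 1, 0))
  res <- build_consensus(tab, mode = "II", min_models = 1)
  expect_equal(res$consensus, 15)
  expect_equal(res$n_models_used, 2)
  expect_true(is.na(build_consensus(tab, mode = "II",
                                    min_models = 3)$consensus))
  expect_error(build_consensus(toy_table(c(1, 2)), mode = "II"),
               "applicability-domain")
})

test_that("missing predictions mean the model does not cover the compound", {
  tab <- toy_table(c(10, NA, 30), ad = c(1, 1, 1))
  expect_equal(build_consensus(tab)$consensus, 20)
  expect_equal(build_consensus(tab, mode = "II")$n_models_used, 2)
})

test_that("consensus of identical models is idempotent and mode II with
           permissive flags reproduces mode I", {
  ds <- generate_dataset(small_config(n_compounds = 120))
  tab <- ds$table
  same <- tab
  same$pred_m2 <- same$pred_m1
  same$pred_m3 <- same$pred_m1
  expect_equal(build_consensus(same)$consensus, same$pred_m1)

  allin <- tab
  for (m in 1:3) allin[[paste0("in_ad_m", m)]] <- 1L
  expect_equal(build_consensus(allin, mode = "II", min_models = 1)$consensus,
               build_consensus(tab, mode = "I")$consensus)
})

test_that("consensus RMSE never exceeds the mean of individual model RMSEs", {
  for (s in 1:5) {
    ds <- generate_dataset(small_config(n_compounds = 400, n_models = 5,
                                        seed = s))
    tab <- ds$table
    ind <- sapply(paste0("pred_m", 1:5),
                  function(cl) rmse(tab$y_exp, tab[[cl]]))
    cons <- build_consensus(tab)
    expect_lte(rmse(cons$y_exp, cons$consensus), mean(ind))
  }
})

test_that("stringency sweep has non-increasing coverage and crafted-mask
           coverages match enumeration", {
  tab <- rbind(toy_table(c(1, 2, 3), ad = c(1, 0, 0)),
               toy_table(c(1, 2, 3), ad = c(1, 1, 0)),
               toy_table(c(1, 2, 3), ad = c(1, 1, 1)))
  tab$compound_id <- c("a", "b", "c")
  sw <- stringency_sweep(tab, min_models = 1:3)
  expect_equal(sw$coverage, c(100, 200 / 3, 100 / 3))

  ds <- generate_dataset(small_config(n_compounds = 500, n_models = 5,
                                      ad_coverage_per_model =
                                        c(0.5, 0.6, 0.7, 0.8, 0.9)))
  sw <- stringency_sweep(ds$table, min_models = 1:5)
  expect_true(all(diff(sw$coverage) <= 0))

  # all compounds inside every AD: full coverage at every stringency
  allin <- ds$table
  for (m in 1:5) allin[[paste0("in_ad_m", m)]] <- 1L
  expect_true(all(stringency_sweep(allin, min_models = 1:5)$coverage == 100))
})

test_that("stringency rows with an empty covered set carry NA metrics", {
  tab <- toy_table(c(1, 2), ad = c(0, 0))
  sw <- stringency_sweep(tab, min_models = 1:2)
  expect_equal(sw$coverage, c(0, 0))
  expect_true(all(is.na(sw$rmse)))
})

test_that("Grubbs refinement drops a deviating model, else equals mode I", {
  tab <- toy_table(c(20, 21, 22, 19, 95))
  res <- grubbs_refined_consensus(tab, alpha = 0.1)
  expect_equal(res$consensus, mean(c(20, 21, 22, 19)))
  expect_equal(res$n_models_used, 4)

  calm <- toy_table(c(20, 21, 22, 19, 23))
  expect_equal(grubbs_refined_consensus(calm, alpha = 0.1)$consensus,
               build_consensus(calm)$consensus)

  expect_warning(two <- grubbs_refined_consensus(toy_table(c(10, 30))),
                 "fewer than 3 models")
  expect_equal(two$consensus, 20)
})

test_that("predict and residuals methods act on new tables", {
  ds <- generate_dataset(small_config(n_compounds = 50))
  res <- build_consensus(ds$table)
  expect_equal(predict(res, ds$table), res$consensus)
  expect_equal(residuals(res), res$y_exp - res$consensus)
})
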