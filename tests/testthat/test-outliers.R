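test_that("bin closing follows the size and rising-error criteria", {
  # homogeneous errors: the second bin can only close at the data end
  b <- fit_bins(seq(0, 1, length.out = 100), rep(5, 100), min_bin_size = 50)
  expect_equal(b$n, c(50, 50))
  expect_equal(b$rmse, c(5, 5))

  # fewer compounds than the minimum: one bin covering everything
  b <- suppressMessages(fit_bins(1:30 / 30, rep(2, 30), min_bin_size = 50))
  expect_equal(nrow(b), 1)
  expect_equal(b$n, 30)

  # errors growing with DM: several bins with non-decreasing RMSE
  dm <- withr::with_seed(3, sort(runif(200)))
  err <- withr::with_seed(4, abs(rnorm(200, 0, 1 + 9 * dm)))
  b <- fit_bins(dm, err, min_bin_size = 50)
  expect_gte(nrow(b), 2)
  expect_true(all(diff(b$rmse) >= 0))
  expect_true(all(b$n[-nrow(b)] >= 50))
  expect_equal(sum(b$n), 200)
})

test_that("tied DM values are never split across a bin boundary", {
  dm <- c(rep(0, 49), rep(1, 10), rep(2, 60))
  err <- c(rep(1, 49), rep(1, 10), rep(10, 60))
  b <- fit_bins(dm, err, min_bin_size = 50)
  # first bin must extend through the whole dm == 1 tie group
  expect_equal(b$n[1], 59)
  expect_equal(b$dm_max[1], 1)
})

test_that("flagging uses strict exceedance of z times the bin RMSE", {
  dm <- seq(0, 1, length.out = 100)
  err <- rep(4, 100)
  bins <- fit_bins(dm, err, min_bin_size = 50)

  none <- flag_outliers(dm, err, bins, z = 3)
  expect_equal(none$summary$n_flagged, 0)

  err2 <- err
  err2[10] <- 10 * bins$rmse[1]
  rep2 <- flag_outliers(dm, err2, fit_bins(dm, err2, 50), z = 3)
  expect_true(rep2$compounds$flagged[10])

  # an error exactly at the threshold is not flagged
  at <- flag_outliers(dm, rep(3 * 4, 100), bins, z = 3)
  expect_equal(at$summary$n_flagged, 0)
})

test_that("raising z never increases the flagged count and cleaning helps", {
  ds <- generate_dataset(synthetic_config(n_compounds = 1500, seed = 6))
  tab <- ds$table
  dm <- tab$std_m1
  err <- abs(tab$y_exp - tab$pred_m1)
  bins <- fit_bins(dm, err, 50)
  counts <- sapply(c(1.5, 2, 2.5, 3, 4),
                   function(z) flag_outliers(dm, err, bins,
                                             z = z)$summary$n_flagged)
  expect_true(all(diff(counts) <= 0))

  rep3 <- flag_outliers(dm, err, bins, z = 3, y_exp = tab$y_exp,
                        y_pred = tab$pred_m1)
  expect_gt(rep3$summary$n_flagged, 0)
  expect_lte(rep3$summary$rmse_clean, rep3$summary$rmse_full)
  expect_gt(rep3$summary$rmse_outlier, rep3$summary$rmse_full)
  # every compound lands in exactly one bin and the counts add up
  expect_equal(tabulate(rep3$compounds$bin, nbins = nrow(rep3$bins)),
               rep3$bins$n)
})

test_that("DM values outside the fitted range go to the terminal bins", {
  dm <- seq(1, 2, length.out = 100)
  bins <- fit_bins(dm, rep(1, 100), 50)
  expect_message(
    rep <- flag_outliers(c(0.5, 2.5), c(1, 1), bins, z = 3),
    "outside the fitted range")
  expect_equal(rep$compounds$bin, c(1, nrow(bins)))
})

test_that("AD cutoff is the order-statistic quantile of training DM", {
  expect_equal(ad_threshold(1:100, 0.9), 90)
  expect_equal(ad_threshold(sample(1:100), 0.9), 90)
  expect_equal(ad_threshold(rep(7, 12), 0.5), 7)
  expect_equal(ad_threshold(c(3, 1, 2), 1.0), 3)
  expect_error(ad_threshold(numeric(0)), "empty")
  expect_error(ad_threshold(1:10, 0), "coverage")
})

test_that("cross-model intersection keeps ids flagged by enough models", {
  sets <- list(c("a", "b"), c("a", "c"), c("a", "b"), c("d"), character(0))
  expect_equal(cross_model_outliers(sets, 3), "a")
  expect_setequal(cross_model_outliers(sets, 2), c("a", "b"))
  expect_length(cross_model_outliers(list(character(0), character(0)), 1), 0)
  # duplicated ids within one model's set count once
  expect_length(cross_model_outliers(list(c("x", "x", "x")), 2), 0)
})

test_that("the ensemble scan wires per-model reports into a consensus set", {
  ds <- generate_dataset(synthetic_config(n_compounds = 1000, seed = 8))
  scan <- ensemble_outlier_scan(ds$table, min_bin_size = 50, z = 3,
                                min_models = 3)
  expect_length(scan$per_model, 9)
  expect_s3_class(scan$per_model$m1, "outlier_report")
  flagged_counts <- sapply(scan$per_model,
                           function(r) r$summary$n_flagged)
  expect_true(all(flagged_counts >= 0))
  # every consensus id was flagged by at least three models
  counts <- table(unlist(lapply(scan$per_model, function(r)
    unique(r$compounds$compound_id[r$compounds$flagged]))))
  expect_true(all(counts[scan$consensus_ids] >= 3))
})
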