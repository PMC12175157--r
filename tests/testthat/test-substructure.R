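test_that("support filter keeps bits at the threshold and drops below it", {
  m <- cbind(bit_a = c(rep(1, 32), rep(0, 68)),
             bit_b = c(rep(1, 31), rep(0, 69)),
             bit_c = rep(0, 100))
  kept <- filter_support(m, min_support = 32)
  expect_identical(colnames(kept), "bit_a")
  expect_equal(ncol(filter_support(m, min_support = 1)), 2)
})

test_that("the rescaled bootstrap null is centred when subset == full set", {
  se <- withr::with_seed(1, rnorm(2000, 0, 18))^2
  pv <- substructure_pvalues(se, rep(TRUE, 2000), n_boot = 1e5, seed = 2)
  expect_equal(pv$rmse_sub, pv$rmse_overall)
  # both tails near 0.5; slack covers 3 Monte-Carlo SEs plus the small
  # skewness of the resampled RMSE around its centre
  expect_lt(abs(pv$p_improvement - 0.5), 0.015)
  expect_lt(abs(pv$p_degradation - 0.5), 0.015)
  expect_lte(pv$p_improvement + pv$p_degradation, 1)
})

test_that("degenerate and one-sided subsets behave as documented", {
  se <- c(rep(0, 50), rep(4, 450))
  expect_warning(
    pv <- substructure_pvalues(se, c(rep(TRUE, 50), rep(FALSE, 450)),
                               n_boot = 100, seed = 1),
    "degenerate")
  expect_equal(pv$p_improvement, 0)
  expect_error(substructure_pvalues(se, rep(FALSE, 500), 100), "empty")
  expect_error(substructure_pvalues(se, rep(TRUE, 499), 100), "match")
})

test_that("a strongly degraded subset yields a small degradation p-value", {
  se <- withr::with_seed(3, c(rnorm(900, 0, 15)^2, rnorm(100, 0, 30)^2))
  mask <- c(rep(FALSE, 900), rep(TRUE, 100))
  pv <- substructure_pvalues(se, mask, n_boot = 2e4, seed = 4)
  expect_lt(pv$p_degradation, 0.01)
  expect_gt(pv$p_improvement, 0.95)
  expect_gt(pv$rmse_sub, pv$rmse_overall)
})

test_that("full-pool resampling is available as the alternative null", {
  se <- withr::with_seed(5, rnorm(1000, 0, 15)^2)
  mask <- withr::with_seed(6, runif(1000) < 0.1)
  pv <- substructure_pvalues(se, mask, n_boot = 2e4, seed = 7,
                             source = "full")
  expect_gt(min(pv$p_improvement, pv$p_degradation), 0.001)
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  for (r in 1:25) {
    p <- withr::with_seed(r, runif(sample(1:40, 1)))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("the scan filters support, directs significance, and is invariant
           to bit order", {
  cfg <- small_config(
    n_compounds = 600, n_models = 3, n_substructure_bits = 30,
    outlier_fraction = 0,
    planted_effect_bits = list(list(bit = 1, multiplier = 2.5,
                                    support = 80)))
  ds <- generate_dataset(cfg)
  cons <- build_consensus(ds$table)
  tab <- data.frame(y_exp = cons$y_exp, consensus = cons$consensus)

  scan <- run_substructure_scan(tab, ds$substructure, "consensus",
                                min_support = 32, n_boot = 5000, seed = 9)
  hit <- scan[scan$bit == "bit_1", ]
  expect_equal(hit$direction, "degradation")
  expect_true(hit$significant)
  expect_true(all(scan$support >= 32))
  expect_true(all(scan$p_bh >= scan$p_min))

  # shuffling bit columns leaves per-bit results unchanged (label seeds)
  perm <- withr::with_seed(1, sample(ncol(ds$substructure)))
  scan2 <- run_substructure_scan(tab, ds$substructure[, perm], "consensus",
                                 min_support = 32, n_boot = 5000, seed = 9)
  expect_equal(scan2[order(scan2$bit), ], scan[order(scan$bit), ],
               ignore_attr = TRUE)
})

test_that("scan guards: empty support set and misaligned matrices", {
  ds <- generate_dataset(small_config(n_compounds = 40))
  tab <- data.frame(y_exp = ds$table$y_exp, consensus = ds$table$pred_m1)
  empty <- run_substructure_scan(tab, ds$substructure, "consensus",
                                 min_support = 41, n_boot = 10)
  expect_equal(nrow(empty), 0)
  expect_error(run_substructure_scan(tab[1:10, ], ds$substructure,
                                     "consensus"),
               "align")
  expect_error(run_substructure_scan(tab, ds$substructure, "nope"),
               "not found")
})
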