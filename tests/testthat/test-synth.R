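test_that("quantile/moment matching reproduces its targets deterministically", {
  ln <- fit_lognormal_iqr(0.55, 0.41, 0.79)
  expect_equal(ln$median, 0.55, tolerance = 1e-6)
  expect_equal(ln$q3 - ln$q1, 0.79 - 0.41, tolerance = 1e-6)
  lg <- fit_logitnormal_iqr(28, 18, 44)
  expect_equal(lg$median, 28, tolerance = 1e-6)
  expect_equal(lg$q3 - lg$q1, 44 - 18, tolerance = 1e-6)
  tn <- fit_truncnorm_moments(7.30, 3.91, -5, 25)
  expect_equal(tn$mean, 7.30, tolerance = 1e-6)
  expect_equal(tn$sd, 3.91, tolerance = 1e-6)
  # truncation that actually bites: implantation depth bounded below at 0
  tn2 <- fit_truncnorm_moments(4.79, 4.02, 0, 25)
  expect_equal(tn2$mean, 4.79, tolerance = 1e-5)
  expect_equal(tn2$sd, 4.02, tolerance = 1e-5)
  expect_true(tn2$exact)
  # infeasible target (CV > 1 against a lower bound): closest fit, flagged
  tn3 <- fit_truncnorm_moments(16.50, 18.74, 0, 90)
  expect_false(tn3$exact)
  expect_error(fit_lognormal_iqr(0.5, 0.6, 0.6), "q3 > q1")
})

test_that("statistical generation is reproducible and respects invariants", {
  a <- sample_cohort_statistical(500, seed = 99)
  b <- sample_cohort_statistical(500, seed = 99)
  expect_identical(a, b)
  c2 <- sample_cohort_statistical(500, seed = 100)
  expect_false(identical(a$cpmax, c2$cpmax))
  expect_true(all(a$cpi >= 0 & a$cpi <= 100))
  expect_true(all(a$cpmax >= 0))
  expect_identical(a$ca, as.integer(a$lbbb_rbbb | a$ppi))
  expect_true(all(a$device_type %in% c("CV", "ER/EPRO", "LT")))
  # device size is consistent with device type
  expect_true(all(substr(a$device_size, 1, 2) %in% c("CV", "ER", "LT")))
})

test_that("statistical generation hits its calibration targets at moderate n", {
  co <- sample_cohort_statistical(8000, seed = 4)
  expect_equal(mean(co$ca), 89 / 151, tolerance = 0.03)
  expect_equal(median(co$cpmax[co$ca == 1]), 0.55, tolerance = 0.05)
  expect_equal(median(co$cpi[co$ca == 1]), 28, tolerance = 0.05)
  expect_equal(median(co$cpi[co$ca == 0]), 10, tolerance = 0.08)
  expect_equal(mean(co$doi[co$ca == 1]), 7.30, tolerance = 0.03)
  expect_equal(mean(co$ibms_length[co$ca == 0]), 10.09, tolerance = 0.03)
  # device frequencies per group
  f_ca <- prop.table(table(co$device_type[co$ca == 1]))
  expect_equal(unname(f_ca["LT"]), 30 / 89, tolerance = 0.05)
})

test_that("the default calibration clears the Bayes-achievable AUC floor", {
  expect_gte(bayes_auc(n = 50000, seed = 1), 0.84)
})

test_that("the categorical fixture reproduces the published counts exactly", {
  fx <- fixture_cohort_from_table1()
  expect_equal(nrow(fx), 151)
  expect_equal(sum(fx$ca), 89)
  expect_equal(sum(fx$ppi), 32)
  expect_equal(sum(fx$lbbb_rbbb), 79)            # 78 LBBB + 1 RBBB
  expect_identical(fx$ca, as.integer(fx$lbbb_rbbb | fx$ppi))
  tab <- table(fx$device_type, fx$ca)
  expect_equal(unname(tab[, "1"]), c(50, 9, 30))
  expect_equal(unname(tab[, "0"]), c(33, 15, 14))
  expect_equal(sum(fx$device_type == "LT" & fx$ca == 1), 30)
  expect_equal(sum(fx$device_type == "LT"), 44)
  # size-level cross-tab, CA column
  expect_equal(sum(fx$device_size == "LT 27" & fx$ca == 1), 13)
  # PPI-exclusion filter for the L/RBBB sub-cohort
  expect_equal(sum(fx$ppi == 0), 119)
})

test_that("calibration_report summarises groups and degenerate cohorts", {
  fx <- fixture_cohort_from_table1()
  rep <- calibration_report(fx)
  prev <- rep$prevalence
  expect_equal(prev$prevalence[prev$outcome == "ca"], 89 / 151)
  expect_equal(round(100 * prev$prevalence[prev$outcome == "ca"], 1), 58.9)
  # degenerate cohort: identical rows -> zero SD everywhere
  dg <- fx[rep(1, 10), ]
  rep2 <- calibration_report(dg)
  expect_true(all(rep2$numeric_summary$sd == 0))
  ns <- rep$numeric_summary
  expect_equal(ns$median[ns$variable == "cpmax" & ns$group == "ca"], 0.55)
})

test_that("mechanistic generation produces valid records deterministically", {
  co <- sample_cohort_mechanistic(40, seed = 21)
  expect_equal(nrow(co), 40)
  expect_true(all(co$cpi >= 0 & co$cpi <= 100))
  expect_true(all(co$cpmax >= 0))
  expect_identical(co$ca, as.integer(co$lbbb_rbbb | co$ppi))
  expect_identical(co, sample_cohort_mechanistic(40, seed = 21))
  # sizing rule: index within the matrix window when feasible
  expect_true(all(co$sizing_index > 0.8 & co$sizing_index < 1.45))
})

test_that("a null outcome link gives prevalence ~0.59 independent of features", {
  cfg <- mechanistic_config(beta = c(b0 = qlogis(89 / 151), cpmax = 0,
                                     cpi = 0, doi = 0))
  co <- sample_cohort_mechanistic(400, seed = 8, config = cfg)
  expect_true(abs(mean(co$ca) - 89 / 151) < 4 * sqrt(0.59 * 0.41 / 400))
  # and with the default link the CA group has higher median Cpmax
  co2 <- sample_cohort_mechanistic(400, seed = 9)
  expect_gt(median(co2$cpmax[co2$ca == 1]), median(co2$cpmax[co2$ca == 0]))
})
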