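test_that("product-limit estimator matches a hand computation", {
  cohort <- data.frame(pfi_months = c(2, 4, 6, 8, 10), event = 1)
  km <- kaplan_meier(cohort)
  expect_equal(km_eval(km, 6), 0.4)       # 5 subjects, 3rd event
  expect_equal(km_eval(km, 1), 1)
  expect_equal(km_eval(km, 10), 0)
  expect_equal(median_survival(km), 6)
  expect_true(all(diff(km$surv) <= 0))
})

test_that("censoring reduces risk sets without steps", {
  all_censored <- data.frame(pfi_months = c(1, 5, 9), event = 0)
  km <- kaplan_meier(all_censored)
  expect_true(all(km$surv == 1))
  expect_true(is.na(median_survival(km)))
  single <- kaplan_meier(data.frame(pfi_months = 4, event = 1))
  expect_equal(km_eval(single, c(3.9, 4)), c(1, 0))
  # hand-mixed case: censoring between events
  mixed <- kaplan_meier(data.frame(pfi_months = c(2, 3, 5), event = c(1, 0, 1)))
  expect_equal(km_eval(mixed, 2), 2 / 3)
  expect_equal(km_eval(mixed, 5), 2 / 3 * 0)  # 1 at risk at t=5
})

test_that("without censoring the KM curve equals the empirical survival", {
  set.seed(8)
  x <- round(stats::rexp(40, 0.2), 2)
  km <- kaplan_meier(data.frame(pfi_months = x, event = 1))
  grid <- seq(0, max(x), length.out = 50)
  emp <- vapply(grid, function(t) mean(x > t), numeric(1))
  expect_equal(km_eval(km, grid), emp)
  expect_equal(median_survival(km),
               sort(x)[ceiling(length(x) / 2)], tolerance = 1e-9)
})

test_that("log-rank testing behaves at the extremes and is symmetric", {
  a <- data.frame(pfi_months = c(1, 1, 1), event = 1)
  b <- data.frame(pfi_months = c(100, 100, 100), event = 1)
  lr <- logrank_test(a, b)
  expect_lt(lr$p, 0.05)
  lr_swap <- logrank_test(b, a)
  expect_equal(lr$statistic, lr_swap$statistic)
  same <- data.frame(pfi_months = c(3, 6, 9), event = 1)
  lr0 <- logrank_test(same, same)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-9)
})

test_that("KM-RMSE measures curve discrepancy on the grid", {
  c1 <- kaplan_meier(data.frame(pfi_months = c(2, 4, 6, 8), event = 1))
  grid <- 0:8
  expect_equal(km_rmse(c1, c1, grid), 0)
  # maximal discrepancy: S=1 vs S=0 everywhere on the grid
  top <- kaplan_meier(data.frame(pfi_months = 100, event = 0))
  bottom <- kaplan_meier(data.frame(pfi_months = 1e-9, event = 1))
  expect_equal(km_rmse(top, bottom, 1:10), 1)
  # constant offset of 0.1
  s1 <- structure(data.frame(time = 0, surv = 0.9), class = c("vct_km", "data.frame"))
  s2 <- structure(data.frame(time = 0, surv = 0.8), class = c("vct_km", "data.frame"))
  expect_equal(km_rmse(s1, s2, 1:5), 0.1)
  expect_error(km_rmse(c1, c1, numeric(0)), "empty")
})

test_that("synthetic cohorts hit the requested median and censoring", {
  cohort <- generate_synthetic_cohort(10000, 6, seed = 123)
  expect_gt(stats::median(cohort$pfi_months), 5.7)
  expect_lt(stats::median(cohort$pfi_months), 6.3)
  expect_true(all(cohort$event == 1))
  again <- generate_synthetic_cohort(10000, 6, seed = 123)
  expect_identical(cohort, again)
  cens <- generate_synthetic_cohort(1000, 6, censor_fraction = 0.3,
                                    seed = 5)
  expect_equal(sum(cens$event == 0), 300)
  expect_true(all(cens$pfi_months >= 0))
})

test_that("cohort CSV files round-trip", {
  cohort <- generate_synthetic_cohort(50, 7, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  back <- read_cohort(f)
  expect_equal(back, cohort, tolerance = 1e-12)
  expect_error(suppressWarnings(read_cohort(tempfile())),
               "cannot open|No such")
})

test_that("a single-point grid is returned as the calibration optimum", {
  p <- scaled_params()
  cohort <- generate_synthetic_cohort(100, 6, seed = 3)
  grid <- grid_spec(u = 1e-5, alpha1 = 0.02, alpha2 = 0.01,
                    n_patients = 10)
  spec <- cohort_spec(10, p, base_seed = 4)
  cal <- calibrate_grid(cohort, grid, spec)
  expect_equal(unname(cal$best), c(1e-5, 0.02, 0.01))
  expect_equal(nrow(cal$rmse_table), 1)
  expect_gte(cal$best_rmse, 0)
})

test_that("grid specs validate their ranges and skip invalid weight orderings", {
  expect_error(grid_spec(u = 1e-3, alpha1 = 0.1, alpha2 = 0.1),
               "u")
  expect_error(grid_spec(u = 1e-5, alpha1 = 2, alpha2 = 0.1))
  p <- scaled_params()
  cohort <- generate_synthetic_cohort(50, 6, seed = 3)
  grid <- grid_spec(u = 1e-5, alpha1 = c(0.02, 0.3),
                    alpha2 = c(0.01, 0.25), n_patients = 5)
  cal <- calibrate_grid(cohort, grid, cohort_spec(5, p, 4))
  tab <- cal$rmse_table
  expect_true(all(is.na(tab$rmse[tab$alpha2 > tab$alpha1])))
  expect_true(all(!is.na(tab$rmse[tab$alpha2 <= tab$alpha1])))
})
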