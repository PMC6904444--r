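test_that("patient sampling is mean-correct, clamped and prefix-stable", {
  p <- model_parameters()
  spec <- cohort_spec(n_per_arm = 10, params = p, base_seed = 42)
  # degenerate spread: every patient identical
  p0 <- model_parameters(sigma_log_M = 0, sigma_log_dchemo = 0)
  pat0 <- sample_patient(cohort_spec(5, p0, 1), 3)
  expect_equal(pat0$M_diagnosis, 3.959e11)
  expect_equal(pat0$d_chemo, 0.856)
  # arithmetic-mean parameterization of the log-normal
  n <- 4000
  draws <- vapply(seq_len(n), function(i)
    sample_patient(spec, i)$M_diagnosis, numeric(1))
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - 3.959e11), 3 * se)
  dch <- vapply(1:500, function(i) sample_patient(spec, i)$d_chemo,
                numeric(1))
  expect_true(all(dch < 1))
  # substreams are prefix-stable and patients reproducible
  expect_identical(sample_patient(spec, 7), sample_patient(spec, 7))
  s10 <- vctsim:::.patient_seeds(42, 10)
  s50 <- vctsim:::.patient_seeds(42, 50)
  expect_identical(s10$sampling, s50$sampling[1:10])
  expect_identical(s10$simulation, s50$simulation[1:10])
})

test_that("dominant mechanism is the largest per-mechanism cell tally", {
  expect_equal(dominant_mechanism(
    tumor_state(c("100" = 100, "010" = 50, "001" = 10))), "pre")
  expect_equal(dominant_mechanism(
    tumor_state(c("010" = 1000, "100" = 10))), "on")
  # carriers are counted across genotypes: "110" counts for pre and on
  expect_equal(dominant_mechanism(
    tumor_state(c("110" = 60, "001" = 100))), "post")
  # three-way tie on "111" only, and the no-resistance fallback
  expect_equal(dominant_mechanism(tumor_state(c("111" = 5))), "pre")
  expect_equal(dominant_mechanism(tumor_state(c("000" = 5))), "pre")
})

test_that("an RCTS is reproducible with coherent bookkeeping", {
  p <- scaled_params()
  spec <- cohort_spec(n_per_arm = 15, params = p, base_seed = 77)
  arms <- list(soc = regimen(),
               wee1 = regimen(drugs = default_drug_registry()$wee1))
  tr <- run_rcts(spec, arms)
  expect_equal(as.vector(table(tr$outcomes$arm)), c(15, 15))
  s <- summary(tr)
  expect_equal(s$burden_ratio[s$arm == "soc"], 1)
  # trial-level monotonicity needs paired patients: same base seed,
  # regimen with vs without the drug
  paired_soc <- vctsim:::.simulate_cohort(15, p, regimen(), "hybrid",
                                          base_seed = 101)
  paired_wee <- vctsim:::.simulate_cohort(
    15, p, regimen(drugs = default_drug_registry()$wee1), "hybrid",
    base_seed = 101)
  expect_lt(mean(paired_wee$burden_post), mean(paired_soc$burden_post))
  # KM median equals the direct sorted median when nothing is censored
  soc <- tr$outcomes[tr$outcomes$arm == "soc", ]
  if (all(soc$event == 1)) {
    expect_equal(s$median_pfi[s$arm == "soc"],
                 sort(soc$pfi_months)[ceiling(nrow(soc) / 2)])
  }
  tr2 <- run_rcts(spec, arms)
  expect_identical(tr$outcomes, tr2$outcomes)
  # identical regimens on the same seed give a null log-rank test
  tr3 <- run_rcts(spec, list(a = regimen(), b = regimen()))
  a <- tr3$outcomes[tr3$outcomes$arm == "a", ]
  b <- tr3$outcomes[tr3$outcomes$arm == "b", ]
  # arms draw independent patients, so only the reference ratio is exact
  expect_equal(tr3$summary$burden_ratio[1], 1)
  expect_s3_class(tr3, "vct_trial")
})

test_that("MSCTS stratification partitions patients and fills both arms", {
  p <- scaled_params()
  spec <- cohort_spec(n_per_arm = 12, params = p, base_seed = 13)
  wee1 <- default_drug_registry()$wee1
  tr <- run_mscts(spec, wee1)
  expect_equal(sum(tr$outcomes$arm == "positive"), 12)
  expect_equal(sum(tr$outcomes$arm == "negative"), 12)
  expect_equal(anyDuplicated(tr$outcomes$patient), 0L)
  expect_true(all(tr$outcomes$dominant[tr$outcomes$arm == "positive"]
                  == "on"))
  expect_true(all(tr$outcomes$dominant[tr$outcomes$arm == "negative"]
                  != "on"))
  expect_true(is.finite(tr$relative_benefit))
  # pool mode: one cohort split by biomarker
  trp <- run_mscts(spec, wee1, mode = "pool")
  expect_equal(nrow(trp$outcomes), 12)
  expect_equal(anyDuplicated(trp$outcomes$patient), 0L)
})

test_that("an ineffective drug is exactly equivalent to chemotherapy alone", {
  # E = 0 leaves the kill map untouched, so for a fixed patient seed
  # the whole simulation path is identical with or without the drug
  p <- scaled_params()
  null_drug <- drug("placebo", "on", E = 0)
  expect_equal(build_kill_map(p, 0.856, null_drug),
               build_kill_map(p, 0.856))
  for (seed in c(2, 9)) {
    pat <- virtual_patient(M_diagnosis = 1e6, seed = seed)
    a <- simulate_patient(pat, regimen(), p, "hybrid")
    b <- simulate_patient(pat, regimen(drugs = null_drug), p, "hybrid")
    expect_identical(a$pfi, b$pfi)
    expect_identical(a$state$counts, b$state$counts)
  }
  # consequently the stratification benefit is pure biomarker
  # prognosis: small relative to the cohort's PFI spread
  spec <- cohort_spec(n_per_arm = 40, params = p, base_seed = 19)
  tr <- run_mscts(spec, null_drug)
  spread <- stats::sd(tr$outcomes$pfi_months)
  expect_lt(abs(tr$relative_benefit), spread)
})

test_that("burden calibration rescales the drug effect toward a target", {
  p <- scaled_params()
  spec <- cohort_spec(n_per_arm = 25, params = p, base_seed = 31)
  wee1 <- default_drug_registry()$wee1
  cal <- calibrate_drug_effect(wee1, 0.10, spec, tol = 0.02)
  info <- attr(cal, "calibration")
  expect_true(info$attainable)
  expect_lt(abs(info$achieved - 0.10), 0.03)
  expect_true(cal$E >= 0 && cal$E <= 1)
  # a reduction beyond the target compartment's share is unattainable
  expect_warning(
    cal2 <- calibrate_drug_effect(wee1, 0.98, spec, tol = 0.02),
    "unattainable")
  expect_false(attr(cal2, "calibration")$attainable)
  expect_equal(cal2$E, 1)
})
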