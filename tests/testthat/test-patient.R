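test_that("deterministic pre-treatment stop time matches ln(M)/(b-d)", {
  p <- model_parameters(u = 0)
  dx <- simulate_pretreatment(virtual_patient(), p, "deterministic")
  expect_equal(dx$time, log(3.959e11) / 0.006, tolerance = 1e-6)
  expect_gte(total_burden(dx), 3.959e11)
  expect_lt(total_burden(dx), 3.959e11 * 1.001)
})

test_that("stochastic pre-treatment reaches the diagnosis burden", {
  p <- scaled_params()
  set.seed(21)
  dx <- simulate_pretreatment(virtual_patient(M_diagnosis = 1e6), p,
                              "hybrid")
  expect_gte(total_burden(dx), 1e6)
  # stopping bracket: at most one e-fold of overshoot per max chunk
  expect_lt(total_burden(dx), 1e6 * exp(1))
  expect_gte(attr(dx, "resamples"), 0)
  # mostly sensitive at diagnosis, but mutants present on average
  set.seed(22)
  fr <- replicate(30, {
    dx <- simulate_pretreatment(virtual_patient(M_diagnosis = 1e6), p,
                                "hybrid")
    1 - dx$counts[["000"]] / total_burden(dx)
  })
  expect_gt(mean(fr), 0)
  expect_lt(mean(fr), 0.5)
})

test_that("seeded start approximates the resampled conditioning", {
  p <- scaled_params()
  set.seed(31)
  m_res <- mean(replicate(40, total_burden(
    simulate_pretreatment(virtual_patient(M_diagnosis = 1e6), p,
                          "hybrid", start = "resample"))))
  m_seed <- mean(replicate(40, total_burden(
    simulate_pretreatment(virtual_patient(M_diagnosis = 1e6), p,
                          "hybrid", start = "seeded"))))
  expect_equal(m_res / m_seed, 1, tolerance = 0.25)
})

test_that("treatment phase follows the closed-form pulse product when u = 0", {
  p <- model_parameters(u = 0)
  pat <- virtual_patient(d_chemo = 0.856)
  dx <- simulate_pretreatment(pat, p, "deterministic")
  M <- total_burden(dx)
  out <- run_treatment(dx, pat, regimen(), p, "deterministic")
  # 6 pulses (survival 0.144 each), one 2-log surgery, 6 x 21 days of
  # regrowth between events
  expected <- M * (1 - 0.856)^6 * 1e-2 * exp(0.006 * 126)
  expect_equal(total_burden(out), expected, tolerance = 1e-9)
  expect_equal(attr(out, "last_platinum_time"), dx$time + 126)
})

test_that("an empty regimen is the identity and pulses spare resistant cells", {
  p <- model_parameters(u = 0)
  pat <- virtual_patient()
  s <- tumor_state(c("000" = 1e8, "111" = 1e5), time = 100)
  out <- run_treatment(s, pat, regimen(n_nact = 0, surgery = FALSE,
                                       n_adj = 0), p, "deterministic")
  expect_equal(out$counts, s$counts)
  # fully resistant cells are only reduced by surgery, never by pulses
  out2 <- run_treatment(s, pat, regimen(), p, "deterministic")
  expect_equal(out2$counts[["111"]],
               1e5 * 1e-2 * exp(0.006 * 126), tolerance = 1e-9)
})

test_that("relapse timing matches the closed-form regrowth when u = 0", {
  p <- model_parameters(u = 0)
  s <- tumor_state(c("000" = 2.4e8), time = 1000)
  attr(s, "last_platinum_time") <- 1000
  out <- simulate_to_relapse(s, p, "deterministic")
  expect_equal(out$pfi, log(1e9 / 2.4e8) / 0.006 / 30.44,
               tolerance = 1e-4)  # ~ 7.8 months
  expect_equal(out$event, 1L)
  # immediate progression
  s2 <- tumor_state(c("010" = 2e9), time = 50)
  attr(s2, "last_platinum_time") <- 50
  out2 <- simulate_to_relapse(s2, p, "deterministic")
  expect_equal(out2$pfi, 0)
  expect_equal(out2$event, 1L)
  # cure under the model: censored at the follow-up cap
  s3 <- tumor_state(c("000" = 0), time = 50)
  attr(s3, "last_platinum_time") <- 50
  out3 <- simulate_to_relapse(s3, p, "deterministic")
  expect_equal(out3$event, 0L)
  expect_equal(out3$pfi, p$followup_cap_days / 30.44)
})

test_that("a patient simulation is reproducible from its seed", {
  p <- scaled_params()
  pat <- virtual_patient(M_diagnosis = 1e6, d_chemo = 0.856, seed = 99)
  a <- simulate_patient(pat, regimen(), p, "hybrid")
  b <- simulate_patient(pat, regimen(), p, "hybrid")
  expect_identical(a$pfi, b$pfi)
  expect_identical(a$burden_post_treatment, b$burden_post_treatment)
  expect_identical(a$state$counts, b$state$counts)
  expect_true(a$pfi >= 0)
})

test_that("adding a drug never worsens the residual burden", {
  wee1 <- default_drug_registry()$wee1
  # deterministic engine: kill-map monotonicity holds path by path
  p_det <- model_parameters()
  pat <- virtual_patient()
  dx <- simulate_pretreatment(pat, p_det, "deterministic")
  soc <- run_treatment(dx, pat, regimen(), p_det, "deterministic")
  combo <- run_treatment(dx, pat, regimen(drugs = wee1), p_det,
                         "deterministic")
  expect_lt(total_burden(combo), total_burden(soc))
  # stochastic engine: monotone in aggregate over seeded patients
  # (per-path comparisons diverge once binomial draws differ)
  p <- scaled_params()
  res <- vapply(1:30, function(seed) {
    pat <- virtual_patient(M_diagnosis = 1e6, seed = seed)
    c(soc = simulate_patient(pat, regimen(), p,
                             "hybrid")$burden_post_treatment,
      combo = simulate_patient(pat, regimen(drugs = wee1), p,
                               "hybrid")$burden_post_treatment)
  }, numeric(2))
  expect_lt(mean(res["combo", ]), mean(res["soc", ]))
})

test_that("the trajectory export is tidy and phase-labelled", {
  p <- scaled_params()
  pat <- virtual_patient(M_diagnosis = 1e6, seed = 5)
  out <- simulate_patient(pat, regimen(), p, "hybrid",
                          trajectory = TRUE)
  tr <- out$trajectory
  expect_equal(names(tr), c("time_days", "genotype", "count", "phase"))
  expect_setequal(unique(tr$phase),
                  c("pre", "nact", "surgery", "adj", "post"))
  expect_equal(sum(tr$phase == "nact"), 3 * 8)
  expect_true(all(tr$count >= 0))
  # composition fractions sum to 1 at every recorded time point
  for (tp in unique(tr$time_days)) {
    sub <- tr[tr$time_days == tp, ]
    if (sum(sub$count) > 0) {
      st <- tumor_state(stats::setNames(sub$count, sub$genotype))
      expect_equal(sum(composition(st)), 1)
    }
  }
})
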