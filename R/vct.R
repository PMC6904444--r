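# Virtual clinical trials: randomized (RCTS) and molecularly
# stratified (MSCTS) designs over cohorts of sampled virtual patients.

#' Cohort specification for a virtual trial
#'
#' @param n_per_arm Patients per trial arm.
#' @param params [model_parameters()] shared by all patients; the
#'   per-patient diagnosis burden and chemotherapy effect are sampled
#'   log-normally around `M_diagnosis_mean` and `d_chemotherapy_mean`
#'   with log-scale spreads `sigma_log_M` and `sigma_log_dchemo`.
#' @param base_seed Integer seed from which all per-patient substreams
#'   are derived.
#' @return Object of class `vct_cohort_spec`.
#' @examples
#' cohort_spec(n_per_arm = 10, base_seed = 1)
#' @export
cohort_spec <- function(n_per_arm = 1000,
                        params = model_parameters(),
                        base_seed = 1) {
  stopifnot(n_per_arm >= 1, inherits(params, "vct_params"))
  structure(list(n_per_arm = n_per_arm, params = params,
                 base_seed = as.integer(base_seed)),
            class = "vct_cohort_spec")
}

# Per-patient seed substreams: a single base seed spawns, for patient
# i, one seed for parameter sampling and one for the simulation.
# Draws are interleaved so the streams are prefix-stable: enlarging a
# cohort never reshuffles existing patients.
.patient_seeds <- function(base_seed, n) {
  set.seed(base_seed)
  s <- sample.int(.Machine$integer.max, 2 * n, replace = TRUE)
  list(sampling = s[seq(1, 2 * n, by = 2)],
       simulation = s[seq(2, 2 * n, by = 2)])
}

#' Sample one virtual patient from a cohort specification
#'
#' The diagnosis burden is log-normal with arithmetic mean
#' `M_diagnosis_mean` and log-sd `sigma_log_M`; the per-cycle
#' chemotherapy effect is log-normal with arithmetic mean
#' `d_chemotherapy_mean` and log-sd `sigma_log_dchemo`, clamped below
#' 1. Deterministic given `(base_seed, index)`.
#'
#' @param spec A [cohort_spec()].
#' @param index Patient index (1-based).
#' @return A [virtual_patient()].
#' @export
sample_patient <- function(spec, index) {
  stopifnot(inherits(spec, "vct_cohort_spec"), index >= 1)
  seeds <- .patient_seeds(spec$base_seed, index)
  p <- spec$params
  set.seed(seeds$sampling[index])
  lnorm_mean <- function(m, sigma) {
    if (sigma == 0) m else stats::rlnorm(1, log(m) - sigma^2 / 2, sigma)
  }
  M <- lnorm_mean(p$M_diagnosis_mean, p$sigma_log_M)
  dch <- min(lnorm_mean(p$d_chemotherapy_mean, p$sigma_log_dchemo),
             1 - 1e-12)
  virtual_patient(M_diagnosis = M, d_chemo = dch,
                  seed = seeds$simulation[index])
}

#' Dominant resistance mechanism of a tumor
#'
#' The biomarker used to stratify MSCTS arms: for each mechanism, the
#' score is the total number of cells carrying it (active bit),
#' regardless of the other bits; the dominant mechanism is the argmax,
#' with ties broken in fixed `(pre, on, post)` order. A tumor with no
#' resistant cells is assigned `"pre"` by the same tie-break.
#'
#' @param state A [tumor_state()].
#' @return One of `"pre"`, `"on"`, `"post"`.
#' @examples
#' dominant_mechanism(tumor_state(c("010" = 1000, "100" = 10)))
#' @export
dominant_mechanism <- function(state) {
  scores <- as.numeric(state$counts %*% .genotype_bits)
  .mechanisms[which.max(scores)]
}

# Simulate n patients under one regimen; returns a per-patient data
# frame. Patient i is fully determined by (base_seed, i).
.simulate_cohort <- function(n, params, reg, engine, base_seed,
                             start = "resample") {
  spec <- cohort_spec(n_per_arm = n, params = params,
                      base_seed = base_seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- sample_patient(spec, i)
    out <- simulate_patient(pat, reg, params, engine, start)
    rows[[i]] <- data.frame(
      patient = i, seed = pat$seed, M_diagnosis = pat$M_diagnosis,
      d_chemo = pat$d_chemo, pfi_months = out$pfi, event = out$event,
      burden_post = out$burden_post_treatment,
      frac_sensitive = out$composition_post_treatment[["sensitive"]],
      frac_partial = out$composition_post_treatment[["partial"]],
      frac_full = out$composition_post_treatment[["full"]],
      dominant = out$dominant
    )
  }
  do.call(rbind, rows)
}

.arm_summary <- function(df) {
  km <- kaplan_meier(df)
  data.frame(
    n = nrow(df),
    median_pfi = median_survival(km),
    events = sum(df$event),
    mean_burden_post = mean(df$burden_post),
    mean_frac_sensitive = mean(df$frac_sensitive, na.rm = TRUE),
    mean_frac_partial = mean(df$frac_partial, na.rm = TRUE),
    mean_frac_full = mean(df$frac_full, na.rm = TRUE)
  )
}

.make_trial <- function(type, outcomes, spec, reference_arm) {
  arms <- unique(outcomes$arm)
  summaries <- do.call(rbind, lapply(arms, function(a) {
    cbind(arm = a, .arm_summary(outcomes[outcomes$arm == a, ]))
  }))
  ref <- summaries$mean_burden_post[summaries$arm == reference_arm]
  summaries$burden_ratio <- summaries$mean_burden_post / ref
  pairs <- if (length(arms) > 1) {
    combs <- utils::combn(arms, 2, simplify = FALSE)
    do.call(rbind, lapply(combs, function(pr) {
      lr <- logrank_test(outcomes[outcomes$arm == pr[1], ],
                         outcomes[outcomes$arm == pr[2], ])
      data.frame(arm_a = pr[1], arm_b = pr[2],
                 statistic = lr$statistic, p = lr$p)
    }))
  } else NULL
  structure(list(type = type, outcomes = outcomes,
                 summary = summaries, logrank = pairs,
                 reference_arm = reference_arm, spec = spec),
            class = "vct_trial")
}

#' Run a randomized controlled trial simulation (RCTS)
#'
#' Simulates `n_per_arm` independent virtual patients per arm (each arm
#' draws its own patients, as in a randomized trial) and summarizes
#' per-arm Kaplan-Meier curves, median PFI, mean post-treatment burden
#' and composition, the burden ratio versus the reference arm, and
#' pairwise log-rank tests.
#'
#' @param spec A [cohort_spec()].
#' @param arms Named list of [regimen()]s; the first arm is the
#'   chemotherapy-alone reference.
#' @param engine Simulation engine.
#' @param start Pre-treatment conditioning mode, see
#'   [simulate_pretreatment()].
#' @return A `vct_trial` object; see [summary.vct_trial()].
#' @examples
#' \donttest{
#' pars <- model_parameters(M_diagnosis_mean = 1e9, M_relapse = 1e7)
#' spec <- cohort_spec(n_per_arm = 5, params = pars, base_seed = 7)
#' run_rcts(spec, list(soc = regimen(),
#'                     wee1 = regimen(drugs = default_drug_registry()$wee1)))
#' }
#' @export
run_rcts <- function(spec, arms, engine = c("hybrid", "exact",
                                            "deterministic"),
                     start = "resample") {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "vct_cohort_spec"), length(arms) >= 1)
  if (is.null(names(arms)) || any(names(arms) == "")) {
    names(arms) <- paste0("arm", seq_along(arms))
  }
  set.seed(spec$base_seed)
  arm_seeds <- sample.int(.Machine$integer.max, length(arms),
                          replace = TRUE)
  outcomes <- do.call(rbind, lapply(seq_along(arms), function(a) {
    df <- .simulate_cohort(spec$n_per_arm, spec$params, arms[[a]],
                           engine, base_seed = arm_seeds[a],
                           start = start)
    cbind(arm = names(arms)[a], df)
  }))
  .make_trial("rcts", outcomes, spec, reference_arm = names(arms)[1])
}

#' Run a molecularly stratified controlled trial simulation (MSCTS)
#'
#' Patients are classified at diagnosis by an ideal biomarker (100%
#' sensitivity and specificity) for their dominant resistance
#' mechanism. The biomarker-positive arm holds patients whose dominant
#' mechanism equals the drug's target; all other patients are
#' biomarker-negative. Both arms receive chemotherapy plus the drug.
#'
#' @param spec A [cohort_spec()].
#' @param dr The targeted [drug()] under study.
#' @param engine Simulation engine.
#' @param mode `"fill"`: keep sampling patients until both arms hold
#'   `n_per_arm` (patients arriving after their arm is full are
#'   discarded); `"pool"`: sample exactly `n_per_arm` patients and
#'   split them by biomarker, giving unequal arms.
#' @param start Pre-treatment conditioning mode.
#' @param max_draws Safety cap on sampled patients in `"fill"` mode.
#' @return A `vct_trial` with arms `positive` and `negative` and a
#'   `relative_benefit` element (median PFI difference in months,
#'   positive minus negative).
#' @export
run_mscts <- function(spec, dr, engine = c("hybrid", "exact",
                                           "deterministic"),
                      mode = c("fill", "pool"), start = "resample",
                      max_draws = NULL) {
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "vct_cohort_spec"), inherits(dr, "vct_drug"))
  n <- spec$n_per_arm
  if (is.null(max_draws)) max_draws <- 50 * n
  reg <- regimen(drugs = list(dr))
  seeds <- NULL
  rows <- list()
  counts <- c(positive = 0L, negative = 0L)
  i <- 0L
  done <- function() {
    if (mode == "pool") i >= n else all(counts >= n)
  }
  while (!done()) {
    i <- i + 1L
    if (i > max_draws) {
      warning("MSCTS arm(s) not filled after ", max_draws,
              " sampled patients")
      break
    }
    pat <- sample_patient(spec, i)
    set.seed(pat$seed)
    dx <- simulate_pretreatment(pat, spec$params, engine, start)
    arm <- if (dominant_mechanism(dx) == dr$target) "positive"
           else "negative"
    if (mode == "fill" && counts[[arm]] >= n) next
    post <- run_treatment(dx, pat, reg, spec$params, engine)
    out <- simulate_to_relapse(post, spec$params, engine)
    counts[[arm]] <- counts[[arm]] + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm, patient = i, seed = pat$seed,
      M_diagnosis = pat$M_diagnosis, d_chemo = pat$d_chemo,
      pfi_months = out$pfi, event = out$event,
      burden_post = out$burden_post_treatment,
      frac_sensitive = out$composition_post_treatment[["sensitive"]],
      frac_partial = out$composition_post_treatment[["partial"]],
      frac_full = out$composition_post_treatment[["full"]],
      dominant = dominant_mechanism(dx)
    )
  }
  outcomes <- do.call(rbind, rows)
  if (is.null(outcomes) || !any(outcomes$arm == "positive")) {
    stop("MSCTS: no biomarker-positive patients for target '",
         dr$target, "'", call. = FALSE)
  }
  trial <- .make_trial("mscts", outcomes, spec,
                       reference_arm = "negative")
  med <- function(a) median_survival(
    kaplan_meier(outcomes[outcomes$arm == a, ]))
  trial$drug <- dr
  trial$relative_benefit <- med("positive") - med("negative")
  trial
}

#' @export
print.vct_trial <- function(x, ...) {
  cat(sprintf("Virtual clinical trial (%s), %d arm(s)\n",
              toupper(x$type), nrow(x$summary)))
  print(summary(x), ...)
  invisible(x)
}

#' Summarize a virtual trial
#'
#' @param object A `vct_trial` from [run_rcts()] or [run_mscts()].
#' @param ... Unused.
#' @return The per-arm summary data frame: cohort size, KM median PFI
#'   (months), number of events, mean post-treatment burden and its
#'   ratio to the reference arm, and mean residual composition.
#' @export
summary.vct_trial <- function(object, ...) {
  s <- object$summary
  s[, c("arm", "n", "median_pfi", "events", "mean_burden_post",
        "burden_ratio", "mean_frac_sensitive", "mean_frac_partial",
        "mean_frac_full")]
}

#' Plot the Kaplan-Meier curves of a virtual trial
#'
#' @param x A `vct_trial`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.vct_trial <- function(x, ...) {
  arms <- unique(x$outcomes$arm)
  cols <- seq_along(arms) + 1
  xmax <- max(x$outcomes$pfi_months)
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "PFI (months)", ylab = "Survival", ...)
  for (a in seq_along(arms)) {
    km <- kaplan_meier(x$outcomes[x$outcomes$arm == arms[a], ])
    graphics::lines(stats::stepfun(km$time[-1], km$surv),
                    col = cols[a], do.points = FALSE)
  }
  graphics::legend("topright", legend = arms, col = cols, lty = 1)
  invisible(x)
}
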