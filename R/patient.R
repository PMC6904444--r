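# One virtual patient through the three phases of first-line therapy:
# pre-treatment growth from a single sensitive cell to the diagnosis
# burden, the NACT / interval-debulking-surgery / adjuvant treatment
# phase with pulsed chemotherapy, and post-treatment regrowth until
# relapse. The platinum-free interval (PFI) is measured from the last
# platinum pulse to the time the burden re-reaches M_relapse.

#' Define a virtual patient
#'
#' @param M_diagnosis Tumor burden at diagnosis for this patient
#'   (cells).
#' @param d_chemo Per-cycle chemotherapy kill fraction on sensitive
#'   cells for this patient, in `[0, 1]`.
#' @param seed Integer seed making the patient's simulation
#'   reproducible, or `NULL` to use the current RNG stream.
#' @return An object of class `vct_patient`.
#' @examples
#' virtual_patient(seed = 1)
#' @export
virtual_patient <- function(M_diagnosis = 3.959e11, d_chemo = 0.856,
                            seed = NULL) {
  stopifnot(M_diagnosis > 0, d_chemo >= 0, d_chemo <= 1)
  structure(list(M_diagnosis = M_diagnosis, d_chemo = d_chemo,
                 seed = seed), class = "vct_patient")
}

#' Define a treatment regimen
#'
#' The standard of care is three cycles of neoadjuvant chemotherapy
#' (NACT), interval debulking surgery (IDS) and three adjuvant (ADJ)
#' cycles, with consecutive events separated by one cycle interval.
#' Targeted drugs are co-administered at every chemotherapy pulse.
#'
#' @param n_nact,n_adj Numbers of neoadjuvant and adjuvant chemotherapy
#'   cycles.
#' @param surgery Logical; include interval debulking surgery.
#' @param beta Surgical cell-log kill; `NULL` uses the model parameter.
#' @param drugs Targeted drugs co-administered with chemotherapy (a
#'   [drug()], a list of drugs with distinct targets, or `NULL`).
#' @param cycle_interval Days between events; `NULL` uses the model
#'   parameter.
#' @return An object of class `vct_regimen`.
#' @examples
#' soc_regimen <- regimen()
#' wee1_regimen <- regimen(drugs = default_drug_registry()$wee1)
#' @export
regimen <- function(n_nact = 3, surgery = TRUE, beta = NULL,
                    n_adj = 3, drugs = NULL, cycle_interval = NULL) {
  stopifnot(n_nact >= 0, n_adj >= 0)
  structure(list(n_nact = n_nact, surgery = isTRUE(surgery),
                 beta = beta, n_adj = n_adj,
                 drugs = .as_drug_list(drugs),
                 cycle_interval = cycle_interval),
            class = "vct_regimen")
}

#' Simulate the pre-treatment phase
#'
#' Grows the tumor from a single sensitive cell until the total burden
#' first reaches the patient's diagnosis burden. Stochastic engines
#' condition on non-extinction: by default extinct runs are resampled
#' (the extinction probability from one cell is `d/b`, about 0.99 at
#' the default rates); `start = "seeded"` instead starts the growth
#' deterministically at `b/(b - d)` cells, the mean size of a surviving
#' lineage, which is faster and asymptotically equivalent.
#'
#' @param patient A [virtual_patient()].
#' @param params [model_parameters()].
#' @param engine Simulation engine, see [simulate_interval()].
#' @param start `"resample"` or `"seeded"` (stochastic engines only).
#' @param max_resamples Cap on extinction resamples before erroring.
#' @return The diagnosis [tumor_state()]; its `time` is the age of the
#'   tumor in days. Attribute `"resamples"` counts discarded extinct
#'   runs.
#' @export
simulate_pretreatment <- function(patient, params,
                                  engine = c("hybrid", "exact",
                                             "deterministic"),
                                  start = c("resample", "seeded"),
                                  max_resamples = 10000) {
  engine <- match.arg(engine)
  start <- match.arg(start)
  M <- patient$M_diagnosis
  horizon <- 10 * log(M) / (params$b - params$d)
  resamples <- 0

  if (engine == "deterministic") {
    state <- simulate_interval(tumor_state(c("000" = 1)), horizon,
                               params, engine, stop_total = M)
  } else if (start == "seeded" && engine == "hybrid") {
    p2 <- params
    p2$hybrid_threshold <- 1  # all-deterministic core with lineage flux
    state <- tumor_state(c("000" = params$b / (params$b - params$d)))
    state <- simulate_interval(state, horizon, p2, engine,
                               stop_total = M)
  } else {
    repeat {
      state <- simulate_interval(tumor_state(c("000" = 1)), horizon,
                                 params, engine, stop_total = M)
      if (attr(state, "stopped") == "threshold") break
      resamples <- resamples + 1
      if (resamples >= max_resamples) {
        stop("pre-treatment phase: resample cap reached", call. = FALSE)
      }
    }
  }
  if (attr(state, "stopped") != "threshold") {
    stop("pre-treatment phase did not reach the diagnosis burden",
         call. = FALSE)
  }
  attr(state, "resamples") <- resamples
  state
}

#' Simulate the treatment phase
#'
#' Applies, in order and separated by one cycle interval: `n_nact`
#' chemotherapy pulses, surgery, and `n_adj` chemotherapy pulses. The
#' first pulse is given at the diagnosis time; the returned state is
#' taken immediately after the final event.
#'
#' @param state Diagnosis state from [simulate_pretreatment()].
#' @param patient A [virtual_patient()] (supplies `d_chemo`).
#' @param reg A [regimen()].
#' @param record Logical; record the state after every treatment event
#'   in a tidy trajectory attribute.
#' @inheritParams simulate_pretreatment
#' @return The post-treatment `tumor_state`, with attribute
#'   `"last_platinum_time"` (days; the diagnosis time when the regimen
#'   contains no chemotherapy pulse).
#' @export
run_treatment <- function(state, patient, reg, params,
                          engine = c("hybrid", "exact",
                                     "deterministic"),
                          record = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(reg, "vct_regimen"))
  interval <- reg$cycle_interval
  if (is.null(interval)) interval <- params$cycle_interval_days
  beta <- reg$beta
  if (is.null(beta)) beta <- params$beta_surgery
  killmap <- build_kill_map(params, patient$d_chemo, reg$drugs)
  stochastic <- engine != "deterministic"

  events <- c(rep("nact", reg$n_nact),
              if (reg$surgery) "surgery",
              rep("adj", reg$n_adj))
  last_platinum <- state$time
  traj <- list()
  first <- TRUE
  for (ev in events) {
    if (!first) state <- simulate_interval(state, interval, params,
                                           engine)
    first <- FALSE
    if (ev == "surgery") {
      state <- apply_surgery(state, beta)
    } else {
      state <- apply_pulse(state, killmap, stochastic = stochastic,
                           threshold = params$hybrid_threshold)
      last_platinum <- state$time
    }
    if (record) traj[[length(traj) + 1L]] <- .state_rows(state, ev)
  }
  attr(state, "last_platinum_time") <- last_platinum
  if (record) attr(state, "trajectory") <- do.call(rbind, traj)
  state
}

# tidy trajectory rows for one recorded state
.state_rows <- function(state, phase) {
  data.frame(time_days = state$time, genotype = .genotype_labels,
             count = unname(state$counts), phase = phase)
}

#' Simulate the post-treatment phase until relapse
#'
#' Advances the residual tumor until the total burden reaches
#' `M_relapse` or the follow-up cap. The platinum-free interval (PFI)
#' is the time from the last platinum pulse to relapse, in months
#' (30.44 days per month). A residual burden already at or above
#' `M_relapse` gives `pfi = 0` with an event; an extinct tumor or a
#' capped follow-up gives a censored outcome at the cap.
#'
#' @param state Post-treatment state from [run_treatment()].
#' @inheritParams simulate_pretreatment
#' @param last_platinum_time Time of the last platinum pulse (days);
#'   defaults to the attribute recorded by [run_treatment()].
#' @return An object of class `vct_outcome`: list with `pfi` (months),
#'   `event` (1 relapse, 0 censored), `burden_post_treatment`,
#'   `composition_post_treatment` and the relapse-time `state`.
#' @export
simulate_to_relapse <- function(state, params,
                                engine = c("hybrid", "exact",
                                           "deterministic"),
                                last_platinum_time = NULL) {
  engine <- match.arg(engine)
  if (is.null(last_platinum_time)) {
    last_platinum_time <- attr(state, "last_platinum_time")
  }
  stopifnot(is.numeric(last_platinum_time))
  burden0 <- total_burden(state)
  comp0 <- if (burden0 > 0) composition(state) else
    c(sensitive = NA_real_, partial = NA_real_, full = NA_real_)
  cap_days <- params$followup_cap_days
  cap_months <- cap_days / .days_per_month

  outcome <- function(pfi, event, st) {
    structure(list(pfi = pfi, event = event,
                   burden_post_treatment = burden0,
                   composition_post_treatment = comp0,
                   state = st),
              class = "vct_outcome")
  }

  if (burden0 >= params$M_relapse) return(outcome(0, 1L, state))
  if (burden0 == 0) return(outcome(cap_months, 0L, state))

  deadline <- last_platinum_time + cap_days
  remaining <- deadline - state$time
  if (remaining > 0) {
    state <- simulate_interval(state, remaining, params, engine,
                               stop_total = params$M_relapse)
  }
  if (attr(state, "stopped") == "threshold") {
    pfi <- (state$time - last_platinum_time) / .days_per_month
    outcome(pfi, 1L, state)
  } else {
    outcome(cap_months, 0L, state)
  }
}

#' Simulate one virtual patient end to end
#'
#' Composes the pre-treatment, treatment and post-treatment phases.
#' Given the same seed, parameters and regimen, the outcome is fully
#' reproducible.
#'
#' @inheritParams simulate_pretreatment
#' @param reg A [regimen()].
#' @param trajectory Logical; include a tidy per-phase trajectory
#'   (`time_days`, `genotype`, `count`, `phase` in
#'   pre/nact/surgery/adj/post) in the outcome.
#' @return A `vct_outcome` (see [simulate_to_relapse()]) with
#'   additional fields `dominant` (dominant resistance mechanism at
#'   diagnosis, see [dominant_mechanism()]), `burden_diagnosis` and
#'   `age_at_diagnosis_days`.
#' @examples
#' \donttest{
#' p <- virtual_patient(M_diagnosis = 1e8, seed = 42)
#' pars <- model_parameters(M_diagnosis_mean = 1e8, M_relapse = 1e6)
#' simulate_patient(p, regimen(), pars)
#' }
#' @export
simulate_patient <- function(patient, reg = regimen(),
                             params = model_parameters(),
                             engine = c("hybrid", "exact",
                                        "deterministic"),
                             start = c("resample", "seeded"),
                             trajectory = FALSE) {
  engine <- match.arg(engine)
  start <- match.arg(start)
  if (!is.null(patient$seed)) set.seed(patient$seed)
  dx <- simulate_pretreatment(patient, params, engine, start)
  post <- run_treatment(dx, patient, reg, params, engine,
                        record = trajectory)
  out <- simulate_to_relapse(post, params, engine)
  out$dominant <- dominant_mechanism(dx)
  out$burden_diagnosis <- total_burden(dx)
  out$age_at_diagnosis_days <- dx$time
  if (trajectory) {
    out$trajectory <- rbind(.state_rows(dx, "pre"),
                            attr(post, "trajectory"),
                            .state_rows(out$state, "post"))
  }
  out
}

#' @export
print.vct_outcome <- function(x, ...) {
  cat(sprintf("PFI %.2f months (%s)\n", x$pfi,
              if (x$event == 1) "relapse" else "censored"))
  cat(sprintf("  residual burden %.4g cells; composition S/P/F = %s\n",
              x$burden_post_treatment,
              paste(sprintf("%.1f%%",
                            100 * x$composition_post_treatment),
                    collapse = "/")))
  invisible(x)
}
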