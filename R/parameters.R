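# Model parameterization. Defaults are the standard parameter set for
# advanced HGSOC: slow net growth (b - d = 0.006/day), per-mechanism
# activation probability u per cell division, log-scale chemotherapy
# weights alpha1/alpha2 for partially resistant cells, and a 2-log
# surgical debulking.

.days_per_month <- 30.44

.param_fields <- c(
  "b", "d", "u", "M_diagnosis_mean", "M_relapse", "d_chemotherapy_mean",
  "alpha1", "alpha2", "beta_surgery", "sigma_log_M", "sigma_log_dchemo",
  "cycle_interval_days", "followup_cap_days", "hybrid_threshold"
)

#' Model parameters for the platinum-resistance branching process
#'
#' Constructs and validates the parameter set of the multitype
#' branching-process model. Defaults are the standard values for advanced
#' high-grade serous ovarian cancer.
#'
#' @param b Division rate (1/day).
#' @param d Death rate (1/day); must satisfy `b > d > 0`.
#' @param u Per-mechanism activation probability per cell division.
#' @param M_diagnosis_mean Mean tumor burden at diagnosis (cells).
#' @param M_relapse Tumor burden defining relapse (cells); must be below
#'   `M_diagnosis_mean`.
#' @param d_chemotherapy_mean Mean per-cycle kill fraction of a
#'   chemotherapy pulse on fully sensitive cells, in `[0, 1]`.
#' @param alpha1,alpha2 Dimensionless weights of the chemotherapy effect
#'   on cells with one, respectively two, active resistance mechanisms;
#'   `alpha2 <= alpha1`, both in `[0, 1]`.
#' @param beta_surgery Cell-log kill of debulking surgery (every count is
#'   multiplied by `10^-beta_surgery`).
#' @param sigma_log_M Log-scale spread of the diagnosis burden across
#'   virtual patients.
#' @param sigma_log_dchemo Log-scale spread of the per-patient
#'   chemotherapy effect.
#' @param cycle_interval_days Days between successive treatment events
#'   (chemotherapy cycles, surgery).
#' @param followup_cap_days Post-treatment follow-up cap (days); patients
#'   that have not relapsed by then are censored.
#' @param hybrid_threshold Clone size above which the hybrid engine
#'   tracks a genotype deterministically (cells).
#' @return An object of class `vct_params` (a validated named list).
#' @examples
#' p <- model_parameters()
#' p$b - p$d
#' @export
model_parameters <- function(b = 0.667,
                             d = 0.661,
                             u = 1e-5,
                             M_diagnosis_mean = 3.959e11,
                             M_relapse = 1e9,
                             d_chemotherapy_mean = 0.856,
                             alpha1 = 0.02,
                             alpha2 = 0.01,
                             beta_surgery = 2,
                             sigma_log_M = 0.5,
                             sigma_log_dchemo = 0.1,
                             cycle_interval_days = 21,
                             followup_cap_days = 3653,
                             hybrid_threshold = 1e4) {
  p <- list(
    b = b, d = d, u = u,
    M_diagnosis_mean = M_diagnosis_mean,
    M_relapse = M_relapse,
    d_chemotherapy_mean = d_chemotherapy_mean,
    alpha1 = alpha1, alpha2 = alpha2,
    beta_surgery = beta_surgery,
    sigma_log_M = sigma_log_M,
    sigma_log_dchemo = sigma_log_dchemo,
    cycle_interval_days = cycle_interval_days,
    followup_cap_days = followup_cap_days,
    hybrid_threshold = hybrid_threshold
  )
  validate_parameters(p)
  class(p) <- "vct_params"
  p
}

validate_parameters <- function(p) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  for (f in .param_fields) {
    stopifnot_msg(is.numeric(p[[f]]) && length(p[[f]]) == 1 &&
                    is.finite(p[[f]]),
                  paste0("parameter '", f, "' must be a finite number"))
  }
  stopifnot_msg(p$b > p$d && p$d > 0, "requires b > d > 0")
  stopifnot_msg(p$u >= 0 && p$u < 1, "requires 0 <= u < 1")
  stopifnot_msg(p$d_chemotherapy_mean >= 0 && p$d_chemotherapy_mean <= 1,
                "d_chemotherapy_mean must lie in [0, 1]")
  stopifnot_msg(p$alpha1 >= 0 && p$alpha1 <= 1 &&
                  p$alpha2 >= 0 && p$alpha2 <= 1,
                "alpha1 and alpha2 must lie in [0, 1]")
  stopifnot_msg(p$alpha2 <= p$alpha1, "requires alpha2 <= alpha1")
  stopifnot_msg(p$M_relapse < p$M_diagnosis_mean,
                "requires M_relapse < M_diagnosis_mean")
  stopifnot_msg(p$beta_surgery >= 0, "beta_surgery must be >= 0")
  stopifnot_msg(p$sigma_log_M >= 0 && p$sigma_log_dchemo >= 0,
                "log-scale spreads must be >= 0")
  stopifnot_msg(p$cycle_interval_days > 0, "cycle interval must be > 0")
  stopifnot_msg(p$followup_cap_days > 0, "follow-up cap must be > 0")
  stopifnot_msg(p$hybrid_threshold >= 1, "hybrid_threshold must be >= 1")
  invisible(p)
}

#' @export
print.vct_params <- function(x, ...) {
  cat("Platinum-resistance model parameters\n")
  cat(sprintf("  growth: b = %.4g/day, d = %.4g/day (net %.4g/day)\n",
              x$b, x$d, x$b - x$d))
  cat(sprintf("  mechanism activation: u = %.3g per division\n", x$u))
  cat(sprintf("  burdens: M_diagnosis ~ %.4g cells, M_relapse = %.3g\n",
              x$M_diagnosis_mean, x$M_relapse))
  cat(sprintf(
    "  chemotherapy: d_chemo = %.3g, alpha1 = %.3g, alpha2 = %.3g\n",
    x$d_chemotherapy_mean, x$alpha1, x$alpha2))
  cat(sprintf("  surgery: %.3g-log kill; cycle interval %g days\n",
              x$beta_surgery, x$cycle_interval_days))
  invisible(x)
}

#' Read or write a model-parameter configuration file
#'
#' Parameters are stored as a flat YAML (or JSON) mapping using the
#' standard parameter names as keys. Unknown keys are rejected; missing
#' keys fall back to the defaults of [model_parameters()].
#'
#' @param path File path; format is chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `read_model_config()` returns a `vct_params` object;
#'   `write_model_config()` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_model_config(model_parameters(u = 2e-5), f)
#' read_model_config(f)$u
#' @export
read_model_config <- function(path) {
  vals <- .read_flat_config(path)
  unknown <- setdiff(names(vals), .param_fields)
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_parameters, vals)
}

#' @param params A `vct_params` object to serialize.
#' @rdname read_model_config
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "vct_params"))
  .write_flat_config(unclass(params), path)
}

.read_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

.write_flat_config <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
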