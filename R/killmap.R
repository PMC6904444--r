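# Per-genotype chemotherapy effect. The weight ladder w(k) scales the
# patient's per-cycle kill fraction by the number k of active resistance
# mechanisms; co-administered targeted drugs partially neutralize their
# target mechanism, moving a genotype's weight one rung back toward
# sensitivity with strength E.

#' Chemotherapy weight ladder
#'
#' Weight of the chemotherapy effect as a function of the number of
#' active resistance mechanisms: 1 for sensitive cells, `alpha1` for one
#' mechanism, `alpha2` for two, and 0 for fully resistant cells.
#'
#' @param k Number of active mechanisms (vector of integers in 0..3).
#' @param params [model_parameters()] supplying `alpha1` and `alpha2`.
#' @return Numeric vector of weights in `[0, 1]`, non-increasing in `k`.
#' @examples
#' chemo_weight(0:3, model_parameters())
#' @export
chemo_weight <- function(k, params = model_parameters()) {
  if (any(!k %in% 0:3)) stop("k must lie in 0..3", call. = FALSE)
  c(1, params$alpha1, params$alpha2, 0)[k + 1]
}

#' Per-genotype kill fractions of one chemotherapy pulse
#'
#' Builds the kill map applied at each chemotherapy cycle. A genotype
#' with `k` active mechanisms has base weight `w(k)` from
#' [chemo_weight()]. Each co-administered drug whose target mechanism is
#' active in the genotype neutralizes that mechanism with strength `E`,
#' interpolating the weight one rung down the ladder:
#' `w <- w + E * (w(level - 1) - w)`, applied once per covered active
#' mechanism in fixed `(pre, on, post)` order, each application using
#' the next-lower rung. Drugs whose target is inactive in a genotype do
#' not affect it. The kill fraction is `d_chemo_patient * w`.
#'
#' @param params [model_parameters()].
#' @param d_chemo_patient This patient's per-cycle kill fraction on
#'   sensitive cells, in `[0, 1]`.
#' @param drugs A [drug()] object, a list of them with distinct targets,
#'   or `NULL` for chemotherapy alone.
#' @return Named numeric vector of kill fractions per genotype, class
#'   `kill_map`.
#' @examples
#' km <- build_kill_map(model_parameters(), 0.856,
#'                      default_drug_registry()$wee1)
#' km[["010"]]
#' @export
build_kill_map <- function(params, d_chemo_patient, drugs = NULL) {
  stopifnot(inherits(params, "vct_params"))
  if (!is.finite(d_chemo_patient) || d_chemo_patient < 0 ||
      d_chemo_patient > 1) {
    stop("d_chemo_patient must lie in [0, 1]", call. = FALSE)
  }
  drugs <- .as_drug_list(drugs)
  eff <- stats::setNames(numeric(3), .mechanisms)
  for (dr in drugs) eff[dr$target] <- dr$E

  kills <- vapply(seq_len(8), function(i) {
    bits <- .genotype_bits[i, ]
    level <- sum(bits)
    w <- chemo_weight(level, params)
    for (m in .mechanisms) {
      if (bits[[m]] == 1L && eff[[m]] > 0) {
        w <- w + eff[[m]] * (chemo_weight(level - 1, params) - w)
        level <- level - 1L
      }
    }
    d_chemo_patient * w
  }, numeric(1))
  structure(stats::setNames(kills, .genotype_labels), class = "kill_map")
}

#' Apply one chemotherapy pulse to a tumor state
#'
#' Chemotherapy is modelled as an instantaneous pulse at the start of
#' each cycle. In deterministic mode every count is multiplied by
#' `1 - kill`. In stochastic mode, clones below the hybrid threshold
#' survive binomially (integer counts); larger clones are treated
#' multiplicatively.
#'
#' @param state A [tumor_state()].
#' @param killmap Kill fractions from [build_kill_map()].
#' @param stochastic Logical; draw binomial survivors for small clones.
#' @param threshold Clone size above which survival is multiplicative in
#'   stochastic mode.
#' @return The post-pulse `tumor_state` (time unchanged).
#' @examples
#' s <- tumor_state(c("000" = 1e6))
#' km <- build_kill_map(model_parameters(), 0.856)
#' apply_pulse(s, km)
#' @export
apply_pulse <- function(state, killmap, stochastic = FALSE,
                        threshold = 1e4) {
  stopifnot(length(killmap) == 8)
  n <- state$counts
  surv <- 1 - as.numeric(killmap)
  if (stochastic) {
    small <- n > 0 & n < threshold
    n[!small] <- n[!small] * surv[!small]
    if (any(small)) {
      n[small] <- stats::rbinom(sum(small), round(n[small]), surv[small])
    }
  } else {
    n <- n * surv
  }
  state$counts <- n
  state
}
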