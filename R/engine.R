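# Simulation engines for the multitype branching process.
#
# "exact"        — Gillespie over the 8-type birth-death-mutation process
#                  (compiled; integer counts).
# "hybrid"       — clones above `hybrid_threshold` grow deterministically
#                  at their genotype's effective net rate while emitting
#                  mutant lineages as a Poisson process (exact
#                  finite-horizon survival and size laws per lineage);
#                  clones below the threshold are advanced with the exact
#                  linear birth-death transition law (binomial survivors
#                  + negative-binomial offspring).
# "deterministic"— mean-field solution via the matrix exponential of the
#                  8x8 rate matrix.
#
# All stochastic draws use R's global RNG, so set.seed() gives full
# reproducibility.

.engine_modes <- c("hybrid", "exact", "deterministic")

# Expected-count rate matrix: A[j,i] is the flux from genotype i to j.
# A birth in type i (rate b*N_i) leaves the parent unchanged and adds a
# daughter that activates each inactive mechanism independently with
# probability u.
.rate_matrix <- function(params) {
  b <- params$b; d <- params$d; u <- params$u
  A <- matrix(0, 8, 8, dimnames = list(.genotype_labels,
                                       .genotype_labels))
  for (i in seq_len(8)) {
    bits <- .genotype_bits[i, ]
    inactive <- which(bits == 0L)
    m <- length(inactive)
    # daughter genotype distribution over subsets of inactive mechanisms
    # (index-based: combn() would misread a length-1 vector as a range)
    subsets <- c(list(integer(0)), if (m > 0) {
      unlist(lapply(seq_len(m), function(k) {
        lapply(utils::combn(seq_len(m), k, simplify = FALSE),
               function(idx) inactive[idx])
      }), recursive = FALSE)
    })
    for (s in subsets) {
      nb <- bits
      nb[s] <- 1L
      j <- which(.genotype_labels == paste(nb, collapse = ""))
      A[j, i] <- A[j, i] + b * u^length(s) * (1 - u)^(m - length(s))
    }
    A[i, i] <- A[i, i] - d
  }
  A
}

# Matrix exponential by scaling-and-squaring with a Taylor series;
# adequate for this well-conditioned 8x8 generator.
.expm <- function(M) {
  nrm <- max(rowSums(abs(M)))
  s <- max(0L, ceiling(log2(max(nrm, 1))))
  Ms <- M / 2^s
  E <- diag(nrow(M))
  term <- E
  for (k in 1:30) {
    term <- term %*% Ms / k
    E <- E + term
    if (max(abs(term)) < 1e-16 * max(abs(E))) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# 8-point Gauss-Legendre nodes and weights on [0, 1]
.gauss8 <- local({
  x <- c(0.1834346424956498, 0.5255324099163290, 0.7966664774136267,
         0.9602898564975363)
  w <- c(0.3626837833783620, 0.3137066458778873, 0.2223810344533745,
         0.1012285362903763)
  list(x = (c(-rev(x), x) + 1) / 2, w = c(rev(w), w) / 2)
})

# One hybrid chunk of length dt. Returns the new counts vector.
#
# Each genotype grows at its effective net rate lam_i = b*(1-u)^m_i - d
# (a daughter that mutates leaves the parent genotype; m_i inactive
# mechanisms), which keeps the per-genotype means exact. Mutant
# lineages are emitted as a Poisson process with rate
# u_eff * b * N_i(s); each founder is thinned by its exact
# finite-horizon survival probability 1 - alpha(dt - s) and, if it
# survives, enters with the exact linear birth-death single-cell size
# law 1 + Geometric(1 - beta(dt - s)). This is exact in distribution
# per lineage at every horizon (only within-chunk onward mutation of a
# new lineage is neglected, which the chunk-size cap controls).
.hybrid_step <- function(n0, dt, params, threshold = NULL,
                         founder_cap = 300) {
  b <- params$b; d <- params$d; u <- params$u
  if (is.null(threshold)) threshold <- params$hybrid_threshold
  m_inact <- 3 - rowSums(.genotype_bits)
  b_eff <- b * (1 - u)^m_inact
  lam <- b_eff - d
  lam[abs(lam) < 1e-10] <- 1e-10   # guard the critical-case formulas
  elt <- exp(lam * dt)

  n1 <- numeric(8)
  integral <- numeric(8)             # int N_i(s) ds over the chunk
  small <- logical(8)
  for (i in which(n0 > 0)) {
    if (n0[i] >= threshold || round(n0[i]) < 1) {
      n1[i] <- n0[i] * elt[i]
      integral[i] <- n0[i] * (elt[i] - 1) / lam[i]
    } else {
      small[i] <- TRUE
      denom <- b_eff[i] * elt[i] - d
      a_ext <- d * (elt[i] - 1) / denom
      beta <- b_eff[i] * (elt[i] - 1) / denom
      k <- stats::rbinom(1, round(n0[i]), 1 - a_ext)
      n1[i] <- if (k > 0) k + stats::rnbinom(1, k, 1 - beta) else 0
      integral[i] <- (n0[i] + n1[i]) / 2 * dt
    }
  }

  if (u > 0) {
    # single-step flux: a division of type i sends a daughter to j
    # (one extra active mechanism) at rate b * u * (1-u)^(m_i - 1)
    flux <- numeric(8)
    for (i in which(n0 > 0)) {
      targets <- .mutation_targets_idx[[i]]
      if (!length(targets) || integral[i] == 0) next
      u_eff <- u * (1 - u)^(m_inact[i] - 1)
      # founding-time density along the source's within-chunk bridge
      propose <- function(k) {
        if (small[i]) stats::runif(k, 0, dt) else
          log(1 + stats::runif(k) * (elt[i] - 1)) / lam[i]
      }
      dens_at <- function(s) {
        if (small[i]) rep(integral[i] / dt, length(s)) else
          n0[i] * exp(lam[i] * s)
      }
      for (j in targets) {
        bj <- b_eff[j]; lj <- lam[j]
        surv_p <- function(delta) {          # 1 - alpha_j(delta)
          el <- exp(lj * delta)
          1 - d * (el - 1) / (bj * el - d)
        }
        gx <- .gauss8$x * dt
        nu_all <- u_eff * b * integral[i]
        nu_s <- u_eff * b * dt *
          sum(.gauss8$w * dens_at(gx) * surv_p(dt - gx))
        if (nu_s <= founder_cap) {
          k <- stats::rpois(1, nu_s)
          if (k > 0) {
            # rejection-sample founding times of surviving lineages
            acc <- max(nu_s / nu_all, 1e-3)
            ss <- numeric(0)
            while (length(ss) < k) {
              m <- ceiling((k - length(ss)) / acc) + 10
              cand <- propose(m)
              keep <- stats::runif(m) < surv_p(dt - cand)
              ss <- c(ss, cand[keep])
            }
            delta <- dt - ss[seq_len(k)]
            el <- exp(lj * delta)
            beta <- bj * (el - 1) / (bj * el - d)
            flux[j] <- flux[j] + k +
              sum(stats::rnbinom(k, 1, 1 - beta))
          }
        } else {
          # many founders: fluctuations are negligible, add the exact
          # expected mutant mass at chunk end
          dl <- lam[j] - lam[i]
          growth <- if (abs(dl) < 1e-12) dt * elt[j] else
            (elt[j] - elt[i]) / dl
          flux[j] <- flux[j] + u_eff * b * n0[i] * growth
        }
      }
    }
    n1 <- n1 + flux
  }
  n1
}

#' Advance a tumor state in time
#'
#' Simulates the 8-type birth-death-mutation process for a given
#' duration under one of three engines: `"exact"` (Gillespie),
#' `"hybrid"` (deterministic growth of large clones with stochastic
#' emission and early-drift survival of new mutant lineages, exact
#' birth-death transitions for small clones) or `"deterministic"`
#' (mean-field matrix exponential). Optionally stops early once the
#' total burden reaches `stop_total`.
#'
#' @param state A [tumor_state()].
#' @param duration Days to advance (`>= 0`).
#' @param params [model_parameters()].
#' @param engine `"hybrid"`, `"exact"` or `"deterministic"`.
#' @param stop_total Stop as soon as total burden reaches this value
#'   (default `Inf`: run for the full duration).
#' @return The advanced `tumor_state`; attribute `"stopped"` is one of
#'   `"duration"`, `"threshold"` or `"extinct"`.
#' @examples
#' s <- tumor_state(c("000" = 1e6))
#' simulate_interval(s, 100, model_parameters(), "deterministic")
#' @export
simulate_interval <- function(state, duration, params,
                              engine = c("hybrid", "exact",
                                         "deterministic"),
                              stop_total = Inf) {
  engine <- match.arg(engine)
  stopifnot(duration >= 0)
  if (duration == 0) {
    attr(state, "stopped") <- "duration"
    return(state)
  }
  lam <- params$b - params$d

  if (engine == "exact") {
    res <- .gillespie_interval(state$counts, params$b, params$d,
                               params$u, duration,
                               if (is.finite(stop_total)) stop_total
                               else 0)
    state$counts <- stats::setNames(res$counts, .genotype_labels)
    state$time <- state$time + res$time
    attr(state, "stopped") <- res$stopped
    return(state)
  }

  if (engine == "deterministic") {
    A <- .rate_matrix(params)
    step <- function(n, dt) as.numeric(.expm(A * dt) %*% n)
    if (!is.finite(stop_total)) {
      state$counts[] <- step(state$counts, duration)
      state$time <- state$time + duration
      attr(state, "stopped") <- "duration"
      return(state)
    }
    # total burden grows exactly as e^((b-d) t), so the crossing time
    # has a closed form; iterate to absorb rounding
    elapsed <- 0
    while (elapsed < duration && sum(state$counts) < stop_total) {
      guess <- log(stop_total / sum(state$counts)) / lam
      dt <- min(duration - elapsed, max(guess * (1 + 1e-12), 1e-9))
      state$counts[] <- step(state$counts, dt)
      elapsed <- elapsed + dt
    }
    state$time <- state$time + elapsed
    attr(state, "stopped") <- if (sum(state$counts) >= stop_total)
      "threshold" else "duration"
    return(state)
  }

  # hybrid: chunk at one e-fold of growth, shortened when the
  # per-chunk mutation pressure u*b*dt would make second-order
  # (within-chunk) mutations non-negligible
  chunk_max <- 1 / lam
  if (params$u > 0) {
    chunk_max <- min(chunk_max, 0.01 / (params$u * params$b))
  }
  elapsed <- 0
  stopped <- "duration"
  while (elapsed < duration) {
    tot <- sum(state$counts)
    if (tot == 0) { stopped <- "extinct"; break }
    if (tot >= stop_total) { stopped <- "threshold"; break }
    dt <- min(duration - elapsed, chunk_max)
    if (is.finite(stop_total)) {
      # aim the chunk at the projected crossing to limit overshoot
      guess <- log(stop_total / tot) / lam
      if (guess < dt) dt <- max(guess, 0.25)
    }
    state$counts[] <- .hybrid_step(state$counts, dt, params)
    elapsed <- elapsed + dt
  }
  if (sum(state$counts) == 0) stopped <- "extinct"
  else if (sum(state$counts) >= stop_total) stopped <- "threshold"
  state$time <- state$time + elapsed
  attr(state, "stopped") <- stopped
  state
}
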