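# Genotype lattice: three binary platinum-resistance mechanisms
# (pre-, on-, post-target), giving 8 cell types. Activation is
# irreversible, so the lattice is the Boolean cube ordered
# lexicographically on (pre, on, post): "000" first, "111" last.

.mechanisms <- c("pre", "on", "post")

.genotype_bits <- local({
  m <- as.matrix(expand.grid(post = 0:1, on = 0:1, pre = 0:1))[, 3:1]
  rownames(m) <- apply(m, 1, paste, collapse = "")
  storage.mode(m) <- "integer"
  m
})

.genotype_labels <- rownames(.genotype_bits)

# mutation_targets_idx[[i]]: indices (1..8) reachable from genotype i by
# activating exactly one inactive mechanism, in (pre, on, post) order
.mutation_targets_idx <- local({
  lapply(seq_len(8), function(i) {
    bits <- .genotype_bits[i, ]
    idx <- integer(0)
    for (m in seq_len(3)) {
      if (bits[m] == 0L) {
        nb <- bits
        nb[m] <- 1L
        idx <- c(idx, which(.genotype_labels ==
                              paste(nb, collapse = "")))
      }
    }
    idx
  })
})

.as_genotype_label <- function(g) {
  if (is.numeric(g) && length(g) == 3) {
    g <- paste(as.integer(g), collapse = "")
  }
  if (!is.character(g) || length(g) != 1 || !g %in% .genotype_labels) {
    stop("invalid genotype: must be one of ", paste(.genotype_labels,
         collapse = ", "), call. = FALSE)
  }
  g
}

#' Enumerate the eight resistance genotypes
#'
#' Each cancer-cell genotype is a triple of binary flags marking whether
#' the pre-target (reduced platinum bioavailability), on-target (enhanced
#' DNA-damage repair) and post-target (dysfunctional apoptosis) resistance
#' mechanisms are active. The order is lexicographic on
#' `(pre, on, post)`: the fully sensitive genotype `"000"` comes first and
#' the fully resistant `"111"` last.
#'
#' @return A data frame with columns `label` (3-digit string), `pre`,
#'   `on`, `post` (0/1 flags) and `k` (number of active mechanisms).
#' @examples
#' enumerate_genotypes()
#' @export
enumerate_genotypes <- function() {
  data.frame(
    label = .genotype_labels,
    pre = .genotype_bits[, "pre"],
    on = .genotype_bits[, "on"],
    post = .genotype_bits[, "post"],
    k = rowSums(.genotype_bits),
    row.names = NULL
  )
}

#' Number of active resistance mechanisms in a genotype
#'
#' @param g Genotype, as a 3-digit label (e.g. `"101"`) or a numeric
#'   triple of 0/1 flags in `(pre, on, post)` order.
#' @return Integer in 0..3.
#' @examples
#' active_count("101")
#' @export
active_count <- function(g) {
  g <- .as_genotype_label(g)
  sum(.genotype_bits[g, ])
}

#' Genotypes reachable by a single mechanism activation
#'
#' Resistance mechanisms accumulate irreversibly during cell division, so
#' the mutational neighbours of a genotype are exactly those obtained by
#' activating one currently inactive mechanism.
#'
#' @inheritParams active_count
#' @return Character vector of genotype labels (possibly empty), in
#'   `(pre, on, post)` activation order.
#' @examples
#' mutation_targets("000")
#' mutation_targets("111")
#' @export
mutation_targets <- function(g) {
  g <- .as_genotype_label(g)
  .genotype_labels[.mutation_targets_idx[[which(.genotype_labels == g)]]]
}
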