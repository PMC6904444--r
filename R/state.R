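# Tumor state: cell counts per genotype at a time point.

#' Construct a tumor state
#'
#' A tumor state holds one (nonnegative) cell count per resistance
#' genotype plus the time since the first cancer cell. Counts may be
#' non-integer: the hybrid engine tracks large clones as continuous
#' masses.
#'
#' @param counts Numeric vector of 8 nonnegative counts. Either unnamed
#'   in the canonical genotype order (see [enumerate_genotypes()]) or
#'   named by genotype label; a named vector may be partial, missing
#'   genotypes get count 0.
#' @param time Days since the first cancer cell.
#' @return An object of class `tumor_state`.
#' @examples
#' tumor_state(c("000" = 1e6, "010" = 250))
#' @export
tumor_state <- function(counts = c("000" = 1), time = 0) {
  full <- stats::setNames(numeric(8), .genotype_labels)
  if (is.null(names(counts))) {
    stopifnot(length(counts) == 8)
    full[] <- as.numeric(counts)
  } else {
    bad <- setdiff(names(counts), .genotype_labels)
    if (length(bad)) stop("unknown genotype label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    full[names(counts)] <- as.numeric(counts)
  }
  if (any(full < 0) || any(!is.finite(full))) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  structure(list(counts = full, time = as.numeric(time)),
            class = "tumor_state")
}

total_burden <- function(state) sum(state$counts)

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf("Tumor state at day %.1f: %.4g cells\n", x$time,
              total_burden(x)))
  occ <- x$counts[x$counts > 0]
  if (length(occ)) {
    print(signif(occ, 4))
  }
  invisible(x)
}

#' Resistance-class composition of a tumor
#'
#' Splits the tumor into the fully sensitive genotype (`"000"`), the
#' partially resistant genotypes (one or two active mechanisms) and the
#' fully resistant genotype (`"111"`).
#'
#' @param state A [tumor_state()] with positive total burden.
#' @return Named numeric vector `c(sensitive, partial, full)` summing
#'   to 1.
#' @examples
#' composition(tumor_state(c("000" = 29, "010" = 70, "111" = 1)))
#' @export
composition <- function(state) {
  n <- state$counts
  tot <- sum(n)
  if (tot <= 0) stop("composition undefined for an empty tumor",
                     call. = FALSE)
  k <- rowSums(.genotype_bits)
  c(sensitive = n[["000"]] / tot,
    partial = sum(n[k %in% c(1, 2)]) / tot,
    full = n[["111"]] / tot)
}

#' Apply debulking surgery to a tumor state
#'
#' Surgery removes a fixed fraction of every clone: each genotype count
#' is multiplied by `10^-beta`, so the composition is preserved exactly.
#'
#' @param state A [tumor_state()].
#' @param beta Cell-log kill (`beta = 2` removes 99% of all cells).
#' @return The post-surgery `tumor_state` (time unchanged).
#' @examples
#' apply_surgery(tumor_state(c("000" = 1e9)), beta = 2)
#' @export
apply_surgery <- function(state, beta) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  state$counts <- state$counts * 10^(-beta)
  state
}
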