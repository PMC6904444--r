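# Targeted-drug definitions and the three-level evidence score.

#' Total relative efficacy from three evidence levels
#'
#' Aggregates a targeted drug's relative efficacy versus platinum across
#' in vitro (`I`), in vivo (`V`) and clinical-trial (`C`) evidence as
#' `E = 0.2 I + 0.3 V + 0.5 C`: clinical evidence is weighted 2.5 times
#' the in vitro evidence and in vivo evidence at 60% of clinical.
#'
#' @param I,V,C Relative efficacies in `[0, 1]` at the three evidence
#'   levels (1 means the same effect size as platinum itself).
#' @return Total relative efficacy `E` in `[0, 1]`.
#' @examples
#' total_relative_efficacy(0.5, 0.4, 0.3)
#' @export
total_relative_efficacy <- function(I, V, C) {
  vals <- c(I = I, V = V, C = C)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("I, V and C must lie in [0, 1]", call. = FALSE)
  }
  0.2 * I + 0.3 * V + 0.5 * C
}

#' Define a targeted drug
#'
#' A drug neutralizes one platinum-resistance mechanism with total
#' relative efficacy `E`. `E` is either given directly (when only the
#' aggregate is known) or derived from the three evidence levels via
#' [total_relative_efficacy()]; if both are supplied the evidence levels
#' take precedence.
#'
#' @param name Drug identifier.
#' @param target Targeted mechanism: `"pre"`, `"on"` or `"post"`.
#' @param E Total relative efficacy override in `[0, 1]`.
#' @param I,V,C Optional evidence-level efficacies; either all three or
#'   none must be given.
#' @return An object of class `vct_drug`.
#' @examples
#' drug("wee1", "on", E = 0.85)
#' drug("example", "pre", I = 0.5, V = 0.4, C = 0.3)$E
#' @export
drug <- function(name, target, E = NULL, I = NULL, V = NULL, C = NULL) {
  target <- match.arg(target, .mechanisms)
  ivc <- list(I = I, V = V, C = C)
  n_ivc <- sum(!vapply(ivc, is.null, logical(1)))
  if (n_ivc == 3) {
    E <- total_relative_efficacy(I, V, C)
  } else if (n_ivc > 0) {
    stop("supply either all of I, V, C or none", call. = FALSE)
  } else if (is.null(E)) {
    stop("supply either E or all of I, V, C", call. = FALSE)
  }
  if (!is.finite(E) || E < 0 || E > 1) {
    stop("E must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, target = target, E = E,
                 I = I, V = V, C = C),
            class = "vct_drug")
}

#' @export
print.vct_drug <- function(x, ...) {
  cat(sprintf("Drug '%s': %s-target, E = %.3g\n", x$name, x$target, x$E))
  invisible(x)
}

#' Default registry of resistance-targeting drugs
#'
#' The three agents modelled against the three resistance-mechanism
#' classes: trientine (copper chelation, restores platinum uptake;
#' pre-target; E = 0.41), a Wee1 inhibitor (abrogates the G2/M
#' checkpoint, resensitizes DNA-repair-proficient cells; on-target;
#' E = 0.85) and birinapant (IAP antagonist, restores apoptosis;
#' post-target; E = 0.35). Evidence-level values are not carried here,
#' only the aggregate efficacies.
#'
#' @return Named list of three [drug()] objects.
#' @examples
#' default_drug_registry()$wee1
#' @export
default_drug_registry <- function() {
  list(
    trientine = drug("trientine", "pre", E = 0.41),
    wee1 = drug("wee1", "on", E = 0.85),
    birinapant = drug("birinapant", "post", E = 0.35)
  )
}

# Normalize a drugs argument to a validated list of vct_drug with
# distinct targets.
.as_drug_list <- function(drugs) {
  if (is.null(drugs)) return(list())
  if (inherits(drugs, "vct_drug")) drugs <- list(drugs)
  stopifnot(all(vapply(drugs, inherits, logical(1), "vct_drug")))
  targets <- vapply(drugs, `[[`, character(1), "target")
  if (anyDuplicated(targets)) {
    stop("two drugs share the same target mechanism", call. = FALSE)
  }
  drugs
}

#' Read drug definitions from a configuration file
#'
#' Each entry names a drug and gives its `target` plus either the three
#' evidence levels `I`, `V`, `C` or a direct efficacy `E`.
#'
#' @param path YAML or JSON file: a mapping from drug name to fields.
#' @return Named list of [drug()] objects.
#' @export
read_drug_config <- function(path) {
  raw <- .read_flat_config(path)
  out <- lapply(names(raw), function(nm) {
    f <- raw[[nm]]
    allowed <- c("target", "E", "I", "V", "C")
    unknown <- setdiff(names(f), allowed)
    if (length(unknown)) {
      stop("unknown drug key(s) for '", nm, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    drug(nm, f$target, E = f$E, I = f$I, V = f$V, C = f$C)
  })
  stats::setNames(out, names(raw))
}
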