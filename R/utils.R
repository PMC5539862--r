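#' Disease-stage factor levels
#'
#' Stages follow the clinical grouping of the Global Deterioration Scale:
#' early (GDS 2-3), middle (GDS 4-5), late (GDS 6-7).
#'
#' @return Character vector `c("early", "middle", "late")`.
#' @export
stage_levels <- function() c("early", "middle", "late")

as_stage <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), stage_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = stage_levels())
}

# Deterministic per-substream seed derivation from one master seed.
# Keeps results stable when the number of repetitions changes: stream k
# always gets the same seed. Stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483647)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Trapezoidal quadrature on the unit-spaced grid 1..l: end points get
# weight 1/2. For a constant difference c this gives c^2 * (l - 1).
trapz_grid <- function(v) {
  l <- length(v)
  if (l < 2) return(0)
  sum(v) - (v[1] + v[l]) / 2
}

trapz_weights <- function(l) {
  w <- rep(1, l)
  w[c(1, l)] <- 0.5
  w
}

# Majority vote with deterministic tie-break: among tied labels, prefer the
# one with the largest training prevalence, then the earliest stage in the
# fixed order early < middle < late.
majority_vote <- function(labels, prevalence = NULL) {
  labels <- as_stage(labels)
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1 && !is.null(prevalence)) {
    prev <- prevalence[top]
    prev[is.na(prev)] <- 0
    top <- top[prev == max(prev)]
  }
  factor(top[1], levels = stage_levels())
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    abort(paste0("`", name, "` must be a finite number ",
                 if (strict) "> " else ">= ", min))
  }
  invisible(x)
}
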