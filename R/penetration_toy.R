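# Penetration-probability toy model.
#
# Absorption in its simplest conception: each molecule of the applied dose
# penetrates the skin barrier with some probability within the observation
# window. Two extreme cases bracket how relative absorption can depend on
# dose. Case 1: only the molecule nearest the barrier penetrates (p = 1),
# all others have p = 0, so the expected relative absorption is 100/dose -
# it falls inversely with dose (slope 0 for absolute absorbed vs dose).
# Case 2: every molecule shares the same p, so relative absorption is
# constant at 100*p whatever the dose (slope 1).

#' Construct a molecule ensemble
#'
#' @param probabilities Per-molecule penetration probabilities, each in
#'   `[0, 1]`; length is the dose in molecules.
#' @return An object of class `molecule_ensemble`.
#' @export
molecule_ensemble <- function(probabilities) {
  probabilities <- as.numeric(probabilities)
  if (length(probabilities) < 1L) {
    stop("ensemble must contain at least one molecule", call. = FALSE)
  }
  if (any(is.na(probabilities)) || any(probabilities < 0) ||
      any(probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(probabilities = probabilities), class = "molecule_ensemble")
}

#' Case 1 ensemble: only the nearest molecule penetrates
#'
#' Probability vector `c(1, 0, 0, ...)` of length `dose`.
#'
#' @param dose Dose in molecules, integer >= 1.
#' @return A [molecule_ensemble()].
#' @export
case1_ensemble <- function(dose) {
  if (length(dose) != 1L || is.na(dose) || dose < 1) {
    stop("dose must be an integer >= 1", call. = FALSE)
  }
  molecule_ensemble(c(1, rep(0, dose - 1L)))
}

#' Case 2 ensemble: every molecule penetrates with the same probability
#'
#' @param dose Dose in molecules, integer >= 1.
#' @param p Shared penetration probability, default 0.1.
#' @return A [molecule_ensemble()].
#' @export
case2_ensemble <- function(dose, p = 0.1) {
  if (length(dose) != 1L || is.na(dose) || dose < 1) {
    stop("dose must be an integer >= 1", call. = FALSE)
  }
  molecule_ensemble(rep(p, dose))
}

#' Expected relative absorption of an ensemble
#'
#' `100 * sum(p_i) / N` percent: the expected number of penetrated molecules
#' relative to the dose.
#'
#' @param ensemble A [molecule_ensemble()].
#' @return Expected relative absorption, percent (always in `[0, 100]`).
#' @export
#' @examples
#' expected_relative_absorption(case1_ensemble(100))   # 1%
#' expected_relative_absorption(case2_ensemble(1000))  # 10%
expected_relative_absorption <- function(ensemble) {
  stopifnot(inherits(ensemble, "molecule_ensemble"))
  p <- ensemble$probabilities
  100 * sum(p) / length(p)
}

#' Simulate penetration as independent Bernoulli draws
#'
#' One draw per molecule at its own probability; reproducible for a given
#' seed (the global random seed is restored afterwards).
#'
#' @param ensemble A [molecule_ensemble()].
#' @param seed Integer seed (required).
#' @return Integer count of penetrated molecules.
#' @export
simulate_penetration <- function(ensemble, seed) {
  stopifnot(inherits(ensemble, "molecule_ensemble"))
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  p <- ensemble$probabilities
  withr::with_seed(as.integer(seed), {
    sum(stats::runif(length(p)) < p)
  })
}

#' The two bracketing case series
#'
#' Expected relative absorption of Case 1 at doses 1, 2, 10, 100 molecules
#' and of Case 2 (p = 0.1) at doses 10, 20, 100, 1000.
#'
#' @return A data.frame with columns `case`, `dose`, `expected_pct`.
#' @export
toy_case_series <- function() {
  d1 <- c(1L, 2L, 10L, 100L)
  d2 <- c(10L, 20L, 100L, 1000L)
  data.frame(
    case = rep(c("case1", "case2"), each = 4L),
    dose = c(d1, d2),
    expected_pct = c(
      vapply(d1, function(d) expected_relative_absorption(case1_ensemble(d)),
             numeric(1L)),
      vapply(d2, function(d) expected_relative_absorption(case2_ensemble(d)),
             numeric(1L))
    )
  )
}
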