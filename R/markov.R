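#' Build the monthly transition matrix for one arm
#'
#' Assembles the 5x5 row-stochastic monthly transition matrix over the
#' states NYHA I-IV and dead. Death is absorbing and, in the shipped model,
#' fed only by heart-failure death out of NYHA III and IV; zeros in the
#' published rows are structural (e.g. NYHA IV patients cannot improve) and
#' are never perturbed by sensitivity analyses.
#'
#' @param params A `cea_parameters` object.
#' @param arm `"mitraclip"` or `"omt"`.
#'
#' @return A 5x5 matrix of class `cea_transition_matrix` with
#'   dimnames `nyha1 ... nyha4, dead` and an `arm` attribute.
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
#' build_transition_matrix(params, "omt")
build_transition_matrix <- function(params, arm = c("mitraclip", "omt")) {
  stopifnot(inherits(params, "cea_parameters"))
  arm <- match.arg(arm)
  m <- params$transitions[[arm]]
  validate_transition_matrix(m)
  structure(m, arm = arm, class = c("cea_transition_matrix", "matrix", "array"))
}

validate_transition_matrix <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || !all(dim(m) == c(5L, 5L))) {
    abort("A transition matrix must be 5x5 (NYHA I-IV and dead).")
  }
  if (any(m < 0) || any(m > 1)) {
    abort("Transition probabilities must lie in [0, 1].")
  }
  bad <- which(abs(rowSums(m) - 1) > tol)
  if (length(bad)) {
    abort(sprintf("Transition row(s) %s do not sum to 1.",
                  paste(rownames(m)[bad] %||% bad, collapse = ", ")))
  }
  if (!identical(unname(m[5L, ]), c(0, 0, 0, 0, 1)) &&
      any(abs(m[5L, ] - c(0, 0, 0, 0, 1)) > tol)) {
    abort("The dead state must be absorbing: row (0, 0, 0, 0, 1).")
  }
  invisible(m)
}

## Fast internal trace: (n_cycles + 1) x 5 occupancy matrix, row 1 = entry.
markov_trace <- function(init, m, n_cycles) {
  out <- matrix(0, n_cycles + 1L, 5L)
  out[1L, ] <- init
  v <- init
  for (t in seq_len(n_cycles)) {
    v <- v %*% m
    out[t + 1L, ] <- v
  }
  colnames(out) <- STATES
  out
}

#' Propagate a cohort through the Markov model
#'
#' Left-multiplies the occupancy vector by the monthly transition matrix for
#' `n_cycles` cycles, recording occupancy after every cycle. Row `cycle = 0`
#' is the entry distribution handed over by the 30-day stage.
#'
#' @param initial Numeric length-5 occupancy vector on the simplex
#'   (NYHA I-IV, dead), e.g. the `initial_distribution` of [run_stage()].
#' @param matrix A `cea_transition_matrix` (or any valid 5x5 row-stochastic
#'   matrix with absorbing death).
#' @param n_cycles Number of monthly cycles (>= 1).
#'
#' @return A tibble of class `cea_trace` with columns `cycle` (0 ... n_cycles),
#'   `nyha1` ... `nyha4`, `dead`.
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
#' stage <- run_stage(params, "omt")
#' tr <- run_cohort(stage$initial_distribution[[1]],
#'                  build_transition_matrix(params, "omt"), 336)
run_cohort <- function(initial, matrix, n_cycles) {
  if (length(initial) != 5L || any(initial < 0) || abs(sum(initial) - 1) > 1e-9) {
    abort("`initial` must be a length-5 occupancy vector summing to 1.")
  }
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    abort("`n_cycles` must be at least 1.")
  }
  validate_transition_matrix(unclass(matrix))
  tr <- markov_trace(as.numeric(initial), unclass(matrix), as.integer(n_cycles))
  out <- as_tibble(as.data.frame(tr))
  out <- dplyr::mutate(out, cycle = 0:as.integer(n_cycles), .before = 1L)
  class(out) <- c("cea_trace", class(out))
  out
}

trace_matrix <- function(trace) {
  as.matrix(trace[, STATES])
}

## Per-cycle effective live occupancy (n_cycles x 4): mean of start- and
## end-of-cycle occupancy under half-cycle correction, end-of-cycle without.
effective_occupancy <- function(tr, half_cycle) {
  n <- nrow(tr) - 1L
  live <- tr[, 1:4, drop = FALSE]
  if (half_cycle) {
    0.5 * (live[1:n, , drop = FALSE] + live[2:(n + 1L), , drop = FALSE])
  } else {
    live[2:(n + 1L), , drop = FALSE]
  }
}

#' Life expectancy from a cohort trace
#'
#' Sums the alive occupancy over all cycles and converts months to years.
#' With half-cycle correction each cycle contributes the mean of its start-
#' and end-of-cycle alive mass; without, the end-of-cycle mass.
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param half_cycle Apply half-cycle correction (default `TRUE`).
#'
#' @return Undiscounted life expectancy in years over the model horizon.
#' @export
life_years <- function(trace, half_cycle = TRUE) {
  occ <- effective_occupancy(trace_matrix(trace), half_cycle)
  sum(occ) / 12
}

#' Expected lifetime heart-failure hospitalizations from a cohort trace
#'
#' Each live state carries a monthly hospitalization probability; expected
#' events are the occupancy-weighted sum over cycles, using the same
#' half-cycle convention as [life_years()].
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param h Numeric length-4 vector of monthly hospitalization probabilities
#'   for NYHA I-IV.
#' @param half_cycle Apply half-cycle correction (default `TRUE`).
#'
#' @return Expected hospitalization events per person.
#' @export
expected_hospitalizations <- function(trace, h, half_cycle = TRUE) {
  if (length(h) != 4L) abort("`h` must give one probability per NYHA class (length 4).")
  if (any(h < 0) || any(h > 1)) abort("`h` entries must lie in [0, 1].")
  occ <- effective_occupancy(trace_matrix(trace), half_cycle)
  sum(occ %*% h)
}
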