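#' Run the 30-day decision-tree stage for one arm
#'
#' The first model stage covers the 30 days after allocation. The MitraClip
#' arm is charged the eight one-time procedure-related cost components plus
#' one month of medical therapy, and incurs the one-time procedure and
#' averaged complication disutilities. The comparator arm is charged one
#' month of medical therapy only. Each arm leaves the stage with its
#' configured post-30-day NYHA distribution, scaled by any 30-day mortality
#' (the dead share of the handed-over distribution equals the 30-day
#' mortality exactly).
#'
#' @param params A `cea_parameters` object.
#' @param arm `"mitraclip"` or `"omt"`.
#'
#' @return A one-row tibble of class `cea_stage` with columns `arm`,
#'   `stage_cost` (CNY), `stage_utility_decrement` (QALY), `stage_deaths`
#'   (probability) and list-column `initial_distribution` (length-5 numeric
#'   over NYHA I-IV and dead).
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
#' run_stage(params, "mitraclip")
run_stage <- function(params, arm = c("mitraclip", "omt")) {
  stopifnot(inherits(params, "cea_parameters"))
  arm <- match.arg(arm)
  m <- params$decision_tree$thirty_day_mortality[[arm]]
  live <- params$decision_tree$initial_distribution[[arm]] * (1 - m)
  dist <- c(live, dead = m)
  names(dist) <- STATES
  if (arm == "mitraclip") {
    stage_cost <- sum(params$costs$mitraclip_onetime) + params$costs$omt_monthly
    decrement <- params$utilities$disutility$procedure +
      params$utilities$disutility$complications
  } else {
    stage_cost <- params$costs$omt_monthly
    decrement <- 0
  }
  out <- tibble(
    arm = arm,
    stage_cost = stage_cost,
    stage_utility_decrement = decrement,
    stage_deaths = m,
    initial_distribution = list(dist)
  )
  class(out) <- c("cea_stage", class(out))
  out
}
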