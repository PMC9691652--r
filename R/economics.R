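#' Monthly discount factor from an annual rate
#'
#' Compound conversion: `(1 + annual_rate)^(1/12) - 1`, so that twelve
#' monthly discounting steps equal one annual step.
#'
#' @param annual_rate Annual discount rate (fraction per year, >= 0).
#' @return Monthly discount rate (fraction per month).
#' @export
#'
#' @examples
#' monthly_discount_factor(0.05)
monthly_discount_factor <- function(annual_rate) {
  if (!is.numeric(annual_rate) || any(annual_rate < 0)) {
    abort("`annual_rate` must be non-negative.")
  }
  (1 + annual_rate)^(1 / 12) - 1
}

discount_weights <- function(annual_rate, n_cycles) {
  dm <- monthly_discount_factor(annual_rate)
  (1 + dm)^(-seq_len(n_cycles))
}

## Core accrual over one arm's trace matrix; plain numerics for speed.
## Convention: without half-cycle correction, a cycle's flows accrue to the
## end-of-cycle occupancy; with correction, to the mean of start and end.
## One-time stage quantities enter undiscounted at time zero.
accrue_core <- function(tr, h, stage_cost, stage_dec, omt_monthly, c_hosp,
                        u, du_hosp, disc, half_cycle) {
  occ <- effective_occupancy(tr, half_cycle)
  alive <- rowSums(occ)
  ev <- as.numeric(occ %*% h)
  flows <- alive * omt_monthly + ev * c_hosp
  list(
    lifetime_cost = stage_cost + sum(disc * flows),
    lifetime_qaly = -stage_dec + sum(disc * (as.numeric(occ %*% u) - ev * du_hosp)),
    life_years = sum(alive) / 12,
    hospitalizations = sum(ev),
    undiscounted_cost = stage_cost + sum(flows)
  )
}

#' Accrue discounted lifetime outcomes for one arm
#'
#' Combines the 30-day stage result with the cohort trace: monthly
#' medical-therapy costs and per-event hospitalization costs, NYHA-state
#' utilities and per-event hospitalization disutility, all discounted at the
#' monthly equivalent of the annual rate. One-time stage cost and stage
#' disutility enter undiscounted at time zero. Occupancy terms follow the
#' model's half-cycle convention.
#'
#' @param stage A `cea_stage` row from [run_stage()].
#' @param trace A `cea_trace` from [run_cohort()] for the same arm.
#' @param params A `cea_parameters` object.
#'
#' @return A one-row tibble of class `cea_arm` with columns `arm`,
#'   `lifetime_cost`, `lifetime_qaly`, `life_years`, `hospitalizations`,
#'   `undiscounted_cost`.
#' @export
accrue_arm <- function(stage, trace, params) {
  stopifnot(inherits(params, "cea_parameters"))
  arm <- stage$arm[[1]]
  res <- accrue_core(
    tr = trace_matrix(trace),
    h = params$hospitalization_risk[[arm]],
    stage_cost = stage$stage_cost[[1]],
    stage_dec = stage$stage_utility_decrement[[1]],
    omt_monthly = params$costs$omt_monthly,
    c_hosp = params$costs$hf_hospitalization,
    u = params$utilities$monthly,
    du_hosp = params$utilities$disutility$hf_hospitalization,
    disc = discount_weights(params$econ$annual_discount_rate, nrow(trace) - 1L),
    half_cycle = params$model$half_cycle_correction
  )
  out <- tibble(arm = arm, !!!res)
  class(out) <- c("cea_arm", class(out))
  out
}

#' Compare two arms on cost and effectiveness
#'
#' Computes incremental cost and effectiveness, the incremental
#' cost-effectiveness ratio (ICER), net monetary benefit at the
#' willingness-to-pay threshold, and the ICER/WTP ratio. The ICER is
#' undefined (reported `NA`) when incremental effectiveness is zero; when
#' the intervention is cheaper and more effective it is reported as
#' dominant rather than as a negative ratio.
#'
#' @param intervention,comparator One-row tibbles (or lists) carrying
#'   `lifetime_cost` and `lifetime_qaly`, e.g. from [accrue_arm()].
#' @param wtp Willingness-to-pay threshold in CNY per QALY.
#'
#' @return A one-row tibble of class `cea_comparison` with columns
#'   `delta_cost`, `delta_qaly`, `icer`, `dominance`, `nmb`,
#'   `icer_wtp_ratio`, `wtp`.
#' @export
#'
#' @examples
#' a <- tibble::tibble(lifetime_cost = 423817, lifetime_qaly = 2.32)
#' b <- tibble::tibble(lifetime_cost = 28369, lifetime_qaly = 1.80)
#' compare_arms(a, b, wtp = 242928)
compare_arms <- function(intervention, comparator, wtp) {
  dc <- intervention$lifetime_cost[[1]] - comparator$lifetime_cost[[1]]
  dq <- intervention$lifetime_qaly[[1]] - comparator$lifetime_qaly[[1]]
  dominance <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else "none"
  icer <- if (dq != 0 && dominance == "none") dc / dq else NA_real_
  nmb <- wtp * dq - dc
  out <- tibble(
    delta_cost = dc, delta_qaly = dq, icer = icer, dominance = dominance,
    nmb = nmb, icer_wtp_ratio = if (!is.na(icer)) icer / wtp else NA_real_,
    wtp = wtp
  )
  class(out) <- c("cea_comparison", class(out))
  out
}

#' Run the full base-case cost-effectiveness pipeline
#'
#' For each arm: 30-day stage, cohort propagation over the model horizon,
#' discounted accrual; then the pairwise comparison of MitraClip against
#' medical therapy at the configured willingness-to-pay threshold.
#'
#' @param params A `cea_parameters` object.
#'
#' @return An object of class `cea_result`: a list with `arms` (two-row
#'   tibble of arm results), `comparison` (one-row [compare_arms()] tibble)
#'   and `wtp`.
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
#' res <- run_cea(params)
#' glance(res)
run_cea <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  arms <- dplyr::bind_rows(lapply(ARMS, function(arm) {
    stage <- run_stage(params, arm)
    tr <- run_cohort(stage$initial_distribution[[1]],
                     build_transition_matrix(params, arm),
                     params$model$n_cycles)
    accrue_arm(stage, tr, params)
  }))
  comparison <- compare_arms(arms[arms$arm == "mitraclip", ],
                             arms[arms$arm == "omt", ],
                             wtp = params$econ$wtp_threshold)
  structure(list(arms = arms, comparison = comparison,
                 wtp = params$econ$wtp_threshold),
            class = "cea_result")
}

#' Re-price the device without re-running the model
#'
#' The one-time device cost enters the intervention arm's lifetime cost
#' undiscounted at time zero, so changing the device price shifts that cost
#' by exactly the price difference and leaves QALYs unchanged.
#'
#' @param cea A `cea_result` from [run_cea()].
#' @param params The `cea_parameters` used to produce `cea`.
#' @param new_device_cost Non-negative replacement device price (CNY).
#' @param label Optional scenario label.
#'
#' @return A one-row tibble: scenario label, device cost, intervention
#'   lifetime cost and QALY, and the [compare_arms()] columns.
#' @export
scenario_device_price <- function(cea, params, new_device_cost, label = NULL) {
  stopifnot(inherits(cea, "cea_result"))
  if (!is.numeric(new_device_cost) || new_device_cost < 0) {
    abort("`new_device_cost` must be non-negative.")
  }
  shift <- new_device_cost - params$costs$mitraclip_onetime[["device"]]
  iv <- cea$arms[cea$arms$arm == "mitraclip", ]
  om <- cea$arms[cea$arms$arm == "omt", ]
  iv$lifetime_cost <- iv$lifetime_cost + shift
  iv$undiscounted_cost <- iv$undiscounted_cost + shift
  cmp <- compare_arms(iv, om, wtp = cea$wtp)
  dplyr::bind_cols(
    tibble(scenario = label %||% NA_character_,
           device_cost = new_device_cost,
           lifetime_cost = iv$lifetime_cost,
           lifetime_qaly = iv$lifetime_qaly),
    cmp
  )
}

#' Device-price scenario table
#'
#' Runs [scenario_device_price()] for a named vector of device prices
#' (default: the configured regional prices), mirroring the published
#' scenario table layout.
#'
#' @param cea A `cea_result`.
#' @param params The matching `cea_parameters`.
#' @param prices Named numeric vector of device prices; defaults to
#'   `params$scenario_device_costs`.
#'
#' @return A tibble with one row per scenario.
#' @export
scenario_table <- function(cea, params, prices = NULL) {
  prices <- prices %||% params$scenario_device_costs
  if (!length(prices)) abort("No scenario device prices supplied or configured.")
  labels <- names(prices) %||% as.character(seq_along(prices))
  dplyr::bind_rows(purrr::map2(
    as.numeric(prices), labels,
    function(p, l) scenario_device_price(cea, params, p, label = l)
  ))
}

#' Cost-effective device price at a willingness-to-pay threshold
#'
#' Because lifetime cost is affine in the device price, the price at which
#' the ICER equals the threshold has the closed form
#' `price* = device_cost - delta_cost + wtp * delta_qaly`. A negative result
#' means the intervention cannot reach the threshold at any non-negative
#' device price; the result is then flagged with a warning but still
#' returned.
#'
#' @param cea A `cea_result`.
#' @param params The matching `cea_parameters`.
#' @param wtp Willingness-to-pay threshold (defaults to the configured one).
#'
#' @return The threshold device price (CNY), with attribute
#'   `overall_onetime` giving the corresponding total one-time procedure
#'   cost. `NA` (with a warning) if incremental effectiveness is not
#'   positive.
#' @export
threshold_device_price <- function(cea, params, wtp = NULL) {
  stopifnot(inherits(cea, "cea_result"))
  wtp <- wtp %||% cea$wtp
  dq <- cea$comparison$delta_qaly
  if (dq <= 0) {
    warn("Incremental effectiveness is not positive; threshold price undefined.")
    return(NA_real_)
  }
  device <- params$costs$mitraclip_onetime[["device"]]
  price <- device - cea$comparison$delta_cost + wtp * dq
  if (price < 0) {
    warn("Threshold device price is negative: not cost-effective at any non-negative price.")
  }
  structure(price,
            overall_onetime = price + sum(params$costs$mitraclip_onetime) - device)
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> MitraClip vs optimal medical therapy\n\n")
  print(as_tibble(x$arms))
  cat("\n")
  print(as_tibble(x$comparison))
  invisible(x)
}

#' Tidy the per-arm results of a cost-effectiveness run
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return The two-row per-arm tibble.
#' @exportS3Method generics::tidy
tidy.cea_result <- function(x, ...) {
  as_tibble(x$arms)
}

#' One-row summary of a cost-effectiveness run
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A one-row tibble with incremental cost/effectiveness, ICER,
#'   dominance, net monetary benefit, ICER/WTP ratio and the threshold.
#' @exportS3Method generics::glance
glance.cea_result <- function(x, ...) {
  as_tibble(x$comparison)
}
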