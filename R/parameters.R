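#' Path to the shipped base-case configuration
#'
#' The package ships a complete base-case configuration: one-time procedure
#' cost components, monthly medical-therapy and per-event hospitalization
#' costs, monthly NYHA utilities and one-time disutilities, per-arm monthly
#' NYHA transition matrices, economic settings (5% annual discount rate,
#' willingness-to-pay derived as three times per-capita GDP), and the
#' calibrated post-30-day NYHA distributions and per-state monthly
#' hospitalization risks (calibrated quantities are flagged as such in the
#' file).
#'
#' @return File path of the bundled YAML configuration.
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
cea_base_case <- function() {
  system.file("extdata", "paper_base_case.yaml", package = "mitracea",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration document (or an equivalent nested
#' list), validates every field, and returns a fully derived parameter set:
#' the number of Markov cycles is computed from entry and terminal age, the
#' willingness-to-pay threshold is derived as three times per-capita GDP when
#' not given explicitly, uncertainty distributions are moment-matched from
#' their 95% intervals, and beta uncertainty specifications are generated for
#' every structurally nonzero off-diagonal transition probability.
#'
#' @param config File path to a `.yaml`/`.yml`/`.json` document, or a nested
#'   list with the same structure (see the bundled configuration at
#'   [cea_base_case()] for the schema).
#'
#' @return An object of class `cea_parameters`.
#' @export
load_parameters <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' not found.", config))
    config <- read_config_file(config)
  }
  if (!is.list(config)) abort("`config` must be a file path or a nested list.")
  build_parameters(config)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort(sprintf("Unsupported config extension '.%s' (use yaml or json).", ext))
  }
}

#' Write a parameter set back to a configuration document
#'
#' Serializes a `cea_parameters` object to YAML or JSON (by file extension).
#' Reloading the written file with [load_parameters()] reproduces the same
#' parameter set.
#'
#' @param params A `cea_parameters` object.
#' @param path Output file path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cea_parameters"))
  config <- as_config(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    abort(sprintf("Unsupported config extension '.%s' (use yaml or json).", ext))
  }
  invisible(path)
}

required_keys <- function(x, keys, where) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    abort(sprintf("Config section '%s' is missing field(s): %s.",
                  where, paste(missing, collapse = ", ")))
  }
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("Field '%s' must be non-negative and finite.", field))
  }
}

check_prob <- function(x, field, tol = 0) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol)) {
    abort(sprintf("Field '%s' must lie in [0, 1].", field))
  }
}

check_simplex <- function(x, field, tol = 1e-12) {
  check_prob(x, field)
  if (abs(sum(x) - 1) > tol) {
    abort(sprintf("Field '%s' must sum to 1 (got %.15g).", field, sum(x)))
  }
}

onetime_components <- c("device", "procedure", "diagnosis", "medicine",
                        "complications", "ward", "nursing", "others")

build_parameters <- function(config) {
  required_keys(config, c("costs", "utilities", "transitions",
                          "hospitalization_risk", "decision_tree",
                          "economics", "model"), "top level")

  ## -- costs -----------------------------------------------------------
  costs_in <- config$costs
  required_keys(costs_in, c("mitraclip_onetime", "omt_monthly", "hf_hospitalization"),
                "costs")
  required_keys(costs_in$mitraclip_onetime, onetime_components, "costs.mitraclip_onetime")
  onetime <- vapply(onetime_components, function(k) {
    v <- costs_in$mitraclip_onetime[[k]]
    check_nonneg(v, paste0("costs.mitraclip_onetime.", k))
    as.numeric(v)
  }, numeric(1))
  check_nonneg(costs_in$omt_monthly, "costs.omt_monthly")
  check_nonneg(costs_in$hf_hospitalization, "costs.hf_hospitalization")
  costs <- list(mitraclip_onetime = onetime,
                omt_monthly = as.numeric(costs_in$omt_monthly),
                hf_hospitalization = as.numeric(costs_in$hf_hospitalization))
  if (!(sum(onetime) > onetime[["device"]])) {
    abort("Sum of one-time MitraClip cost components must exceed the device cost alone.")
  }

  ## -- utilities -------------------------------------------------------
  ut_in <- config$utilities
  required_keys(ut_in, c("monthly", "disutility"), "utilities")
  required_keys(ut_in$monthly, LIVE_STATES, "utilities.monthly")
  u <- vapply(LIVE_STATES, function(k) as.numeric(ut_in$monthly[[k]]), numeric(1))
  check_prob(u, "utilities.monthly")
  if (any(u > 1 / 12 + 1e-6)) {
    abort("Monthly utilities must not exceed 1/12 (perfect health on a monthly scale).")
  }
  if (any(diff(u) > 1e-12)) {
    abort("Monthly utilities must be non-increasing from NYHA I to NYHA IV.")
  }
  required_keys(ut_in$disutility, c("complications", "procedure", "hf_hospitalization"),
                "utilities.disutility")
  du <- lapply(ut_in$disutility[c("complications", "procedure", "hf_hospitalization")],
               as.numeric)
  for (k in names(du)) check_nonneg(du[[k]], paste0("utilities.disutility.", k))
  utilities <- list(monthly = u, disutility = du, dead = 0)

  ## -- transitions -----------------------------------------------------
  required_keys(config$transitions, ARMS, "transitions")
  transitions <- lapply(setNames(ARMS, ARMS), function(arm) {
    rows <- config$transitions[[arm]]
    required_keys(rows, LIVE_STATES, paste0("transitions.", arm))
    m <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
    for (from in LIVE_STATES) {
      row <- rows[[from]]
      required_keys(row, STATES, paste0("transitions.", arm, ".", from))
      p <- vapply(STATES, function(k) as.numeric(row[[k]]), numeric(1))
      check_prob(p, sprintf("transitions.%s.%s", arm, from))
      if (abs(sum(p) - 1) > 1e-12) {
        abort(sprintf("Transition row 'transitions.%s.%s' must sum to 1 (got %.15g).",
                      arm, from, sum(p)))
      }
      m[from, ] <- p
    }
    m["dead", "dead"] <- 1
    m
  })

  ## -- hospitalization risk -------------------------------------------
  required_keys(config$hospitalization_risk, ARMS, "hospitalization_risk")
  hosp <- lapply(setNames(ARMS, ARMS), function(arm) {
    row <- config$hospitalization_risk[[arm]]
    required_keys(row, LIVE_STATES, paste0("hospitalization_risk.", arm))
    h <- vapply(LIVE_STATES, function(k) as.numeric(row[[k]]), numeric(1))
    check_prob(h, paste0("hospitalization_risk.", arm))
    h
  })

  ## -- decision tree ---------------------------------------------------
  dt_in <- config$decision_tree
  required_keys(dt_in, c("initial_distribution", "thirty_day_mortality"), "decision_tree")
  init <- lapply(setNames(ARMS, ARMS), function(arm) {
    row <- dt_in$initial_distribution[[arm]]
    if (is.null(row)) abort(sprintf("Missing 'decision_tree.initial_distribution.%s'.", arm))
    required_keys(row, LIVE_STATES, paste0("decision_tree.initial_distribution.", arm))
    d <- vapply(LIVE_STATES, function(k) as.numeric(row[[k]]), numeric(1))
    check_simplex(d, paste0("decision_tree.initial_distribution.", arm))
    d
  })
  mort <- lapply(setNames(ARMS, ARMS), function(arm) {
    m <- dt_in$thirty_day_mortality[[arm]] %||% 0
    check_prob(m, paste0("decision_tree.thirty_day_mortality.", arm))
    as.numeric(m)
  })
  decision_tree <- list(initial_distribution = init, thirty_day_mortality = mort)

  ## -- economics -------------------------------------------------------
  ec_in <- config$economics
  required_keys(ec_in, c("annual_discount_rate", "per_capita_gdp",
                         "reporting_exchange_rate", "source_exchange_rate",
                         "cpi_factors"), "economics")
  r <- as.numeric(ec_in$annual_discount_rate)
  if (!is.finite(r) || r < 0 || r > 0.5) {
    abort("Field 'economics.annual_discount_rate' must lie in [0, 0.5].")
  }
  gdp <- as.numeric(ec_in$per_capita_gdp)
  check_nonneg(gdp, "economics.per_capita_gdp")
  wtp <- ec_in$wtp_threshold
  wtp <- if (is.null(wtp)) 3 * gdp else as.numeric(wtp)
  check_nonneg(wtp, "economics.wtp_threshold")
  for (k in c("reporting_exchange_rate", "source_exchange_rate")) {
    v <- as.numeric(ec_in[[k]])
    if (!is.finite(v) || v <= 0) abort(sprintf("Field 'economics.%s' must be > 0.", k))
  }
  cpi <- as.numeric(ec_in$cpi_factors)
  if (any(!is.finite(cpi) | cpi <= 0)) abort("Field 'economics.cpi_factors' must be positive.")
  econ <- list(annual_discount_rate = r,
               per_capita_gdp = gdp,
               wtp_threshold = wtp,
               reporting_exchange_rate = as.numeric(ec_in$reporting_exchange_rate),
               source_exchange_rate = as.numeric(ec_in$source_exchange_rate),
               cpi_factors = cpi)

  ## -- model settings --------------------------------------------------
  md_in <- config$model
  required_keys(md_in, c("entry_age", "terminal_age", "cycle_length_months",
                         "half_cycle_correction"), "model")
  entry <- as.numeric(md_in$entry_age)
  terminal <- as.numeric(md_in$terminal_age)
  cyc <- as.numeric(md_in$cycle_length_months)
  if (terminal <= entry) abort("Field 'model.terminal_age' must exceed 'model.entry_age'.")
  if (cyc <= 0) abort("Field 'model.cycle_length_months' must be positive.")
  n_cycles <- as.integer(round((terminal - entry) * 12 / cyc))
  model <- list(entry_age = entry, terminal_age = terminal,
                cycle_length_months = cyc, n_cycles = n_cycles,
                half_cycle_correction = isTRUE(md_in$half_cycle_correction))

  scenario <- if (!is.null(config$scenario_device_costs)) {
    vapply(config$scenario_device_costs, as.numeric, numeric(1))
  } else numeric()

  params <- structure(
    list(costs = costs, utilities = utilities, transitions = transitions,
         hospitalization_risk = hosp, decision_tree = decision_tree,
         econ = econ, model = model, scenario_device_costs = scenario,
         uncertainty = list()),
    class = "cea_parameters"
  )

  ## -- uncertainty -----------------------------------------------------
  unc <- list()
  for (nm in names(config$uncertainty %||% list())) {
    spec <- config$uncertainty[[nm]]
    required_keys(spec, c("family", "base", "low", "high"), paste0("uncertainty.", nm))
    if (is.na(get_parameter(params, nm, missing_ok = TRUE))) {
      abort(sprintf("Uncertainty entry '%s' does not name a model parameter.", nm))
    }
    unc[[nm]] <- derive_distribution(nm, spec$family, as.numeric(spec$base),
                                     as.numeric(spec$low), as.numeric(spec$high))
  }
  frac <- config$transition_uncertainty$ci_halfwidth_fraction %||% 0.25
  unc <- c(unc, transition_uncertainty(transitions, frac))
  params$uncertainty <- unc
  params$transition_ci_fraction <- frac
  params
}

## Beta uncertainty for every structurally nonzero off-diagonal transition
## probability; the 95% CI is base +/- frac * base (clipped to [0, 1]).
## Structural zeros are never given a distribution and are never perturbed.
transition_uncertainty <- function(transitions, frac) {
  out <- list()
  for (arm in ARMS) {
    m <- transitions[[arm]]
    for (from in LIVE_STATES) {
      for (to in STATES) {
        if (to == from) next
        p <- m[from, to]
        if (p <= 0) next
        nm <- sprintf("tp_%s_%s_%s", arm, from, to)
        out[[nm]] <- derive_distribution(nm, "beta", p,
                                         max(0, p * (1 - frac)),
                                         min(1, p * (1 + frac)))
      }
    }
  }
  out
}

#' Look up a scalar model parameter by name
#'
#' Names follow the configuration schema: `cost_device`, ..., `cost_others`,
#' `cost_omt_monthly`, `cost_hf_hospitalization`, `utility_nyha1` ...
#' `utility_nyha4`, `disutility_complications`, `disutility_procedure`,
#' `disutility_hf_hospitalization`, `discount_rate`,
#' `hosp_<arm>_nyha<k>` for hospitalization risks, and
#' `tp_<arm>_<from>_<to>` for transition probabilities.
#'
#' @param params A `cea_parameters` object.
#' @param name Parameter name.
#' @param missing_ok Return `NA` instead of erroring for unknown names.
#' @return The current scalar value.
#' @export
get_parameter <- function(params, name, missing_ok = FALSE) {
  loc <- locate_parameter(params, name)
  if (is.null(loc)) {
    if (missing_ok) return(NA_real_)
    abort(sprintf("Unknown parameter name '%s'.", name))
  }
  loc$get(params)
}

#' Set a scalar model parameter by name
#'
#' Uses the same naming scheme as [get_parameter()]. Setting a transition
#' probability re-balances the row's diagonal (same-state) entry so the row
#' remains stochastic; structural zeros are untouched.
#'
#' @inheritParams get_parameter
#' @param value New value.
#' @return The updated `cea_parameters` object.
#' @export
set_parameter <- function(params, name, value) {
  loc <- locate_parameter(params, name)
  if (is.null(loc)) abort(sprintf("Unknown parameter name '%s'.", name))
  loc$set(params, value)
}

locate_parameter <- function(params, name) {
  if (name %in% paste0("cost_", onetime_components)) {
    comp <- sub("^cost_", "", name)
    return(list(
      get = function(p) p$costs$mitraclip_onetime[[comp]],
      set = function(p, v) { p$costs$mitraclip_onetime[[comp]] <- v; p }
    ))
  }
  if (name %in% c("cost_omt_monthly", "cost_hf_hospitalization")) {
    slot <- sub("^cost_", "", name)
    return(list(
      get = function(p) p$costs[[slot]],
      set = function(p, v) { p$costs[[slot]] <- v; p }
    ))
  }
  if (name %in% paste0("utility_", LIVE_STATES)) {
    st <- sub("^utility_", "", name)
    return(list(
      get = function(p) p$utilities$monthly[[st]],
      set = function(p, v) { p$utilities$monthly[[st]] <- v; p }
    ))
  }
  if (name %in% c("disutility_complications", "disutility_procedure",
                  "disutility_hf_hospitalization")) {
    slot <- sub("^disutility_", "", name)
    return(list(
      get = function(p) p$utilities$disutility[[slot]],
      set = function(p, v) { p$utilities$disutility[[slot]] <- v; p }
    ))
  }
  if (name == "discount_rate") {
    return(list(
      get = function(p) p$econ$annual_discount_rate,
      set = function(p, v) { p$econ$annual_discount_rate <- v; p }
    ))
  }
  m <- regmatches(name, regexec("^hosp_(mitraclip|omt)_(nyha[1-4])$", name))[[1]]
  if (length(m) == 3L) {
    arm <- m[2]; st <- m[3]
    return(list(
      get = function(p) p$hospitalization_risk[[arm]][[st]],
      set = function(p, v) { p$hospitalization_risk[[arm]][[st]] <- v; p }
    ))
  }
  m <- regmatches(name, regexec("^tp_(mitraclip|omt)_(nyha[1-4])_(nyha[1-4]|dead)$",
                                name))[[1]]
  if (length(m) == 4L) {
    arm <- m[2]; from <- m[3]; to <- m[4]
    return(list(
      get = function(p) p$transitions[[arm]][from, to],
      set = function(p, v) {
        p$transitions[[arm]][from, to] <- v
        p$transitions[[arm]] <- rebalance_row(p$transitions[[arm]], from)
        p
      }
    ))
  }
  NULL
}

## After perturbing off-diagonal entries of one row, absorb the change into
## the same-state (diagonal) entry; if the off-diagonal mass exceeds 1 the
## off-diagonal entries are rescaled and the diagonal set to 0.
rebalance_row <- function(m, from) {
  off <- setdiff(STATES, from)
  s <- sum(m[from, off])
  if (s <= 1) {
    m[from, from] <- 1 - s
  } else {
    m[from, off] <- m[from, off] / s
    m[from, from] <- 0
  }
  m
}

as_config <- function(params) {
  named <- function(x) as.list(setNames(as.numeric(x), names(x)))
  tr <- lapply(params$transitions, function(m) {
    rows <- lapply(LIVE_STATES, function(from) named(m[from, ]))
    setNames(rows, LIVE_STATES)
  })
  unc <- params$uncertainty
  unc <- unc[!grepl("^tp_", names(unc))]
  list(
    costs = list(
      mitraclip_onetime = named(params$costs$mitraclip_onetime),
      omt_monthly = params$costs$omt_monthly,
      hf_hospitalization = params$costs$hf_hospitalization
    ),
    utilities = list(
      monthly = named(params$utilities$monthly),
      disutility = params$utilities$disutility
    ),
    transitions = tr,
    hospitalization_risk = lapply(params$hospitalization_risk, named),
    decision_tree = list(
      initial_distribution = lapply(params$decision_tree$initial_distribution, named),
      thirty_day_mortality = params$decision_tree$thirty_day_mortality
    ),
    economics = list(
      annual_discount_rate = params$econ$annual_discount_rate,
      per_capita_gdp = params$econ$per_capita_gdp,
      wtp_threshold = params$econ$wtp_threshold,
      reporting_exchange_rate = params$econ$reporting_exchange_rate,
      source_exchange_rate = params$econ$source_exchange_rate,
      cpi_factors = params$econ$cpi_factors
    ),
    model = list(
      entry_age = params$model$entry_age,
      terminal_age = params$model$terminal_age,
      cycle_length_months = params$model$cycle_length_months,
      half_cycle_correction = params$model$half_cycle_correction
    ),
    scenario_device_costs = as.list(params$scenario_device_costs),
    transition_uncertainty = list(ci_halfwidth_fraction = params$transition_ci_fraction),
    uncertainty = lapply(unc, function(d) {
      list(family = d$family, base = d$base, low = d$low, high = d$high)
    })
  )
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat(sprintf("  One-time MitraClip cost: %s CNY (device %s)\n",
              format(sum(x$costs$mitraclip_onetime), big.mark = ","),
              format(x$costs$mitraclip_onetime[["device"]], big.mark = ",")))
  cat(sprintf("  OMT %g CNY/month; HF hospitalization %g CNY/event\n",
              x$costs$omt_monthly, x$costs$hf_hospitalization))
  cat(sprintf("  Monthly utilities (NYHA I-IV): %s\n",
              paste(format(x$utilities$monthly), collapse = ", ")))
  cat(sprintf("  Horizon: %d monthly cycles (age %g to %g); half-cycle correction %s\n",
              x$model$n_cycles, x$model$entry_age, x$model$terminal_age,
              if (x$model$half_cycle_correction) "on" else "off"))
  cat(sprintf("  Discount %g%%/year; WTP %s CNY/QALY\n",
              100 * x$econ$annual_discount_rate,
              format(x$econ$wtp_threshold, big.mark = ",")))
  cat(sprintf("  Uncertainty distributions: %d (%d transition entries)\n",
              length(x$uncertainty), sum(grepl("^tp_", names(x$uncertainty)))))
  invisible(x)
}
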