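#' Individual-level microsimulation of one arm
#'
#' Independent Monte Carlo oracle for the cohort engine: each patient draws
#' an entry state from the arm's post-30-day distribution, then steps through
#' the monthly transition matrix; while alive at the end of a cycle the
#' patient accrues that cycle's medical-therapy cost and state utility and a
#' Bernoulli heart-failure hospitalization (independent of the transition,
#' matching the cohort engine's independence assumption). Cost, utility and
#' discounting rules are identical to [accrue_arm()] but events are realized
#' at cycle resolution, i.e. without half-cycle correction; comparisons
#' against the cohort engine should therefore disable the correction there.
#'
#' @param params A `cea_parameters` object.
#' @param arm `"mitraclip"` or `"omt"`.
#' @param n Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @param trajectories Also record every patient's state path (an
#'   `n x (n_cycles + 1)` integer matrix, states 1-4 = NYHA I-IV, 5 = dead,
#'   attached as attribute `"trajectories"`). Off by default; intended for
#'   debugging and empirical transition-frequency checks.
#'
#' @return A one-row tibble of class `cea_microsim` with the arm, `n`, and
#'   mean and Monte Carlo standard error of lifetime cost, QALY, life-years
#'   and hospitalizations.
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
#' simulate_patients(params, "omt", n = 2000, seed = 7)
simulate_patients <- function(params, arm = c("mitraclip", "omt"), n, seed = 1L,
                              trajectories = FALSE) {
  stopifnot(inherits(params, "cea_parameters"))
  arm <- match.arg(arm)
  if (n < 1) abort("`n` must be at least 1.")
  n <- as.integer(n)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  stage <- run_stage(params, arm)
  init <- stage$initial_distribution[[1]]
  m <- unclass(build_transition_matrix(params, arm))
  cum <- t(apply(m, 1L, cumsum))
  h <- params$hospitalization_risk[[arm]]
  n_cycles <- params$model$n_cycles
  disc <- discount_weights(params$econ$annual_discount_rate, n_cycles)
  omt_c <- params$costs$omt_monthly
  hosp_c <- params$costs$hf_hospitalization
  u <- params$utilities$monthly
  du_hosp <- params$utilities$disutility$hf_hospitalization

  ## entry state from the post-stage distribution
  r0 <- runif(n)
  cinit <- cumsum(init)
  state <- 1L + as.integer(rowSums(outer(r0, cinit[1:4], ">")))

  cost <- rep(stage$stage_cost[[1]], n)
  qaly <- rep(-stage$stage_utility_decrement[[1]], n)
  months <- numeric(n)
  events <- numeric(n)
  traj <- if (trajectories) matrix(5L, n, n_cycles + 1L) else NULL
  if (trajectories) traj[, 1L] <- state

  alive <- which(state < 5L)
  for (t in seq_len(n_cycles)) {
    if (!length(alive)) break
    k <- length(alive)
    r <- runif(k)
    cur <- state[alive]
    nxt <- 1L + as.integer(rowSums(cum[cur, 1:4, drop = FALSE] < r))
    state[alive] <- nxt
    if (trajectories) traj[, t + 1L] <- state
    surv <- alive[nxt < 5L]
    if (length(surv)) {
      st <- state[surv]
      hosp <- runif(length(surv)) < h[st]
      cost[surv] <- cost[surv] + disc[t] * (omt_c + hosp * hosp_c)
      qaly[surv] <- qaly[surv] + disc[t] * (u[st] - hosp * du_hosp)
      months[surv] <- months[surv] + 1
      events[surv] <- events[surv] + hosp
    }
    alive <- surv
  }

  msd <- function(x) c(mean(x), stats::sd(x) / sqrt(n))
  cs <- msd(cost); qs <- msd(qaly); ls <- msd(months / 12); es <- msd(events)
  out <- tibble(
    arm = arm, n = n,
    mean_cost = cs[1], se_cost = cs[2],
    mean_qaly = qs[1], se_qaly = qs[2],
    mean_life_years = ls[1], se_life_years = ls[2],
    mean_hospitalizations = es[1], se_hospitalizations = es[2]
  )
  if (trajectories) attr(out, "trajectories") <- traj
  class(out) <- c("cea_microsim", class(out))
  out
}

#' Generate a valid (optionally perturbed) configuration document
#'
#' With `jitter = 0` the shipped base-case configuration is returned
#' unchanged. With `jitter > 0`, cost, utility and disutility base values
#' are moved a random fraction (up to `jitter`) of the distance towards
#' their interval bounds, nonzero off-diagonal transition probabilities are
#' perturbed multiplicatively with rows re-balanced through their same-state
#' entry, and the post-30-day distributions and hospitalization risks are
#' jittered on the log scale and renormalized. All parameter-set invariants
#' (simplexes, row sums, utility ordering) are preserved, so the result
#' always loads.
#'
#' @param seed Integer seed.
#' @param jitter Non-negative perturbation size; 0 reproduces the shipped
#'   base case exactly.
#' @param path Optional output file (`.yaml`/`.yml`/`.json`) to write the
#'   document to.
#'
#' @return The configuration as a nested list (invisibly returns the same
#'   list when `path` is given).
#' @export
#'
#' @examples
#' cfg <- generate_fixture(seed = 42, jitter = 0.2)
#' params <- load_parameters(cfg)
generate_fixture <- function(seed = 1L, jitter = 0, path = NULL) {
  if (jitter < 0) abort("`jitter` must be non-negative.")
  config <- read_config_file(cea_base_case())
  if (jitter > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed))

    move <- function(base, low, high) {
      u <- runif(1, -1, 1)
      v <- if (u >= 0) base + jitter * u * (high - base) else base + jitter * u * (base - low)
      min(max(v, low), high)
    }
    for (nm in names(config$uncertainty)) {
      spec <- config$uncertainty[[nm]]
      if (identical(spec$family, "fixed")) next
      newv <- move(spec$base, spec$low, spec$high)
      config$uncertainty[[nm]]$base <- newv
      config <- assign_config_value(config, nm, newv)
    }
    ## keep monthly utilities non-increasing from NYHA I to IV
    uvals <- unlist(config$utilities$monthly[LIVE_STATES])
    uvals <- sort(uvals, decreasing = TRUE)
    for (i in seq_along(LIVE_STATES)) {
      config$utilities$monthly[[LIVE_STATES[i]]] <- unname(uvals[i])
      config$uncertainty[[paste0("utility_", LIVE_STATES[i])]]$base <- unname(uvals[i])
    }
    for (arm in ARMS) {
      ## transitions: perturb nonzero off-diagonals, re-balance the diagonal
      for (from in LIVE_STATES) {
        row <- unlist(config$transitions[[arm]][[from]][STATES])
        off <- setdiff(STATES, from)
        nz <- off[row[off] > 0]
        row[nz] <- pmin(pmax(row[nz] * (1 + jitter * 0.25 * runif(length(nz), -1, 1)), 0), 1)
        s <- sum(row[off])
        if (s <= 1) row[from] <- 1 - s else { row[off] <- row[off] / s; row[from] <- 0 }
        config$transitions[[arm]][[from]] <- as.list(row)
      }
      d <- unlist(config$decision_tree$initial_distribution[[arm]][LIVE_STATES])
      d <- d * exp(jitter * stats::rnorm(4L, 0, 0.5))
      d <- d / sum(d)
      config$decision_tree$initial_distribution[[arm]] <- as.list(setNames(d, LIVE_STATES))
      h <- unlist(config$hospitalization_risk[[arm]][LIVE_STATES])
      h <- pmin(pmax(h * exp(jitter * stats::rnorm(4L, 0, 0.5)), 0), 1)
      config$hospitalization_risk[[arm]] <- as.list(setNames(h, LIVE_STATES))
    }
  }
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("yaml", "yml")) {
      yaml::write_yaml(config, path, precision = 15L)
    } else if (ext == "json") {
      jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      abort(sprintf("Unsupported config extension '.%s'.", ext))
    }
    return(invisible(config))
  }
  config
}

## Route an uncertainty-parameter name to its location in the raw config.
assign_config_value <- function(config, nm, value) {
  if (nm %in% paste0("cost_", onetime_components)) {
    config$costs$mitraclip_onetime[[sub("^cost_", "", nm)]] <- value
  } else if (nm %in% c("cost_omt_monthly", "cost_hf_hospitalization")) {
    config$costs[[sub("^cost_", "", nm)]] <- value
  } else if (grepl("^utility_nyha[1-4]$", nm)) {
    config$utilities$monthly[[sub("^utility_", "", nm)]] <- value
  } else if (grepl("^disutility_", nm)) {
    config$utilities$disutility[[sub("^disutility_", "", nm)]] <- value
  } else if (nm == "discount_rate") {
    config$economics$annual_discount_rate <- value
  }
  config
}
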