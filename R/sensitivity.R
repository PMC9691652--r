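#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full deterministic pipeline with each parameter set to the
#' low and high end of its 95% interval in turn, all other parameters held
#' at base case, and records the ICER at both ends. By default every
#' non-transition uncertainty parameter is varied (the published tornado
#' varies the cost, utility and discount-rate inputs); transition entries
#' (`tp_*`) can be requested explicitly.
#'
#' @param params A `cea_parameters` object.
#' @param names Character vector of uncertainty parameter names; default all
#'   non-transition entries.
#'
#' @return A tibble of class `cea_tornado`, sorted by decreasing swing, with
#'   columns `parameter`, `low`, `high`, `icer_low`, `icer_high`, `swing`,
#'   and attribute `base_icer`.
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
#' tor <- one_way_sensitivity(params)
#' head(tor, 3)
one_way_sensitivity <- function(params, names = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  names <- names %||% grep("^tp_", base::names(params$uncertainty),
                           value = TRUE, invert = TRUE)
  unknown <- setdiff(names, base::names(params$uncertainty))
  if (length(unknown)) {
    abort(sprintf("No uncertainty specification for: %s.",
                  paste(unknown, collapse = ", ")))
  }
  base_icer <- run_cea(params)$comparison$icer
  rows <- purrr::map(names, function(nm) {
    d <- params$uncertainty[[nm]]
    icer_at <- function(v) run_cea(set_parameter(params, nm, v))$comparison$icer
    lo <- icer_at(d$low)
    hi <- icer_at(d$high)
    tibble(parameter = nm, low = d$low, high = d$high,
           icer_low = lo, icer_high = hi, swing = abs(hi - lo))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$swing))
  attr(out, "base_icer") <- base_icer
  class(out) <- c("cea_tornado", class(out))
  out
}

## Deterministic per-parameter RNG substream: the draw stream of one
## parameter depends only on (master seed, parameter name), so adding or
## removing another parameter leaves it unchanged.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) + sum(codes) * 131L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its moment-matched distribution
#' (gamma for costs, beta for utilities, disutilities and transition
#' probabilities; `fixed` entries are never drawn), re-evaluates the full
#' pipeline per draw, and records per-arm and incremental outcomes. After
#' perturbing the nonzero off-diagonal transition probabilities, each row's
#' same-state entry absorbs the change so rows remain stochastic and
#' structural zeros stay zero. Draws use per-parameter substreams derived
#' from `seed`, so results are reproducible and adding a parameter does not
#' shift the others' draws.
#'
#' @param params A `cea_parameters` object.
#' @param n_iter Number of Monte Carlo iterations (default 10,000, the
#'   published iteration count).
#' @param seed Integer master seed.
#'
#' @return A tibble of class `cea_psa` with one row per draw: `draw`, the
#'   drawn parameter values, `cost_mitraclip`, `qaly_mitraclip`, `cost_omt`,
#'   `qaly_omt`, `delta_cost`, `delta_qaly`, `icer`. Attribute `wtp` carries
#'   the threshold.
#' @export
run_psa <- function(params, n_iter = 10000L, seed = 1L) {
  stopifnot(inherits(params, "cea_parameters"))
  if (n_iter < 1) abort("`n_iter` must be at least 1.")
  n_iter <- as.integer(n_iter)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  unc <- params$uncertainty
  drawn <- unc[vapply(unc, function(d) d$family != "fixed", logical(1))]
  draws <- matrix(0, n_iter, length(drawn),
                  dimnames = list(NULL, names(drawn)))
  for (nm in names(drawn)) {
    set.seed(substream_seed(seed, nm))
    draws[, nm] <- sample_distribution(drawn[[nm]], n_iter)
  }

  n <- params$model$n_cycles
  half <- params$model$half_cycle_correction
  disc <- discount_weights(params$econ$annual_discount_rate, n)
  init <- lapply(setNames(ARMS, ARMS), function(a) {
    run_stage(params, a)$initial_distribution[[1]]
  })
  h_risk <- params$hospitalization_risk
  base_m <- params$transitions
  tp_names <- grep("^tp_", colnames(draws), value = TRUE)
  tp_idx <- lapply(tp_names, function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    list(arm = parts[2], from = parts[3], to = parts[4])
  })
  cost_names <- paste0("cost_", onetime_components)

  col <- function(nm, default) if (nm %in% colnames(draws)) draws[, nm] else rep(default, n_iter)
  omt_d <- col("cost_omt_monthly", params$costs$omt_monthly)
  chosp_d <- col("cost_hf_hospitalization", params$costs$hf_hospitalization)
  onetime_d <- rowSums(matrix(unlist(lapply(seq_along(cost_names), function(i) {
    col(cost_names[i], params$costs$mitraclip_onetime[[i]])
  })), nrow = n_iter))
  u_d <- matrix(unlist(lapply(LIVE_STATES, function(st) {
    col(paste0("utility_", st), params$utilities$monthly[[st]])
  })), nrow = n_iter)
  du_proc_d <- col("disutility_procedure", params$utilities$disutility$procedure)
  du_comp_d <- col("disutility_complications", params$utilities$disutility$complications)
  du_hosp_d <- col("disutility_hf_hospitalization",
                   params$utilities$disutility$hf_hospitalization)

  out <- matrix(NA_real_, n_iter, 6,
                dimnames = list(NULL, c("cost_mitraclip", "qaly_mitraclip",
                                        "cost_omt", "qaly_omt",
                                        "delta_cost", "delta_qaly")))
  for (i in seq_len(n_iter)) {
    mats <- base_m
    for (k in seq_along(tp_idx)) {
      ix <- tp_idx[[k]]
      mats[[ix$arm]][ix$from, ix$to] <- draws[i, tp_names[k]]
    }
    for (arm in ARMS) {
      for (from in LIVE_STATES) mats[[arm]] <- rebalance_row(mats[[arm]], from)
    }
    u_i <- u_d[i, ]
    res <- lapply(ARMS, function(arm) {
      stage_cost <- if (arm == "mitraclip") onetime_d[i] + omt_d[i] else omt_d[i]
      stage_dec <- if (arm == "mitraclip") du_proc_d[i] + du_comp_d[i] else 0
      tr <- markov_trace(init[[arm]], mats[[arm]], n)
      accrue_core(tr, h_risk[[arm]], stage_cost, stage_dec, omt_d[i],
                  chosp_d[i], u_i, du_hosp_d[i], disc, half)
    })
    out[i, ] <- c(res[[1]]$lifetime_cost, res[[1]]$lifetime_qaly,
                  res[[2]]$lifetime_cost, res[[2]]$lifetime_qaly,
                  res[[1]]$lifetime_cost - res[[2]]$lifetime_cost,
                  res[[1]]$lifetime_qaly - res[[2]]$lifetime_qaly)
  }

  samples <- dplyr::bind_cols(
    tibble(draw = seq_len(n_iter)),
    as_tibble(draws),
    as_tibble(out)
  )
  samples$icer <- ifelse(samples$delta_qaly != 0,
                         samples$delta_cost / samples$delta_qaly, NA_real_)
  attr(samples, "wtp") <- params$econ$wtp_threshold
  attr(samples, "seed") <- as.integer(seed)
  class(samples) <- c("cea_psa", class(samples))
  samples
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the acceptability of the intervention
#' is the fraction of PSA draws with positive net monetary benefit
#' (`wtp * delta_qaly - delta_cost > 0`). In a two-strategy comparison the
#' comparator's acceptability is the complement.
#'
#' @param samples A `cea_psa` tibble from [run_psa()] (or any data frame
#'   with `delta_cost` and `delta_qaly`).
#' @param wtp_grid Numeric vector of thresholds; default 0 to 1,500,000
#'   CNY/QALY in 10,000-CNY steps.
#'
#' @return A tibble of class `cea_ceac` with columns `wtp`, `acceptability`
#'   (intervention) and `acceptability_comparator`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 1.5e6, by = 1e4)) {
  if (nrow(samples) == 0L) abort("`samples` must contain at least one draw.")
  if (length(wtp_grid) == 0L) {
    out <- tibble(wtp = numeric(), acceptability = numeric(),
                  acceptability_comparator = numeric())
    class(out) <- c("cea_ceac", class(out))
    return(out)
  }
  acc <- vapply(wtp_grid, function(w) {
    mean(w * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  out <- tibble(wtp = wtp_grid, acceptability = acc,
                acceptability_comparator = 1 - acc)
  class(out) <- c("cea_ceac", class(out))
  out
}

#' Willingness-to-pay at which the intervention reaches a given acceptability
#'
#' Linear interpolation of the acceptability curve at its first upward
#' crossing of `level` (default 0.5, where the two strategies are equally
#' likely to be preferred).
#'
#' @param curve A `cea_ceac` tibble.
#' @param level Acceptability level to locate.
#' @return The interpolated willingness-to-pay, or `NA` if the curve never
#'   reaches `level`.
#' @export
ceac_crossover <- function(curve, level = 0.5) {
  above <- which(curve$acceptability >= level)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(curve$wtp[1])
  x0 <- curve$wtp[i - 1]; x1 <- curve$wtp[i]
  y0 <- curve$acceptability[i - 1]; y1 <- curve$acceptability[i]
  if (y1 == y0) return(x1)
  x0 + (level - y0) / (y1 - y0) * (x1 - x0)
}

#' Tidy PSA samples
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return The sample tibble without its class decoration.
#' @exportS3Method generics::tidy
tidy.cea_psa <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cea_psa")
  as_tibble(out)
}

#' One-row PSA summary
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return One-row tibble with draw count, mean incremental cost and
#'   effectiveness, and acceptability at the configured threshold.
#' @exportS3Method generics::glance
glance.cea_psa <- function(x, ...) {
  wtp <- attr(x, "wtp")
  tibble(
    n_draws = nrow(x),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_qaly = mean(x$delta_qaly),
    acceptability_at_wtp = mean(wtp * x$delta_qaly - x$delta_cost > 0),
    wtp = wtp
  )
}
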