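#' Base-case outcome summary used as calibration targets
#'
#' Runs the full pipeline and returns the named scalar outcomes that
#' [calibrate_parameters()] can fit: per-arm life-years, expected
#' hospitalizations, discounted lifetime QALYs and costs, plus the ICER.
#'
#' @param params A `cea_parameters` object.
#' @return A named numeric vector with entries `life_years_<arm>`,
#'   `hospitalizations_<arm>`, `lifetime_qaly_<arm>`, `lifetime_cost_<arm>`
#'   (for `mitraclip` and `omt`) and `icer`.
#' @export
cea_targets <- function(params) {
  res <- run_cea(params)
  a <- res$arms
  out <- c()
  for (arm in ARMS) {
    row <- a[a$arm == arm, ]
    out[paste0("life_years_", arm)] <- row$life_years
    out[paste0("hospitalizations_", arm)] <- row$hospitalizations
    out[paste0("lifetime_qaly_", arm)] <- row$lifetime_qaly
    out[paste0("lifetime_cost_", arm)] <- row$lifetime_cost
  }
  out["icer"] <- res$comparison$icer
  out
}

## Per-start-state occupancy summaries for one arm. Because the cohort trace
## is linear in the entry distribution and the accruals are linear in both
## the entry distribution and the hospitalization risks, every calibration
## target is a bilinear form in the free parameters; precomputing these
## summaries makes one objective evaluation a handful of dot products.
arm_summaries <- function(params, arm) {
  n <- params$model$n_cycles
  half <- params$model$half_cycle_correction
  disc <- discount_weights(params$econ$annual_discount_rate, n)
  m <- params$transitions[[arm]]
  u <- params$utilities$monthly
  L <- A <- Qu <- numeric(4)
  E <- Ed <- matrix(0, 4, 4)
  for (s in 1:4) {
    init <- numeric(5); init[s] <- 1
    tr <- markov_trace(init, m, n)
    occ <- effective_occupancy(tr, half)
    alive <- rowSums(occ)
    L[s] <- sum(alive) / 12
    A[s] <- sum(disc * alive)
    Qu[s] <- sum(disc * as.numeric(occ %*% u))
    E[s, ] <- colSums(occ)
    Ed[s, ] <- colSums(disc * occ)
  }
  stage <- run_stage(params, arm)
  list(L = L, A = A, Qu = Qu, E = E, Ed = Ed,
       stage_cost = stage$stage_cost[[1]],
       stage_dec = stage$stage_utility_decrement[[1]],
       mort = params$decision_tree$thirty_day_mortality[[arm]])
}

arm_outcomes_bilinear <- function(sm, init4, h, params) {
  w <- (1 - sm$mort) * init4
  ev_d <- sum(w * as.numeric(sm$Ed %*% h))
  c(life_years = sum(w * sm$L),
    hospitalizations = sum(w * as.numeric(sm$E %*% h)),
    lifetime_qaly = sum(w * sm$Qu) -
      params$utilities$disutility$hf_hospitalization * ev_d - sm$stage_dec,
    lifetime_cost = sm$stage_cost + params$costs$omt_monthly * sum(w * sm$A) +
      params$costs$hf_hospitalization * ev_d)
}

softmax4 <- function(x3) {
  e <- exp(c(0, x3) - max(0, x3))
  e / sum(e)
}

inv_softmax4 <- function(p, eps = 1e-6) {
  p <- pmax(p, eps)
  log(p[2:4] / p[1])
}

## Ordered probabilities on the logit scale: non-decreasing in NYHA class.
ordered_probs <- function(x4) {
  stats::plogis(cumsum(c(x4[1], log1p(exp(pmin(x4[2:4], 30))))))
}

inv_ordered_probs <- function(h, eps = 1e-6) {
  h <- pmin(pmax(h, eps), 1 - eps)
  z <- stats::qlogis(h)
  d <- pmax(diff(z), eps)
  c(z[1], log(expm1(d)))
}

calibration_blocks <- function(free) {
  blocks <- list()
  for (nm in free) {
    if (grepl("^init_(mitraclip|omt)$", nm)) {
      arm <- sub("^init_", "", nm)
      blocks[[nm]] <- list(kind = "init", arm = arm, n = 3L)
    } else if (grepl("^hosp_(mitraclip|omt)$", nm)) {
      arm <- sub("^hosp_", "", nm)
      blocks[[nm]] <- list(kind = "hosp", arm = arm, n = 4L)
    } else if (grepl("^hosp_(mitraclip|omt)_nyha[1-4]$", nm)) {
      parts <- strsplit(nm, "_")[[1]]
      blocks[[nm]] <- list(kind = "hosp1", arm = parts[2],
                           state = parts[3], n = 1L)
    } else {
      abort(sprintf(paste0("Unknown free parameter '%s' (use init_<arm>, ",
                           "hosp_<arm>, or hosp_<arm>_nyha<k>)."), nm))
    }
  }
  blocks
}

#' Calibrate unreported parameters to published outcomes
#'
#' The post-30-day NYHA distributions and the per-state monthly
#' hospitalization risks are not published; this bounded least-squares fit
#' adjusts them so the model reproduces reported lifetime outcomes.
#' Initial distributions are optimized on the simplex (softmax transform);
#' whole-arm hospitalization-risk blocks are constrained non-decreasing in
#' NYHA class (ordered logit transform), while individually named risks are
#' fitted freely in \[0, 1\]. The objective is the sum of squared relative
#' errors over the targets. The first optimizer start is the current
#' parameter values; further starts are randomized from `seed`.
#'
#' @param params A `cea_parameters` object.
#' @param targets Named numeric vector; names as in [cea_targets()].
#' @param free Character vector of free parameter blocks: `init_<arm>`,
#'   `hosp_<arm>`, or individual `hosp_<arm>_nyha<k>` entries. Empty means
#'   nothing is fitted and `params` is returned unchanged.
#' @param seed Integer seed for the randomized restarts.
#' @param n_starts Number of optimizer starts (>= 1).
#'
#' @return An object of class `cea_calibration`: list with `params` (updated
#'   parameter set), `report` (tibble: target, goal, fitted, rel_error),
#'   `value` (objective at the optimum) and `convergence` (0 = converged).
#' @export
#'
#' @examples
#' params <- load_parameters(cea_base_case())
#' fit <- calibrate_parameters(
#'   params,
#'   targets = c(hospitalizations_mitraclip = 1.16, hospitalizations_omt = 1.51),
#'   free = c("hosp_mitraclip_nyha3", "hosp_omt_nyha3"),
#'   n_starts = 5
#' )
#' tidy(fit)
calibrate_parameters <- function(params, targets, free, seed = 1L, n_starts = 25L) {
  stopifnot(inherits(params, "cea_parameters"))
  if (length(free) == 0L) {
    current <- cea_targets(params)[names(targets)]
    report <- tibble(target = names(targets), goal = unname(targets),
                     fitted = unname(current),
                     rel_error = unname((current - targets) / targets))
    return(structure(list(params = params, report = report,
                          value = sum(report$rel_error^2), convergence = 0L),
                     class = "cea_calibration"))
  }
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    abort("`targets` must be a fully named numeric vector.")
  }
  known <- c(outer(c("life_years_", "hospitalizations_", "lifetime_qaly_",
                     "lifetime_cost_"), ARMS, paste0), "icer")
  bad <- setdiff(names(targets), known)
  if (length(bad)) {
    abort(sprintf("Unknown target(s): %s.", paste(bad, collapse = ", ")))
  }
  blocks <- calibration_blocks(free)

  sm <- lapply(setNames(ARMS, ARMS), function(a) arm_summaries(params, a))
  state0 <- list(
    init = params$decision_tree$initial_distribution,
    h = params$hospitalization_risk
  )

  apply_x <- function(x) {
    st <- state0
    i <- 0L
    for (b in blocks) {
      xs <- x[(i + 1L):(i + b$n)]
      i <- i + b$n
      if (b$kind == "init") st$init[[b$arm]] <- softmax4(xs)
      else if (b$kind == "hosp") st$h[[b$arm]] <- setNames(ordered_probs(xs), LIVE_STATES)
      else st$h[[b$arm]][[b$state]] <- stats::plogis(xs)
    }
    st
  }

  outcomes_of <- function(st) {
    out <- c()
    for (arm in ARMS) {
      o <- arm_outcomes_bilinear(sm[[arm]], st$init[[arm]], st$h[[arm]], params)
      names(o) <- paste0(names(o), "_", arm)
      out <- c(out, o)
    }
    out["icer"] <- (out["lifetime_cost_mitraclip"] - out["lifetime_cost_omt"]) /
      (out["lifetime_qaly_mitraclip"] - out["lifetime_qaly_omt"])
    out
  }

  objective <- function(x) {
    got <- outcomes_of(apply_x(x))[names(targets)]
    sum(((got - targets) / targets)^2)
  }

  x0 <- unlist(lapply(blocks, function(b) {
    if (b$kind == "init") inv_softmax4(state0$init[[b$arm]])
    else if (b$kind == "hosp") inv_ordered_probs(state0$h[[b$arm]])
    else stats::qlogis(min(max(state0$h[[b$arm]][[b$state]], 1e-6), 1 - 1e-6))
  }), use.names = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  best <- NULL
  for (k in seq_len(max(1L, n_starts))) {
    start <- if (k == 1L) x0 else x0 + stats::rnorm(length(x0), 0, 2)
    fit <- tryCatch(
      optim(start, objective, method = "BFGS", control = list(maxit = 500L)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("Calibration optimizer failed for every start.")

  st <- apply_x(best$par)
  params$decision_tree$initial_distribution <- lapply(st$init, function(p) {
    setNames(p / sum(p), LIVE_STATES)
  })
  params$hospitalization_risk <- lapply(st$h, function(h) setNames(pmin(pmax(h, 0), 1), LIVE_STATES))

  achieved <- cea_targets(params)[names(targets)]
  report <- tibble(target = names(targets), goal = unname(targets),
                   fitted = unname(achieved),
                   rel_error = unname((achieved - targets) / targets))
  structure(list(params = params, report = report, value = best$value,
                 convergence = best$convergence),
            class = "cea_calibration")
}

#' @export
print.cea_calibration <- function(x, ...) {
  cat(sprintf("<cea_calibration> objective %.4g, convergence code %d\n",
              x$value, x$convergence))
  print(x$report)
  invisible(x)
}

#' Tidy a calibration fit report
#'
#' @param x A `cea_calibration`.
#' @param ... Unused.
#' @return The per-target fit report tibble.
#' @exportS3Method generics::tidy
tidy.cea_calibration <- function(x, ...) x$report

#' One-row calibration summary
#'
#' @param x A `cea_calibration`.
#' @param ... Unused.
#' @return One-row tibble with the objective value, convergence code and
#'   worst absolute relative error.
#' @exportS3Method generics::glance
glance.cea_calibration <- function(x, ...) {
  tibble(objective = x$value, convergence = x$convergence,
         max_abs_rel_error = max(abs(x$report$rel_error)))
}
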