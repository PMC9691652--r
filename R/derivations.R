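#' Weighted mean of cost components
#'
#' Pools subgroup cost estimates into a single mean, weighting each value by
#' its subgroup size. This is the arithmetic used to combine published
#' per-subgroup costs (e.g. medical-therapy cost strata) into one model input.
#'
#' @param values Numeric vector of values (e.g. costs in CNY).
#' @param weights Numeric vector of non-negative weights, same length as
#'   `values`, not all zero.
#'
#' @return The weighted mean as a single number.
#' @export
#'
#' @examples
#' weighted_mean(c(679, 711.1), c(14.5, 19.2))
weighted_mean <- function(values, weights) {
  if (length(values) == 0L) {
    abort("`values` must contain at least one element.")
  }
  if (length(values) != length(weights)) {
    abort("`values` and `weights` must have equal length.")
  }
  if (any(!is.finite(values)) || any(!is.finite(weights))) {
    abort("`values` and `weights` must be finite.")
  }
  if (any(weights < 0)) {
    abort("`weights` must be non-negative.")
  }
  if (sum(weights) == 0) {
    abort("`weights` must not all be zero.")
  }
  stats::weighted.mean(values, weights)
}

#' Inflate a cost along a chain of CPI factors
#'
#' Multiplies a cost by an ordered sequence of annual healthcare
#' consumer-price-index factors, bringing a historical cost to the analysis
#' year.
#'
#' @param amount Non-negative cost.
#' @param factors Numeric vector of positive annual multipliers (possibly
#'   empty).
#'
#' @return `amount * prod(factors)`.
#' @export
#'
#' @examples
#' inflate_cpi(100, c(1.043, 1.024, 1.018, 1.004))
inflate_cpi <- function(amount, factors = numeric()) {
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount) || amount < 0) {
    abort("`amount` must be a single non-negative number.")
  }
  if (length(factors) && any(!is.finite(factors) | factors <= 0)) {
    abort("`factors` must all be positive.")
  }
  amount * prod(factors)
}

#' Convert a CNY amount to USD
#'
#' @param amount Amount in CNY.
#' @param rate Exchange rate in CNY per USD (> 0).
#'
#' @return Amount in USD.
#' @export
#'
#' @examples
#' convert_currency(322000, 6.45)
convert_currency <- function(amount, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number.")
  }
  amount / rate
}

#' Convert an annual quantity to its monthly equivalent
#'
#' Annual costs and utilities enter the monthly-cycle model as `x / 12`.
#'
#' @param annual Annual value.
#' @return `annual / 12`.
#' @export
monthly_from_annual <- function(annual) {
  annual / 12
}

#' Derive an uncertainty distribution from a base value and 95% interval
#'
#' Turns a published point estimate with a 95% interval into a parametric
#' sampling distribution by moment matching. The interval is read as a
#' symmetric 95% confidence interval, so the standard error is
#' `(high - low) / (2 * 1.96)`. Costs use a gamma distribution
#' (`shape = base^2 / se^2`, `rate = base / se^2`); probabilities and
#' utilities use a beta distribution with method-of-moments `alpha`, `beta`
#' from mean `base` and variance `se^2`. `low == high` yields a degenerate
#' point mass (`family = "fixed"`).
#'
#' @param name Parameter name (carried through for reporting).
#' @param family One of `"gamma"`, `"beta"`, `"fixed"`.
#' @param base Base-case value.
#' @param low,high Lower and upper 95% interval bounds, `low <= base <= high`.
#'
#' @return A list of class `cea_distribution` with elements `name`, `family`,
#'   `base`, `low`, `high`, `se`, and family-specific shape parameters
#'   (`shape`/`rate` for gamma, `alpha`/`beta` for beta).
#' @export
#'
#' @examples
#' derive_distribution("device", "gamma", 322000, 161000, 386400)
derive_distribution <- function(name, family, base, low, high) {
  family <- match.arg(family, c("gamma", "beta", "fixed"))
  if (!(low <= base && base <= high)) {
    abort(sprintf("Parameter '%s': need low <= base <= high.", name))
  }
  if (low == high) family <- "fixed"
  se <- (high - low) / (2 * 1.96)
  out <- list(name = name, family = family, base = base,
              low = low, high = high, se = se)
  if (family == "gamma") {
    if (base < 0) abort(sprintf("Parameter '%s': gamma requires a non-negative base.", name))
    if (base == 0) abort(sprintf("Parameter '%s': gamma requires a positive base.", name))
    out$shape <- base^2 / se^2
    out$rate <- base / se^2
  } else if (family == "beta") {
    if (base <= 0 || base >= 1) {
      abort(sprintf("Parameter '%s': beta requires base in (0, 1).", name))
    }
    v <- se^2
    if (v >= base * (1 - base)) {
      abort(sprintf("Parameter '%s': beta variance %.3g is infeasible for mean %.3g.",
                    name, v, base))
    }
    k <- base * (1 - base) / v - 1
    out$alpha <- base * k
    out$beta <- (1 - base) * k
  }
  structure(out, class = "cea_distribution")
}

#' Sample from a derived uncertainty distribution
#'
#' @param dist A `cea_distribution` from [derive_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; for `family = "fixed"` the base value
#'   is repeated.
#' @export
sample_distribution <- function(dist, n) {
  stopifnot(inherits(dist, "cea_distribution"))
  switch(dist$family,
    gamma = rgamma(n, shape = dist$shape, rate = dist$rate),
    beta  = rbeta(n, shape1 = dist$alpha, shape2 = dist$beta),
    fixed = rep(dist$base, n)
  )
}

#' @export
print.cea_distribution <- function(x, ...) {
  extra <- switch(x$family,
    gamma = sprintf("shape = %.4g, rate = %.4g", x$shape, x$rate),
    beta  = sprintf("alpha = %.4g, beta = %.4g", x$alpha, x$beta),
    fixed = "point mass"
  )
  cat(sprintf("<cea_distribution> %s: %s(base = %g, 95%% CI %g-%g; %s)\n",
              x$name, x$family, x$base, x$low, x$high, extra))
  invisible(x)
}
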