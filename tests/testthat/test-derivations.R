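test_that("weighted_mean pools subgroup costs and rejects degenerate input", {
  # hand evaluation: (679*14.5 + 711.1*19.2) / (14.5 + 19.2)
  expect_equal(weighted_mean(c(679, 711.1), c(14.5, 19.2)),
               (679 * 14.5 + 711.1 * 19.2) / 33.7, tolerance = 1e-12)
  expect_equal(round(weighted_mean(c(679, 711.1), c(14.5, 19.2)), 2), 697.29)
  expect_equal(weighted_mean(42, 3), 42)
  # hand evaluation: (1218.4*18.35 + 1646.8*29.6) / (18.35 + 29.6)
  expect_equal(weighted_mean(c(1218.4, 1646.8), c(18.35, 29.6)),
               (1218.4 * 18.35 + 1646.8 * 29.6) / 47.95, tolerance = 1e-12)
  expect_error(weighted_mean(numeric(), numeric()), "at least one")
  expect_error(weighted_mean(c(1, 2), c(0, 0)), "zero")
  expect_error(weighted_mean(c(1, 2), 1), "equal length")
  expect_error(weighted_mean(c(1, 2), c(-1, 2)), "non-negative")
})

test_that("CPI inflation chain reproduces the published annual OMT and hospitalization costs", {
  expect_equal(inflate_cpi(100), 100)
  expect_equal(inflate_cpi(100, 1.05), 105)
  chain <- c(1.043, 1.024, 1.018, 1.004)
  omt_annual <- inflate_cpi(weighted_mean(c(679, 711.1), c(14.5, 19.2)) * 6.75, chain)
  expect_equal(round(omt_annual), 5138)
  expect_equal(round(monthly_from_annual(omt_annual)), 428)
  hosp <- inflate_cpi(weighted_mean(c(1218.4, 1646.8), c(18.35, 29.6)) * 6.75, chain)
  expect_equal(round(hosp), 10926)
  expect_error(inflate_cpi(-1), "non-negative")
  expect_error(inflate_cpi(10, c(1.05, 0)), "positive")
})

test_that("CPI inflation is invariant under permutation of the factors", {
  set.seed(11)
  for (i in 1:20) {
    f <- runif(6, 0.9, 1.1)
    expect_equal(inflate_cpi(123.4, f), inflate_cpi(123.4, sample(f)),
                 tolerance = 1e-9)
  }
})

test_that("currency conversion reproduces the published USD figures", {
  expect_equal(round(convert_currency(322000, 6.45)), 49922)
  expect_equal(convert_currency(0, 6.45), 0)
  expect_lt(abs(convert_currency(754410, 6.45) - 116963), 1)
  expect_error(convert_currency(100, 0), "positive")
  expect_error(convert_currency(100, -2), "positive")
})

test_that("annual-to-monthly conversion matches the published NYHA I utility", {
  expect_equal(monthly_from_annual(0.780), 0.065)
  expect_equal(round(monthly_from_annual(0.780), 3), 0.065)
})

test_that("moment matching derives gamma and beta shapes from 95% intervals", {
  d <- derive_distribution("device", "gamma", 322000, 161000, 386400)
  # hand evaluation of the moment-matching formulas
  expect_equal(d$se, (386400 - 161000) / (2 * 1.96))
  expect_equal(d$se, 57500)
  expect_equal(d$shape, 322000^2 / 57500^2, tolerance = 1e-12)
  expect_equal(d$shape, 31.36, tolerance = 1e-3)
  expect_equal(d$rate, 322000 / 57500^2, tolerance = 1e-12)
  expect_equal(d$rate, 9.74e-5, tolerance = 1e-3)

  b <- derive_distribution("u_nyha1", "beta", 0.065, 0.062, 0.068)
  expect_equal(b$se, 0.006 / 3.92)
  # method-of-moments beta has the requested mean and variance
  expect_equal(b$alpha / (b$alpha + b$beta), 0.065, tolerance = 1e-12)
  v <- b$alpha * b$beta / ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1))
  expect_equal(v, b$se^2, tolerance = 1e-12)

  f <- derive_distribution("x", "fixed", 5, 5, 5)
  expect_identical(f$family, "fixed")
  expect_identical(sample_distribution(f, 3), c(5, 5, 5))
  # degenerate interval collapses any family to a point mass
  g <- derive_distribution("x", "gamma", 5, 5, 5)
  expect_identical(g$family, "fixed")

  expect_error(derive_distribution("bad", "gamma", 2, 3, 4), "low <= base <= high")
  expect_error(derive_distribution("bad", "beta", 1.2, 1.1, 1.3), "\\(0, 1\\)")
  expect_error(derive_distribution("bad", "beta", 0.5, -10, 10), "infeasible")
})

test_that("sampling each shipped uncertainty distribution recovers its base value", {
  set.seed(2024)
  n <- 1e5
  unc <- BASE_PARAMS$uncertainty
  unc <- unc[vapply(unc, function(d) d$family != "fixed", logical(1))]
  for (d in unc) {
    x <- sample_distribution(d, n)
    # distribution sd equals the moment-matched se, so the Monte Carlo
    # standard error of the mean is se/sqrt(n)
    expect_lt(abs(mean(x) - d$base), 3 * d$se / sqrt(n) + 1e-12)
  }
})
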