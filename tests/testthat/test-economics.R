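test_that("annual discount rates convert to compound monthly factors", {
  expect_equal(monthly_discount_factor(0), 0)
  expect_equal(monthly_discount_factor(0.05), 1.05^(1 / 12) - 1, tolerance = 1e-12)
  expect_equal(monthly_discount_factor(0.05), 0.0040741, tolerance = 1e-3)
  expect_equal(monthly_discount_factor(0.08), 0.0064340, tolerance = 1e-3)
  expect_error(monthly_discount_factor(-0.01), "non-negative")
})

test_that("with utility 1/12, no discounting and no events, QALYs equal life-years", {
  p <- BASE_PARAMS
  p$utilities$monthly[] <- 1 / 12
  p$utilities$disutility <- list(complications = 0, procedure = 0,
                                 hf_hospitalization = 0)
  p$hospitalization_risk <- lapply(p$hospitalization_risk, function(h) h * 0)
  p$econ$annual_discount_rate <- 0
  res <- run_cea(p)
  expect_equal(res$arms$lifetime_qaly, res$arms$life_years, tolerance = 1e-12)
})

test_that("a two-cycle chain accrues the enumerated expected cost", {
  # Single live state, death probability 1/2 per cycle, 100 CNY per cycle,
  # no discounting, end-of-cycle accrual (no half-cycle correction).
  # Enumeration over the outcome tree: alive after cycle 1 w.p. 1/2 (pay
  # 100), alive after cycle 2 w.p. 1/4 (pay 100) -> expected Markov-phase
  # cost 75 on top of the one-time stage cost.
  p <- single_state_params(0.5, omt_monthly = 100, discount = 0, half_cycle = FALSE)
  p$hospitalization_risk <- lapply(p$hospitalization_risk, function(h) h * 0)
  stage <- run_stage(p, "omt")
  tr <- run_cohort(stage$initial_distribution[[1]],
                   build_transition_matrix(p, "omt"), 2)
  res <- accrue_arm(stage, tr, p)
  enumeration <- 100 * 0.5 + 100 * 0.25
  expect_equal(res$lifetime_cost, stage$stage_cost + enumeration, tolerance = 1e-12)
  expect_equal(res$undiscounted_cost, res$lifetime_cost, tolerance = 1e-12)
})

test_that("discounted cost never exceeds undiscounted cost", {
  res <- run_cea(BASE_PARAMS)
  expect_true(all(res$arms$lifetime_cost <= res$arms$undiscounted_cost))
  expect_true(all(res$arms$lifetime_cost >= 0))
  expect_true(all(res$arms$lifetime_qaly >= 0))
})

test_that("arm comparison reproduces published incremental arithmetic", {
  a <- tibble::tibble(lifetime_cost = 423817, lifetime_qaly = 2.32)
  b <- tibble::tibble(lifetime_cost = 28369, lifetime_qaly = 1.80)
  cmp <- compare_arms(a, b, wtp = 242928)
  expect_identical(cmp$delta_cost, 423817 - 28369)
  expect_identical(cmp$delta_cost, 395448)
  expect_equal(cmp$icer, cmp$delta_cost / cmp$delta_qaly, tolerance = 1e-12)
  expect_equal(cmp$nmb, 242928 * cmp$delta_qaly - cmp$delta_cost, tolerance = 1e-12)

  same <- compare_arms(a, a, wtp = 242928)
  expect_identical(same$delta_cost, 0)
  expect_identical(same$delta_qaly, 0)
  expect_true(is.na(same$icer))

  toy <- compare_arms(tibble::tibble(lifetime_cost = 100, lifetime_qaly = 0.5),
                      tibble::tibble(lifetime_cost = 0, lifetime_qaly = 0),
                      wtp = 300)
  expect_equal(toy$icer, 200)
  expect_equal(toy$nmb, 50)

  dom <- compare_arms(tibble::tibble(lifetime_cost = 10, lifetime_qaly = 2),
                      tibble::tibble(lifetime_cost = 20, lifetime_qaly = 1),
                      wtp = 100)
  expect_identical(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))
})

# cea_result reconstructed from published lifetime values; incremental
# effectiveness taken unrounded as 395448/754410
published_cea <- function(wtp = 242928) {
  dq <- 395448 / 754410
  arms <- tibble::tibble(
    arm = c("mitraclip", "omt"),
    lifetime_cost = c(423817, 28369),
    lifetime_qaly = c(1.80 + dq, 1.80),
    life_years = c(3.72, 2.90),
    hospitalizations = c(1.16, 1.51),
    undiscounted_cost = c(423817, 28369)
  )
  structure(list(
    arms = arms,
    comparison = compare_arms(arms[1, ], arms[2, ], wtp),
    wtp = wtp
  ), class = "cea_result")
}

test_that("device-price scenarios shift lifetime cost by exactly the price difference", {
  cea <- published_cea()
  uk <- scenario_device_price(cea, BASE_PARAMS, 143951, label = "uk")
  expect_equal(uk$lifetime_cost, 423817 - (322000 - 143951))
  expect_equal(uk$lifetime_cost, 245768)

  de <- scenario_device_price(cea, BASE_PARAMS, 247478, label = "germany")
  expect_equal(de$delta_cost, 320926)

  same <- scenario_device_price(cea, BASE_PARAMS, 322000)
  expect_equal(same$delta_cost, cea$comparison$delta_cost)
  expect_equal(same$icer, cea$comparison$icer, tolerance = 1e-12)

  expect_error(scenario_device_price(cea, BASE_PARAMS, -1), "non-negative")

  # affine property at arbitrary price pairs
  set.seed(1)
  for (i in 1:5) {
    d1 <- runif(1, 0, 5e5); d2 <- runif(1, 0, 5e5)
    s1 <- scenario_device_price(cea, BASE_PARAMS, d1)
    s2 <- scenario_device_price(cea, BASE_PARAMS, d2)
    expect_equal(s1$lifetime_cost - s2$lifetime_cost, d1 - d2, tolerance = 1e-9)
    expect_identical(s1$lifetime_qaly, s2$lifetime_qaly)
  }

  # ICER strictly decreasing in device price
  prices <- seq(5e4, 4e5, length.out = 6)
  icers <- vapply(prices, function(d) {
    scenario_device_price(cea, BASE_PARAMS, d)$icer
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("the threshold device price is the ICER fixed point", {
  cea <- published_cea()
  price <- threshold_device_price(cea, BASE_PARAMS, wtp = 242928)
  at <- scenario_device_price(cea, BASE_PARAMS, as.numeric(price))
  expect_equal(at$icer, 242928, tolerance = 1e-6)
  # published-value reconstruction of the cost-effective device price
  expect_equal(as.numeric(price),
               322000 - 395448 + 242928 * 395448 / 754410, tolerance = 1e-9)

  # fixed point: threshold at the base-case ICER returns the current price
  expect_equal(as.numeric(threshold_device_price(cea, BASE_PARAMS,
                                                 wtp = cea$comparison$icer)),
               322000, tolerance = 1e-6)

  # at WTP 0 with positive extra cost the price is negative and flagged
  expect_warning(neg <- threshold_device_price(cea, BASE_PARAMS, wtp = 0),
                 "negative")
  expect_lt(as.numeric(neg), 0)

  flat <- published_cea()
  flat$comparison$delta_qaly <- 0
  expect_warning(out <- threshold_device_price(flat, BASE_PARAMS), "undefined")
  expect_true(is.na(out))
})

test_that("net monetary benefit is positive exactly when the ICER beats the threshold", {
  set.seed(5)
  for (i in 1:30) {
    a <- tibble::tibble(lifetime_cost = runif(1, 0, 5e5),
                        lifetime_qaly = runif(1, 0.1, 3))
    b <- tibble::tibble(lifetime_cost = runif(1, 0, 5e5),
                        lifetime_qaly = a$lifetime_qaly - runif(1, 0.01, 1))
    cmp <- compare_arms(a, b, wtp = runif(1, 1e4, 1e6))
    if (cmp$delta_qaly > 0 && !is.na(cmp$icer)) {
      expect_identical(cmp$nmb > 0, cmp$icer < cmp$wtp)
    }
  }
})

test_that("removing discounting weakly increases lifetime cost and QALYs", {
  p0 <- BASE_PARAMS
  p0$econ$annual_discount_rate <- 0
  r0 <- run_cea(p0)
  r5 <- run_cea(BASE_PARAMS)
  expect_true(all(r0$arms$lifetime_cost >= r5$arms$lifetime_cost))
  expect_true(all(r0$arms$lifetime_qaly >= r5$arms$lifetime_qaly))
})

test_that("tidy and glance expose the run as tibbles", {
  res <- run_cea(BASE_PARAMS)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$arm, c("mitraclip", "omt"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$wtp, 242928)
})
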