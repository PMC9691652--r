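test_that("transition matrices carry the published monthly probabilities", {
  mc <- build_transition_matrix(BASE_PARAMS, "mitraclip")
  omt <- build_transition_matrix(BASE_PARAMS, "omt")
  expect_equal(unname(mc["nyha3", ]), c(0, 0.025, 0.895, 0.070, 0.010))
  expect_equal(unname(omt["nyha4", ]), c(0, 0, 0, 0.750, 0.250))
  expect_equal(unname(mc["dead", ]), c(0, 0, 0, 0, 1))
  expect_equal(unname(omt["dead", ]), c(0, 0, 0, 0, 1))
  expect_equal(unname(rowSums(mc)), rep(1, 5), tolerance = 1e-12)

  p <- BASE_PARAMS
  p$transitions$omt["nyha2", "nyha3"] <- 0.1  # row no longer sums to 1
  expect_error(build_transition_matrix(p, "omt"), "sum to 1")
})

test_that("cohort propagation matches explicit vector-matrix iteration", {
  m <- build_transition_matrix(BASE_PARAMS, "omt")

  all_dead <- run_cohort(c(0, 0, 0, 0, 1), m, 10)
  expect_true(all(all_dead$dead == 1))
  expect_true(all(as.matrix(all_dead[, c("nyha1", "nyha2", "nyha3", "nyha4")]) == 0))

  one <- run_cohort(c(0, 0, 0, 1, 0), m, 1)
  expect_equal(one$dead[2], 0.25)
  expect_equal(one$nyha4[2], 0.75)

  expect_error(run_cohort(c(0.5, 0.2, 0.1, 0.1, 0.1), m, 0), "at least 1")
  expect_error(run_cohort(c(0.9, 0.2, 0, 0, 0), m, 5), "summing to 1")

  # brute-force oracle: repeated explicit multiplication, independent loop
  set.seed(42)
  for (rep in 1:5) {
    init <- random_simplex()
    tr <- run_cohort(init, m, 7)
    v <- init
    for (t in 1:7) {
      v_new <- numeric(5)
      for (j in 1:5) v_new[j] <- sum(v * m[, j])
      v <- v_new
      expect_equal(unname(unlist(tr[t + 1, -1])), v, tolerance = 1e-12)
    }
  }
})

test_that("life-year accrual matches closed forms", {
  # no deaths: 24 monthly cycles = 2 years regardless of correction
  p <- single_state_params(0)
  m <- build_transition_matrix(p, "omt")
  tr <- run_cohort(c(1, 0, 0, 0, 0), m, 24)
  expect_equal(life_years(tr, half_cycle = TRUE), 2)
  expect_equal(life_years(tr, half_cycle = FALSE), 2)

  # everyone dead at entry
  tr0 <- run_cohort(c(0, 0, 0, 0, 1), m, 24)
  expect_equal(life_years(tr0), 0)

  # geometric chain, monthly death 0.2, long horizon:
  # end-of-cycle sum = (1-p)/p months; corrected adds half a month
  p2 <- single_state_params(0.2)
  tr2 <- run_cohort(c(1, 0, 0, 0, 0), build_transition_matrix(p2, "omt"), 336)
  expect_equal(life_years(tr2, half_cycle = FALSE) * 12, (1 - 0.2) / 0.2,
               tolerance = 1e-9)
  expect_equal(life_years(tr2, half_cycle = TRUE) * 12, (1 - 0.2) / 0.2 + 0.5,
               tolerance = 1e-9)
})

test_that("expected hospitalizations are occupancy-weighted event sums", {
  p <- single_state_params(0)
  tr <- run_cohort(c(1, 0, 0, 0, 0), build_transition_matrix(p, "omt"), 1)
  expect_equal(expected_hospitalizations(tr, c(0, 0, 0, 0)), 0)
  expect_equal(expected_hospitalizations(tr, c(0.1, 0, 0, 0), half_cycle = FALSE), 0.1)
  expect_equal(expected_hospitalizations(tr, c(0.1, 0, 0, 0), half_cycle = TRUE), 0.1)
  expect_error(expected_hospitalizations(tr, c(0.1, 0.2)), "length 4")
  expect_error(expected_hospitalizations(tr, c(0.1, 0, 0, 2)), "\\[0, 1\\]")
})

test_that("traces conserve mass and absorb monotonically for random chains", {
  set.seed(7)
  for (rep in 1:20) {
    m <- random_transition_matrix()
    init <- random_simplex()
    tr <- run_cohort(init, m, 60)
    expect_equal(rowSums(as.matrix(tr[, -1])), rep(1, 61), tolerance = 1e-9)
    expect_true(all(diff(tr$dead) >= -1e-12))
    # strict increase whenever some live state with positive occupancy
    # can die this cycle
    death_prob <- m[1:4, 5]
    live_occ <- as.matrix(tr[1:60, c("nyha1", "nyha2", "nyha3", "nyha4")])
    can_die <- as.numeric(live_occ %*% death_prob) > 1e-12
    expect_true(all(diff(tr$dead)[can_die] > 0))
  }
})

test_that("half-cycle corrected life years lie between the two Riemann sums", {
  set.seed(8)
  for (rep in 1:10) {
    m <- random_transition_matrix()
    tr <- run_cohort(random_simplex(), m, 60)
    trm <- as.matrix(tr[, -1])
    alive <- 1 - trm[, 5]
    end_sum <- sum(alive[-1]) / 12
    start_sum <- sum(alive[-length(alive)]) / 12
    ly <- life_years(tr, half_cycle = TRUE)
    if (start_sum - end_sum > 1e-12) {
      expect_gt(ly, end_sum)
      expect_lt(ly, start_sum)
      expect_equal(life_years(tr, half_cycle = FALSE), end_sum, tolerance = 1e-12)
    }
  }
})
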