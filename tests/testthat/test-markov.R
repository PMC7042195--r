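test_that("hazard-ratio adjustment acts on the cumulative-hazard scale", {
  expect_equal(adjust_mortality(0.01, 1), 0.01)
  expect_equal(adjust_mortality(0.01, 2.18), 1 - exp(2.18 * log(0.99)),
               tolerance = 1e-12)
  expect_equal(round(adjust_mortality(0.01, 2.18), 6), 0.021671)
  expect_equal(adjust_mortality(1, 5.78), 1)
  expect_equal(adjust_mortality(0, 5.78), 0)
  # stays a probability even where naive multiplication would not
  expect_lt(adjust_mortality(0.5, 5.78), 1)
  expect_error(adjust_mortality(0.01, 0), "> 0")
  expect_error(adjust_mortality(1.2, 2), "\\[0, 1\\]")
})

test_that("the cohort trace is a survival curve ending in extinction", {
  lt <- bundled_life_table()
  for (hr in c(1, 2.18, 5.78)) {
    tr <- cohort_trace(lt, hr, start_age = 6)
    expect_equal(tr$survival[1], 1)
    expect_true(all(diff(tr$survival) <= 0))
    expect_true(all(tr$survival >= 0 & tr$survival <= 1))
    expect_equal(tr$survival[nrow(tr)], 0)  # extinct after the terminal age
    expect_equal(tr$age, 6:111)
  }
  # constant-q table: survival is exactly geometric
  q <- 0.03; hr <- 2.5
  tr <- cohort_trace(const_life_table(q), hr, start_age = 0)
  q_adj <- 1 - (1 - q)^hr
  body <- head(tr, -1)
  expect_equal(body$survival, (1 - q_adj)^(body$cycle), tolerance = 1e-12)
  expect_equal(tr$survival[nrow(tr)], 0)

  gap <- tibble::tibble(age = c(0:50, 52:110), qx = c(rep(0.01, 109), 1))
  expect_error(cohort_trace(validate_life_table(gap), 1, 0), "gap|missing")
  expect_error(cohort_trace(bundled_life_table(), 1, start_age = 200),
               "start age")
})

test_that("payoffs match finite geometric-series closed forms", {
  set.seed(21)
  for (i in 1:100) {
    q <- runif(1, 0.005, 0.2)
    w <- runif(1)
    r <- runif(1, 0, 0.08)
    lt <- const_life_table(q, min_age = 6)
    tr <- cohort_trace(lt, hr = 1, start_age = 6)
    n_cycles <- nrow(tr) - 1  # the extinction row accrues nothing
    expect_equal(discounted_qalys(tr, w, r),
                 oracle_geometric_qalys(q, w, r, n_cycles),
                 tolerance = 1e-9)
    expect_equal(life_expectancy(tr), oracle_geometric_le(q, n_cycles),
                 tolerance = 1e-9)
  }
  # the infinite-horizon limit w(1+r)/(q+r) is approached from below:
  # truncation at the terminal age leaves a ~0.5% deficit at these rates
  lt <- const_life_table(0.02, min_age = 6, terminal_age = 110)
  tr <- cohort_trace(lt, 1, 6)
  got <- discounted_qalys(tr, 1, 0.03)
  expect_lt(got, 1.03 / 0.05)
  expect_equal(got, 1.03 / 0.05, tolerance = 0.01)
})

test_that("discounting and weighting behave as contracts promise", {
  lt <- bundled_life_table()
  tr <- cohort_trace(lt, 2.18, 6)
  # r = 0 recovers undiscounted expected cycles alive
  expect_equal(discounted_qalys(tr, 1, r = 0), sum(tr$survival))
  expect_equal(discounted_qalys(tr, 0, r = 0.03), 0)
  # QALYs with weight 1 and no decline equal discounted life years exactly
  dly <- sum(tr$survival / 1.03^tr$cycle)
  expect_equal(discounted_qalys(tr, 1, r = 0.03), dly, tolerance = 1e-12)
  # payoffs non-increasing in the discount rate
  rs <- c(0, 0.01, 0.03, 0.05, 0.1)
  qs <- vapply(rs, function(r) discounted_qalys(tr, 0.68, r), numeric(1))
  expect_true(all(diff(qs) < 0))
  # adult decline lowers QALYs and respects the floor
  declined <- discounted_qalys(tr, 0.68, 0.03, decline_per_year = 0.005)
  expect_lt(declined, discounted_qalys(tr, 0.68, 0.03))
  floored <- discounted_qalys(tr, 0.68, 0, decline_per_year = 1, floor = 0.2)
  expect_gt(floored, 0.2 * sum(tr$survival[tr$age >= 19]))
})

test_that("age-banded costs are looked up by attained age", {
  p <- base_params()
  lt <- bundled_life_table()
  # non-ASD class accrues nothing
  tr <- cohort_trace(lt, 1, 6)
  expect_equal(discounted_costs(tr, p, "non_asd"), 0)
  # two cycles straddling the 17 -> 18 band boundary, hand-computed
  two <- tibble::tibble(cycle = 0:1, age = 17:18, survival = c(1, 0.99))
  expect_equal(discounted_costs(two, p, "asd_only"),
               58526 + 0.99 * 69889 / 1.03, tolerance = 1e-9)
  expect_equal(discounted_costs(two, p, "asd_id"),
               95983 + 0.99 * 127718 / 1.03, tolerance = 1e-9)
  # constant cost factorizes into cost x discounted life years
  flat <- p
  flat$annual_costs$annual_cost[flat$annual_costs$outcome_class ==
                                  "asd_only"] <- 1000
  tr6 <- cohort_trace(lt, 2.18, 6)
  expect_equal(discounted_costs(tr6, flat, "asd_only"),
               1000 * sum(tr6$survival / 1.03^tr6$cycle), tolerance = 1e-9)
  # scale parameter acts multiplicatively
  scaled <- asd_parameters(annual_cost_scale_asd_id = 1.25)
  expect_equal(discounted_costs(tr6, scaled, "asd_id"),
               1.25 * discounted_costs(tr6, p, "asd_id"), tolerance = 1e-12)
  # ages below the first band are an error
  young <- tibble::tibble(cycle = 0, age = 3, survival = 1)
  expect_error(discounted_costs(young, p, "asd_only"), "outside")
  expect_error(discounted_costs(tr, p, "asd_plus"), "outcome class")
})

test_that("life expectancy is monotone in the hazard ratio", {
  lt <- bundled_life_table()
  le <- vapply(c(1, 2.18, 5.78),
               function(hr) life_expectancy(cohort_trace(lt, hr, 6)),
               numeric(1))
  expect_true(all(diff(le) < 0))
  dead <- const_life_table(1, min_age = 6)
  expect_equal(life_expectancy(cohort_trace(dead, 1, 6)), 0)
  q <- 0.04
  expect_equal(life_expectancy(cohort_trace(const_life_table(q, 6), 1, 6)),
               oracle_geometric_le(q, 105), tolerance = 1e-9)
})

test_that("markov_payoff composes trace, QALYs and costs per class", {
  p <- base_params()
  lt <- bundled_life_table()
  pay <- purrr::map_dfr(c("non_asd", "asd_only", "asd_id"),
                        ~ markov_payoff(p, lt, .x))
  expect_equal(pay$discounted_cost[pay$outcome_class == "non_asd"], 0)
  expect_lt(pay$discounted_qalys[pay$outcome_class == "asd_id"],
            pay$discounted_qalys[pay$outcome_class == "asd_only"])
  # decomposition oracle: recompute each piece independently
  for (cls in c("asd_only", "asd_id")) {
    hr <- if (cls == "asd_only") p$hr_asd else p$hr_asd_id
    w <- if (cls == "asd_only") p$qol_asd else p$qol_asd_id
    tr <- cohort_trace(lt, hr, 6)
    row <- pay[pay$outcome_class == cls, ]
    expect_equal(row$discounted_qalys, discounted_qalys(tr, w, 0.03),
                 tolerance = 1e-12)
    expect_equal(row$discounted_cost, discounted_costs(tr, p, cls),
                 tolerance = 1e-12)
    expect_equal(row$life_expectancy, life_expectancy(tr), tolerance = 1e-12)
  }
  expect_error(markov_payoff(p, lt, "asd_maybe"), "outcome class")
})
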