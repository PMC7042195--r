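lt_fixture <- bundled_life_table()

test_that("strategy summaries decompose into mixtures times payoffs", {
  p <- base_params()
  s <- summarize_strategies(p, lt_fixture)
  pay <- purrr::map_dfr(c("non_asd", "asd_only", "asd_id"),
                        ~ markov_payoff(p, lt_fixture, .x))
  for (i in seq_len(nrow(s))) {
    mix <- outcome_mixture(p, s$strategy[i])
    f <- c(mix$f_non_asd, mix$f_asd_only, mix$f_asd_id)
    expect_equal(s$expected_qalys[i], sum(f * pay$discounted_qalys),
                 tolerance = 1e-12)
    expect_equal(
      s$expected_cost[i],
      expected_upfront_cost(p, s$strategy[i]) + sum(f * pay$discounted_cost),
      tolerance = 1e-12
    )
    expect_gte(s$expected_cost[i], s$upfront_cost[i])
    expect_gt(s$expected_qalys[i], 0)
  }
})

test_that("without disease all strategies deliver identical QALYs", {
  p <- asd_parameters(prevalence_asd = 0)
  s <- summarize_strategies(p, lt_fixture)
  expect_equal(diff(range(s$expected_qalys)), 0, tolerance = 1e-12)
  # costs differ only by screening / treatment upfront
  expect_equal(
    s$expected_cost,
    vapply(s$strategy, function(x) expected_upfront_cost(p, x), numeric(1),
           USE.NAMES = FALSE),
    tolerance = 1e-9
  )
})

test_that("QALYs rise with intervention coverage across strategies", {
  s <- summarize_strategies(base_params(), lt_fixture)
  ordered <- s$expected_qalys[match(
    c("status_quo", "test_treat_6", "test_treat_12", "treat_all"),
    s$strategy
  )]
  expect_true(all(diff(ordered) > 0))
})

test_that("icer reproduces the published arithmetic and guards its domain", {
  # printed societal cells: 6-month screening vs status quo
  value <- icer(list(expected_cost = 296949, expected_qalys = 27.0563),
                list(expected_cost = 294586, expected_qalys = 27.0084))
  expect_equal(value, (296949 - 294586) / (27.0563 - 27.0084))
  expect_lt(abs(value - 49331), 5)

  same_e <- list(expected_cost = 10, expected_qalys = 1)
  expect_error(icer(same_e, list(expected_cost = 5, expected_qalys = 1)),
               "Undefined ICER")
  expect_error(icer(same_e, same_e), "Undefined ICER")
  expect_equal(icer(list(expected_cost = 5, expected_qalys = 2),
                    list(expected_cost = 5, expected_qalys = 1)), 0)
  expect_warning(
    out <- icer(list(expected_cost = 4, expected_qalys = 2),
                list(expected_cost = 5, expected_qalys = 1)),
    "dominates"
  )
  expect_true(is.na(out))
  expect_error(
    icer(list(expected_cost = 1, expected_qalys = 2, perspective = "societal"),
         list(expected_cost = 1, expected_qalys = 1,
              perspective = "educational")),
    "perspectives"
  )
})

random_summary_set <- function(n = 4) {
  tibble::tibble(
    strategy = paste0("s", seq_len(n)),
    perspective = "societal",
    expected_cost = runif(n, 0, 1e5),
    expected_qalys = runif(n, 10, 30)
  )
}

test_that("a constructed losing strategy is flagged strongly dominated", {
  tab <- tibble::tibble(
    strategy = c("A", "B", "C"),
    perspective = "societal",
    expected_cost = c(100, 200, 150),
    expected_qalys = c(20, 19, 21)
  )
  cea <- cea_frontier(tab)
  out <- tidy(cea)
  expect_equal(out$dominance[out$strategy == "B"], "strong")
  expect_equal(out$dominance[out$strategy %in% c("A", "C")], rep("none", 2))
})

test_that("frontier matches brute-force dominance enumeration on random sets", {
  set.seed(31)
  for (i in 1:1000) {
    tab <- random_summary_set()
    cea <- cea_frontier(tab)
    out <- tidy(cea)
    oracle <- oracle_frontier_dominated(tab$expected_cost,
                                        tab$expected_qalys)
    got <- out$dominance[match(tab$strategy, out$strategy)] != "none"
    expect_identical(got, oracle)
    # surviving entries: strictly increasing cost, QALYs and ICER
    alive <- out[out$dominance == "none", ]
    expect_true(all(diff(alive$expected_cost) > 0))
    expect_true(all(diff(alive$expected_qalys) > 0))
    icers <- alive$icer[-1]
    expect_true(all(diff(icers) > 0) || length(icers) < 2)
  }
})

test_that("frontier is invariant to input order and duplicated losers", {
  set.seed(32)
  tab <- random_summary_set()
  ref <- tidy(cea_frontier(tab, baseline = "s1"))
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(tidy(cea_frontier(shuffled, baseline = "s1")), ref)
  loser <- ref[ref$dominance != "none", ][1, ]
  if (!is.na(loser$strategy)) {
    dup <- dplyr::bind_rows(tab, dplyr::mutate(
      tab[tab$strategy == loser$strategy,
          c("strategy", "perspective", "expected_cost", "expected_qalys")],
      strategy = "dup"
    ))
    out <- tidy(cea_frontier(dup, baseline = "s1"))
    expect_equal(out[out$strategy != "dup", names(ref)], ref)
  }
})

test_that("common-baseline ICERs use the fixed reference strategy", {
  # printed Table-2 cells, 12-month screening vs status quo: rounded inputs
  # give 169,416 (the published 169,435 used unrounded internals)
  tab <- tibble::tibble(
    strategy = c("status_quo", "test_treat_12"),
    perspective = "societal",
    expected_cost = c(294586, 303294),
    expected_qalys = c(27.0084, 27.0598)
  )
  out <- common_baseline_icers(tab, "status_quo")
  expect_equal(out$icer_vs_baseline,
               (303294 - 294586) / (27.0598 - 27.0084), tolerance = 1e-12)
  expect_equal(round(out$icer_vs_baseline), 169416)
  expect_false("status_quo" %in% out$strategy)
  expect_error(common_baseline_icers(tab, "nope"), "not found")

  # the first frontier step equals its common-baseline ICER; later steps
  # can only grow their incremental ICER above the common-baseline one
  set.seed(33)
  for (i in 1:200) {
    tab <- random_summary_set()
    cea <- cea_frontier(tab, baseline = NULL)
    alive <- tidy(cea)[tidy(cea)$dominance == "none", ]
    if (nrow(alive) >= 2) {
      expect_equal(alive$icer[2], alive$icer_vs_baseline[2],
                   tolerance = 1e-9)
      expect_true(all(alive$icer[-1] >= alive$icer_vs_baseline[-1] - 1e-9))
    }
  }
})

test_that("the WTP decision rule agrees with net monetary benefit", {
  p <- base_params()
  s <- summarize_strategies(p, lt_fixture)
  cea <- cea_frontier(s)
  expect_equal(optimal_strategy(cea, 0), "status_quo")
  expect_equal(optimal_strategy(cea, Inf), "treat_all")
  set.seed(34)
  for (i in 1:200) {
    tab <- random_summary_set()
    cea_i <- cea_frontier(tab)
    wtp <- runif(1, 0, 2e5)
    best <- optimal_strategy(cea_i, wtp)
    alive <- tidy(cea_i)[tidy(cea_i)$dominance == "none", ]
    nmb <- net_monetary_benefit(alive, wtp)
    expect_equal(best, nmb$strategy[1])
  }
})

test_that("societal costs bound the narrower perspectives", {
  p <- base_params()
  soc <- summarize_strategies(p, lt_fixture, "societal")
  hc <- summarize_strategies(p, lt_fixture, "health_care")
  edu <- summarize_strategies(p, lt_fixture, "educational")
  expect_true(all(soc$expected_cost >= hc$expected_cost))
  expect_true(all(hc$expected_cost >= edu$expected_cost))
  # QALYs do not depend on the cost ledger
  expect_equal(soc$expected_qalys, hc$expected_qalys, tolerance = 1e-12)
  expect_equal(soc$expected_qalys, edu$expected_qalys, tolerance = 1e-12)
})
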