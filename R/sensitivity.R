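# One-way (tornado) and probabilistic (Monte Carlo) sensitivity analyses.

# ICER of comparator vs baseline for one parameter set; the workhorse of
# both analyses. Returns signed infinity when the effect difference is zero
# (e.g. an ID risk ratio of exactly 1 leaves QALYs identical).
comparison_icer <- function(params, lt, comparator = "test_treat_6",
                            baseline = "status_quo",
                            perspective = "societal") {
  s <- summarize_strategies(params, lt, perspective,
                            strategy_set = c(baseline, comparator))
  pairwise_icer(
    s$expected_cost[s$strategy == comparator] -
      s$expected_cost[s$strategy == baseline],
    s$expected_qalys[s$strategy == comparator] -
      s$expected_qalys[s$strategy == baseline]
  )
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs the full decision-tree/Markov pipeline twice with one parameter
#' set to its low and high value (everything else at base case) and records
#' the ICER of the comparator versus the baseline strategy at each end.
#'
#' @param params base-case `asd_parameters`.
#' @param lt an `asd_life_table`.
#' @param parameter a scalar parameter name (see [default_ranges()]).
#' @param low,high the envelope tested; `low <= high` in parameter units.
#' @param comparator,baseline the compared strategies (default: 6-month
#'   screening versus status quo).
#' @param perspective perspective label (default `"societal"`).
#' @return A one-row tibble `parameter`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `bar_width` (`|icer_at_high - icer_at_low|`).
#' @export
one_way <- function(params, lt, parameter, low, high,
                    comparator = "test_treat_6", baseline = "status_quo",
                    perspective = "societal") {
  if (low > high) abort("`low` must not exceed `high`.")
  at <- function(value) {
    comparison_icer(
      set_parameter(params, parameter, value, check_qol_order = FALSE),
      lt, comparator, baseline, perspective
    )
  }
  icer_low <- at(low)
  icer_high <- at(high)
  tibble(
    parameter = parameter, low = low, high = high,
    icer_at_low = icer_low, icer_at_high = icer_high,
    bar_width = abs(icer_high - icer_low)
  )
}

#' Default tornado ranges for a comparison
#'
#' The one-way envelope of the parameters displayed in the tornado diagram:
#' prevalences, intervention effect and uptake, test characteristics of the
#' compared strategy, QOL weights, costs and the discount rate. The test
#' characteristics of the strategy not being compared are dropped (they
#' cannot move the ICER), as are the mortality hazard ratios: their tested
#' ranges are tight confidence intervals whose effect on an incremental
#' comparison is second-order, an order of magnitude below every displayed
#' bar. Both remain available through [one_way()] or a custom `ranges`
#' table.
#'
#' @inheritParams one_way
#' @return A tibble `parameter`, `low`, `high`.
#' @export
default_tornado_ranges <- function(comparator = "test_treat_6",
                                   baseline = "status_quo") {
  ranges <- default_ranges()
  drop <- c("hr_asd", "hr_asd_id")
  involved <- c(comparator, baseline)
  if (!"test_treat_6" %in% involved) {
    drop <- c(drop, "sens_mri_6", "spec_mri_6")
  }
  if (!"test_treat_12" %in% involved) {
    drop <- c(drop, "sens_mri_12", "spec_mri_12")
  }
  ranges[!ranges$parameter %in% drop, ]
}

#' Tornado analysis
#'
#' One-way sensitivity over a set of parameter ranges, sorted by bar width
#' descending. Each entry is independent of evaluation order: every run
#' starts from the same base case.
#'
#' @inheritParams one_way
#' @param ranges tibble `parameter`, `low`, `high`; defaults to
#'   [default_tornado_ranges()] for the chosen comparison.
#' @return An `asd_tornado` tibble of [one_way()] rows, widest bar first.
#' @export
tornado <- function(params, lt, ranges = NULL,
                    comparator = "test_treat_6", baseline = "status_quo",
                    perspective = "societal") {
  if (is.null(ranges)) {
    ranges <- default_tornado_ranges(comparator, baseline)
  }
  out <- purrr::pmap_dfr(
    ranges[, c("parameter", "low", "high")],
    function(parameter, low, high) {
      one_way(params, lt, parameter, low, high, comparator, baseline,
              perspective)
    }
  )
  out <- arrange(out, desc(.data$bar_width))
  base_icer <- comparison_icer(params, lt, comparator, baseline, perspective)
  structure(out, class = c("asd_tornado", class(out)),
            base_icer = base_icer, comparator = comparator,
            baseline = baseline, perspective = perspective)
}

#' @exportS3Method generics::tidy
tidy.asd_tornado <- function(x, ...) {
  as_tibble(unclass_tornado(x))
}

unclass_tornado <- function(x) {
  class(x) <- setdiff(class(x), "asd_tornado")
  x
}

#' Probabilistic sensitivity analysis
#'
#' Propagates joint parameter uncertainty through the whole pipeline:
#' `n` seeded Monte Carlo parameter sets (moment-matched beta/gamma draws
#' via one deterministic substream per parameter; test characteristics and
#' costs held fixed), a full decision-tree/Markov evaluation per draw, and
#' the incremental (cost, QALY) pair of the comparator versus the baseline.
#'
#' @inheritParams one_way
#' @param n number of Monte Carlo draws (>= 1).
#' @param seed master seed; identical seeds give identical results.
#' @param specs distribution specs (see [default_psa_specs()]).
#' @return An `asd_psa` tibble with one row per draw: the sampled parameter
#'   values plus `d_cost` and `d_qalys`. Attributes carry `n`, `seed` and
#'   the comparison.
#' @export
run_psa <- function(params, lt, n = 10000, seed,
                    specs = default_psa_specs(),
                    comparator = "test_treat_6", baseline = "status_quo",
                    perspective = "societal") {
  if (missing(seed) || is.null(seed)) abort("A `seed` is required.")
  if (n < 1) abort("`n` must be >= 1.")
  draws <- sample_parameter_draws(params, specs, n = n, seed = seed)

  # Precompute everything invariant across draws.
  validate_life_table(lt)
  ages <- lt$age[lt$age >= params$start_age]
  q <- lt$qx[lt$age >= params$start_age]
  disc <- (1 + params$discount_rate)^-(seq_along(ages) - 1)
  pview <- perspective_row(params, perspective)
  cost_vec <- function(class) {
    bands <- params$annual_costs[params$annual_costs$outcome_class == class, ]
    bands <- bands[order(bands$age_from), ]
    scale <- switch(class, asd_only = params$annual_cost_scale_asd,
                    asd_id = params$annual_cost_scale_asd_id, 1)
    cost_at_age(ages, bands) * scale * pview$annual_fraction
  }
  c_asd <- cost_vec("asd_only")
  c_id <- cost_vec("asd_id")
  age_excess <- pmax(0, ages - params$qol_decline_start_age)

  draw_col <- function(nm) {
    if (nm %in% names(draws)) draws[[nm]] else rep(params[[nm]], n)
  }
  prev <- draw_col("prevalence_asd")
  p_ei <- draw_col("p_early_intervention")
  p_id <- draw_col("p_id_without_ei")
  rr <- draw_col("rr_id_with_ei")
  hr1 <- draw_col("hr_asd")
  hr2 <- draw_col("hr_asd_id")
  w1 <- draw_col("qol_asd")
  w2 <- draw_col("qol_asd_id")

  weight_vec <- function(w) {
    pmax(pmin(w - params$qol_decline_per_year * age_excess, w),
         params$qol_floor)
  }
  # non-ASD class payoff is draw-invariant (hr 1, weight 1, zero cost)
  s0 <- c(1, cumprod(1 - q)[-length(q)])
  qaly_non <- sum(s0 * disc)

  ei_frac_asd <- function(strategy, i) {
    switch(strategy,
      status_quo = p_ei[i],
      test_treat_6 = params$sens_mri_6 + (1 - params$sens_mri_6) * p_ei[i],
      test_treat_12 = params$sens_mri_12 + (1 - params$sens_mri_12) * p_ei[i],
      treat_all = 1
    )
  }
  fp_frac <- function(strategy) {
    switch(strategy,
      test_treat_6 = 1 - params$spec_mri_6,
      test_treat_12 = 1 - params$spec_mri_12,
      0
    )
  }
  screened <- function(strategy) {
    strategy %in% c("test_treat_6", "test_treat_12")
  }

  d_cost <- numeric(n)
  d_qalys <- numeric(n)
  mri_cost <- if (pview$include_mri) params$cost_mri else 0
  for (i in seq_len(n)) {
    s1 <- c(1, cumprod((1 - q)^hr1[i])[-length(q)])
    s2 <- c(1, cumprod((1 - q)^hr2[i])[-length(q)])
    qaly_asd <- sum(s1 * weight_vec(w1[i]) * disc)
    qaly_id <- sum(s2 * weight_vec(w2[i]) * disc)
    cost_asd <- sum(s1 * c_asd * disc)
    cost_id <- sum(s2 * c_id * disc)
    eval_strategy <- function(strategy) {
      ei <- ei_frac_asd(strategy, i)
      f_id <- prev[i] * p_id[i] * (1 - ei * (1 - rr[i]))
      f_asd <- prev[i] - f_id
      f_ei <- prev[i] * ei + (1 - prev[i]) * fp_frac(strategy) +
        if (strategy == "treat_all") (1 - prev[i]) else 0
      upfront <- f_ei * params$cost_ei * pview$ei_fraction +
        screened(strategy) * mri_cost
      c(cost = upfront + f_asd * cost_asd + f_id * cost_id,
        qalys = (1 - prev[i]) * qaly_non + f_asd * qaly_asd + f_id * qaly_id)
    }
    comp <- eval_strategy(comparator)
    base <- eval_strategy(baseline)
    d_cost[i] <- comp[["cost"]] - base[["cost"]]
    d_qalys[i] <- comp[["qalys"]] - base[["qalys"]]
  }

  out <- draws
  out$d_cost <- d_cost
  out$d_qalys <- d_qalys
  out$draw <- seq_len(n)
  out <- out[, c("draw", setdiff(names(out), "draw"))]
  structure(out, class = c("asd_psa", class(out)),
            n = n, seed = seed, comparator = comparator,
            baseline = baseline, perspective = perspective)
}

#' Cost-effectiveness plane summary of a PSA
#'
#' Quadrant proportions of the incremental (QALY, cost) cloud and, for each
#' willingness-to-pay threshold, the proportion of draws with a QALY gain
#' whose ICER falls below the threshold (cost-saving draws count: their
#' ratio is negative). Draws with a QALY loss sit in their quadrant and are
#' excluded from the threshold proportions.
#'
#' @param psa an `asd_psa` object from [run_psa()].
#' @param wtp vector of thresholds (default `c(50000, 100000)`).
#' @return A tibble `measure`, `value` with quadrant proportions
#'   (`superior` = QALY gain at lower cost), and one
#'   `p_gain_icer_below_<wtp>` row per threshold.
#' @export
ce_plane_summary <- function(psa, wtp = c(50000, 100000)) {
  if (nrow(psa) == 0) abort("The PSA holds no draws.")
  de <- psa$d_qalys; dc <- psa$d_cost
  n <- length(de)
  out <- tibble(
    measure = c("superior", "more_effective_more_costly",
                "less_effective_less_costly", "inferior"),
    value = c(mean(de > 0 & dc < 0), mean(de > 0 & dc >= 0),
              mean(de <= 0 & dc < 0), mean(de <= 0 & dc >= 0))
  )
  for (w in sort(wtp)) {
    out <- bind_rows(out, tibble(
      measure = paste0("p_gain_icer_below_", format(w, scientific = FALSE)),
      value = mean(de > 0 & dc / de < w)
    ))
  }
  out
}

#' @exportS3Method generics::tidy
tidy.asd_psa <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "asd_psa")
  as_tibble(out)
}

#' @exportS3Method generics::glance
glance.asd_psa <- function(x, wtp = c(50000, 100000), ...) {
  s <- ce_plane_summary(x, wtp)
  wide <- as.list(setNames(s$value, s$measure))
  as_tibble(c(list(n = attr(x, "n"), seed = attr(x, "seed"),
                   comparator = attr(x, "comparator"),
                   baseline = attr(x, "baseline"),
                   perspective = attr(x, "perspective")), wide))
}
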