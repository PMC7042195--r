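# The live-or-die Markov cohort engine: hazard-adjusted mortality, survival
# trace, discounted QALYs and age-banded costs, life expectancy.

#' Apply a mortality hazard ratio to an annual death probability
#'
#' Hazard ratios act multiplicatively on the cumulative hazard, not on the
#' probability: `q' = 1 - (1 - q)^hr`. Naive multiplication would exceed 1
#' for large ratios (the ASD+ID ratio is 5.78); this transform stays in
#' \[0, 1\] for any `hr > 0` and is exact under a constant within-year
#' hazard.
#'
#' @param q annual death probability in \[0, 1\] (vectorised).
#' @param hr hazard ratio (> 0).
#' @return Adjusted annual death probability.
#' @examples
#' adjust_mortality(0.01, 2.18)
#' @export
adjust_mortality <- function(q, hr) {
  if (hr <= 0) abort("`hr` must be > 0.")
  if (any(q < 0 | q > 1)) abort("`q` must lie in [0, 1].")
  pmin(1 - (1 - q)^hr, 1)
}

#' Survival trace of a cohort entering at a start age
#'
#' Runs the two-state (alive/dead) Markov cohort with annual cycles:
#' `S(0) = 1`, `S(t+1) = S(t) * (1 - adjust_mortality(q(start_age + t), hr))`.
#' The trace ends in 0 because the terminal life-table age carries `q = 1`.
#'
#' @param lt an `asd_life_table` covering `start_age` through its terminal
#'   age with no gaps.
#' @param hr mortality hazard ratio applied to every age.
#' @param start_age age at cycle 0 (default 6).
#' @return A tibble `cycle`, `age`, `survival`; `survival` is the fraction
#'   alive at the start of each cycle.
#' @export
cohort_trace <- function(lt, hr = 1, start_age = 6) {
  validate_life_table(lt)
  if (!start_age %in% lt$age) {
    abort(paste0("Life table does not cover start age ", start_age, "."))
  }
  q <- lt$qx[lt$age >= start_age]
  ages <- lt$age[lt$age >= start_age]
  q_adj <- adjust_mortality(q, hr)
  s <- cumprod(1 - q_adj)
  # one row per cycle start, closed by the extinction row after the
  # terminal age (q = 1 there, so survival ends at exactly 0)
  tibble(
    cycle = c(seq_along(ages) - 1L, length(ages)),
    age = c(ages, ages[length(ages)] + 1),
    survival = c(1, s)
  )
}

qol_weight_at_age <- function(age, base_weight, decline_per_year = 0,
                              decline_start_age = 18, floor = 0) {
  w <- base_weight - decline_per_year * pmax(0, age - decline_start_age)
  pmax(pmin(w, base_weight), floor)
}

#' Discounted quality-adjusted life years of a trace
#'
#' Accrues `S(t) * w(age_t) / (1 + r)^t` at the start of each annual cycle,
#' with `t = 0` at the model start age; no half-cycle correction is applied.
#' The weight schedule is constant in childhood with an optional linear
#' adult decline (disabled by default).
#'
#' @param trace a cohort trace from [cohort_trace()].
#' @param weight base utility weight in \[0, 1\].
#' @param r annual discount rate (>= 0).
#' @param decline_per_year utility lost per year of age past
#'   `decline_start_age` (default 0).
#' @param decline_start_age age at which decline begins (default 18).
#' @param floor lowest weight the decline may reach (default 0).
#' @return Discounted QALYs (a single number).
#' @export
discounted_qalys <- function(trace, weight, r = 0.03, decline_per_year = 0,
                             decline_start_age = 18, floor = 0) {
  if (r < 0) abort("`r` must be >= 0.")
  w <- qol_weight_at_age(trace$age, weight, decline_per_year,
                         decline_start_age, floor)
  sum(trace$survival * w / (1 + r)^trace$cycle)
}

cost_at_age <- function(age, bands) {
  idx <- findInterval(age, bands$age_from)
  bad <- idx == 0 | age > bands$age_to[pmax(idx, 1)]
  if (any(bad)) {
    abort(paste0("Age ", age[which(bad)[1]], " is outside every cost band."))
  }
  bands$annual_cost[idx]
}

#' Discounted lifetime costs of a trace
#'
#' Accrues `S(t) * c(age_t) / (1 + r)^t` per cycle, with the annual cost
#' looked up in the outcome class's age bands by attained age at cycle
#' start, scaled by the perspective's annual-cost fraction and the class's
#' sensitivity-analysis scale factor.
#'
#' @inheritParams discounted_qalys
#' @param params an `asd_parameters` object (cost schedule, scales).
#' @param outcome_class one of `"non_asd"`, `"asd_only"`, `"asd_id"`.
#' @param perspective perspective label (default `"societal"`).
#' @return Discounted lifetime cost (currency).
#' @export
discounted_costs <- function(trace, params, outcome_class,
                             perspective = "societal",
                             r = params$discount_rate) {
  if (r < 0) abort("`r` must be >= 0.")
  bands <- params$annual_costs[params$annual_costs$outcome_class ==
                                 outcome_class, ]
  if (nrow(bands) == 0) {
    abort(paste0("Unknown outcome class `", outcome_class, "`."))
  }
  bands <- bands[order(bands$age_from), ]
  scale <- switch(outcome_class,
    asd_only = params$annual_cost_scale_asd,
    asd_id = params$annual_cost_scale_asd_id,
    1
  )
  frac <- perspective_row(params, perspective)$annual_fraction
  c_age <- cost_at_age(trace$age, bands)
  sum(trace$survival * c_age / (1 + r)^trace$cycle) * scale * frac
}

#' Life expectancy of a trace
#'
#' Expected whole remaining years, `sum(S(t))` over cycles `t >= 1`.
#'
#' @param trace a cohort trace from [cohort_trace()].
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(trace) {
  sum(trace$survival[trace$cycle >= 1])
}

outcome_classes <- function() c("non_asd", "asd_only", "asd_id")

class_hazard_ratio <- function(params, outcome_class) {
  switch(outcome_class,
    non_asd = 1, asd_only = params$hr_asd, asd_id = params$hr_asd_id,
    abort(paste0("Unknown outcome class `", outcome_class, "`."))
  )
}

class_qol_weight <- function(params, outcome_class) {
  switch(outcome_class,
    non_asd = 1, asd_only = params$qol_asd, asd_id = params$qol_asd_id,
    abort(paste0("Unknown outcome class `", outcome_class, "`."))
  )
}

#' Lifetime Markov payoff of an outcome class
#'
#' Selects the class's mortality hazard ratio, QOL weight and annual cost
#' rows (non-ASD: no excess mortality, weight 1, zero cost; ASD-only and
#' ASD+ID: their respective hazard ratios, weights and cost bands), runs the
#' cohort from the model start age, and returns discounted QALYs, the
#' discounted lifetime cost for the perspective, and undiscounted life
#' expectancy.
#'
#' @param params an `asd_parameters` object.
#' @param lt an `asd_life_table`.
#' @param outcome_class one of `"non_asd"`, `"asd_only"`, `"asd_id"`.
#' @param perspective perspective label.
#' @return A one-row tibble `outcome_class`, `discounted_qalys`,
#'   `discounted_cost`, `life_expectancy`.
#' @export
markov_payoff <- function(params, lt, outcome_class,
                          perspective = "societal") {
  hr <- class_hazard_ratio(params, outcome_class)
  w <- class_qol_weight(params, outcome_class)
  trace <- cohort_trace(lt, hr = hr, start_age = params$start_age)
  tibble(
    outcome_class = outcome_class,
    discounted_qalys = discounted_qalys(
      trace, w, r = params$discount_rate,
      decline_per_year = params$qol_decline_per_year,
      decline_start_age = params$qol_decline_start_age,
      floor = params$qol_floor
    ),
    discounted_cost = discounted_costs(trace, params, outcome_class,
                                       perspective),
    life_expectancy = life_expectancy(trace)
  )
}
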