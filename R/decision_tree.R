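# The four-strategy decision tree: path probabilities, terminal outcome
# mixtures, ID relative risk, and expected upfront (pre-age-6) costs.

#' The four screening strategies
#'
#' @return A tibble with one row per strategy: `status_quo` (no screening;
#'   early intervention reaches a child with ASD only through usual care),
#'   `test_treat_6` and `test_treat_12` (MRI screening in the first year of
#'   life; screen-positives receive early intervention, screen-negatives are
#'   monitored as under the status quo), and `treat_all` (every high-risk
#'   child receives early intervention, no screening). Test strategies carry
#'   their sensitivity/specificity; the others carry `NA`.
#' @param params an `asd_parameters` object supplying test characteristics.
#' @export
strategies <- function(params = asd_parameters()) {
  tibble(
    strategy = c("status_quo", "test_treat_6", "test_treat_12", "treat_all"),
    sensitivity = c(NA, params$sens_mri_6, params$sens_mri_12, NA),
    specificity = c(NA, params$spec_mri_6, params$spec_mri_12, NA)
  )
}

strategy_labels <- function() {
  c("status_quo", "test_treat_6", "test_treat_12", "treat_all")
}

check_strategy <- function(strategy) {
  if (!strategy %in% strategy_labels()) {
    abort(paste0("Unknown strategy `", strategy, "`. Valid strategies: ",
                 paste(strategy_labels(), collapse = ", ")))
  }
  strategy
}

test_characteristics <- function(params, strategy) {
  switch(strategy,
    test_treat_6  = c(sens = params$sens_mri_6,  spec = params$spec_mri_6),
    test_treat_12 = c(sens = params$sens_mri_12, spec = params$spec_mri_12),
    NULL
  )
}

#' Branch path probabilities of a strategy
#'
#' Expands the chance nodes of one strategy into terminal path
#' probabilities. In a test strategy the ASD branch splits by sensitivity
#' into screen-positives (who receive early intervention) and
#' screen-negatives (who revert to the usual-care early-intervention
#' probability); the non-ASD branch splits by specificity into false
#' positives (who incur the intervention cost but no other effect) and true
#' negatives. Paths that do not apply to a strategy carry probability 0.
#'
#' @param params an `asd_parameters` object.
#' @param strategy a strategy label, see [strategies()].
#' @return A tibble `path`, `probability` summing to 1.
#' @examples
#' path_probabilities(asd_parameters(), "test_treat_6")
#' @export
path_probabilities <- function(params, strategy) {
  check_strategy(strategy)
  prev <- params$prevalence_asd
  p_ei <- params$p_early_intervention
  p <- c(
    true_positive = 0, false_negative_with_ei = 0,
    false_negative_without_ei = 0, false_positive = 0, true_negative = 0,
    asd_with_ei = 0, asd_without_ei = 0,
    non_asd_treated = 0, non_asd_untreated = 0
  )
  tc <- test_characteristics(params, strategy)
  if (!is.null(tc)) {
    p["true_positive"] <- prev * tc[["sens"]]
    p["false_negative_with_ei"] <- prev * (1 - tc[["sens"]]) * p_ei
    p["false_negative_without_ei"] <- prev * (1 - tc[["sens"]]) * (1 - p_ei)
    p["false_positive"] <- (1 - prev) * (1 - tc[["spec"]])
    p["true_negative"] <- (1 - prev) * tc[["spec"]]
  } else if (strategy == "status_quo") {
    p["asd_with_ei"] <- prev * p_ei
    p["asd_without_ei"] <- prev * (1 - p_ei)
    p["non_asd_untreated"] <- 1 - prev
  } else { # treat_all
    p["asd_with_ei"] <- prev
    p["non_asd_treated"] <- 1 - prev
  }
  tibble(path = names(p), probability = unname(p))
}

# Probability that a child with ASD receives early intervention by age 4.
p_ei_given_asd <- function(params, strategy) {
  tc <- test_characteristics(params, strategy)
  if (!is.null(tc)) {
    tc[["sens"]] + (1 - tc[["sens"]]) * params$p_early_intervention
  } else if (strategy == "treat_all") {
    1
  } else {
    params$p_early_intervention
  }
}

#' Terminal outcome mixture of a strategy
#'
#' Folds the decision tree into cohort fractions over the three lifetime
#' outcome classes. Early intervention lowers the ID risk of a child with
#' ASD from `p_id_without_ei` to `p_id_without_ei * rr_id_with_ei`;
#' children without ASD are unaffected by treatment (false positives incur
#' only cost).
#'
#' @inheritParams path_probabilities
#' @return A one-row tibble: `strategy`, `f_asd_id`, `f_asd_only`,
#'   `f_non_asd` (summing to 1), `f_received_ei` (fraction receiving early
#'   intervention, false positives included), `f_screened` (1 for test
#'   strategies, else 0).
#' @examples
#' outcome_mixture(asd_parameters(), "status_quo")
#' @export
outcome_mixture <- function(params, strategy) {
  check_strategy(strategy)
  prev <- params$prevalence_asd
  p_id <- params$p_id_without_ei
  rr <- params$rr_id_with_ei
  ei_asd <- p_ei_given_asd(params, strategy)
  f_asd_id <- prev * p_id * (ei_asd * rr + (1 - ei_asd))
  tc <- test_characteristics(params, strategy)
  f_fp <- if (is.null(tc)) 0 else (1 - prev) * (1 - tc[["spec"]])
  f_ei <- prev * ei_asd + f_fp +
    if (strategy == "treat_all") (1 - prev) else 0
  tibble(
    strategy = strategy,
    f_asd_id = f_asd_id,
    f_asd_only = prev - f_asd_id,
    f_non_asd = 1 - prev,
    f_received_ei = f_ei,
    f_screened = as.numeric(!is.null(tc))
  )
}

#' Outcome mixtures for several strategies at once
#'
#' @inheritParams path_probabilities
#' @param strategy_set character vector of strategy labels.
#' @return A tibble with one row per strategy, as [outcome_mixture()].
#' @export
outcome_mixtures <- function(params, strategy_set = strategy_labels()) {
  purrr::map_dfr(strategy_set, ~ outcome_mixture(params, .x))
}

#' Relative risk of ID comorbidity versus a baseline strategy
#'
#' The intermediate outcome of the model: the ratio of cohort ASD+ID
#' fractions, strategy over baseline.
#'
#' @inheritParams path_probabilities
#' @param baseline baseline strategy label (default `"status_quo"`).
#' @return A single risk ratio.
#' @export
relative_risk_id <- function(params, strategy, baseline = "status_quo") {
  base_f <- outcome_mixture(params, baseline)$f_asd_id
  if (base_f <= 0) {
    abort("Baseline ASD+ID prevalence is zero; relative risk undefined.")
  }
  outcome_mixture(params, strategy)$f_asd_id / base_f
}

#' Expected upfront cost of a strategy
#'
#' The pre-age-6 cost per cohort member: MRI screening applied to the whole
#' cohort in test strategies (where the perspective bears it), and the
#' early-intervention cost applied to every path that receives treatment,
#' false positives included. Upfront costs enter undiscounted at model start
#' by default; setting `discount_upfront_to_birth = TRUE` in the parameters
#' discounts them from the age-6 model start back to birth.
#'
#' @inheritParams path_probabilities
#' @param perspective one of `"societal"`, `"health_care"`, `"educational"`.
#' @return Expected upfront cost per cohort member (currency).
#' @examples
#' expected_upfront_cost(asd_parameters(), "test_treat_6")
#' @export
expected_upfront_cost <- function(params, strategy,
                                  perspective = "societal") {
  pview <- perspective_row(params, perspective)
  mix <- outcome_mixture(params, strategy)
  cost <- mix$f_received_ei * params$cost_ei * pview$ei_fraction +
    mix$f_screened * (if (pview$include_mri) params$cost_mri else 0)
  if (isTRUE(params$discount_upfront_to_birth)) {
    cost <- cost / (1 + params$discount_rate)^params$start_age
  }
  cost
}

perspective_row <- function(params, perspective) {
  tab <- params$perspectives
  row <- tab[tab$perspective == perspective, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown perspective `", perspective, "`. Valid: ",
                 paste(tab$perspective, collapse = ", ")))
  }
  row
}
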