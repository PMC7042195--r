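# Strategy-level cost-effectiveness: expected costs/QALYs, ICERs, the
# dominance frontier, common-baseline ICERs, and the WTP decision rule.

#' Expected lifetime cost and QALYs of each strategy
#'
#' Folds the decision tree into the Markov payoffs: for each strategy,
#' expected cost is the upfront (screening + early intervention) cost plus
#' the mixture-weighted discounted lifetime costs of the three outcome
#' classes, and expected QALYs are the mixture-weighted discounted QALYs.
#' ID prevalence and its relative risk versus the baseline are carried as
#' intermediate outcomes.
#'
#' @param params an `asd_parameters` object.
#' @param lt an `asd_life_table`.
#' @param perspective perspective label (default `"societal"`).
#' @param strategy_set strategies to evaluate (default all four).
#' @param baseline strategy used for the relative-risk column.
#' @return A tibble with one row per strategy: `strategy`, `perspective`,
#'   `upfront_cost`, `expected_cost`, `expected_qalys`, `id_prevalence`,
#'   `rr_vs_baseline`.
#' @examples
#' summarize_strategies(asd_parameters(), bundled_life_table())
#' @export
summarize_strategies <- function(params, lt, perspective = "societal",
                                 strategy_set = strategy_labels(),
                                 baseline = "status_quo") {
  payoffs <- purrr::map_dfr(
    outcome_classes(),
    ~ markov_payoff(params, lt, .x, perspective)
  )
  qaly_by_class <- setNames(payoffs$discounted_qalys, payoffs$outcome_class)
  cost_by_class <- setNames(payoffs$discounted_cost, payoffs$outcome_class)
  base_f <- outcome_mixture(params, baseline)$f_asd_id
  purrr::map_dfr(strategy_set, function(s) {
    mix <- outcome_mixture(params, s)
    f <- c(non_asd = mix$f_non_asd, asd_only = mix$f_asd_only,
           asd_id = mix$f_asd_id)
    upfront <- expected_upfront_cost(params, s, perspective)
    tibble(
      strategy = s,
      perspective = perspective,
      upfront_cost = upfront,
      expected_cost = upfront + sum(f * cost_by_class[names(f)]),
      expected_qalys = sum(f * qaly_by_class[names(f)]),
      id_prevalence = mix$f_asd_id,
      rr_vs_baseline = if (base_f > 0) mix$f_asd_id / base_f else NA_real_
    )
  })
}

summary_pair <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("Expected a one-row strategy summary.")
    x <- as.list(x)
  }
  if (!all(c("expected_cost", "expected_qalys") %in% names(x))) {
    abort("A strategy summary needs `expected_cost` and `expected_qalys`.")
  }
  x
}

#' Incremental cost-effectiveness ratio of one strategy over another
#'
#' `(cost_higher - cost_lower) / (qalys_higher - qalys_lower)`. An equal
#' effect makes the ratio undefined and is an error; a higher strategy that
#' is both more effective and cheaper dominates, and no ratio is reported
#' (`NA` with a warning).
#'
#' @param higher,lower one-row strategy summaries (or named lists) with
#'   `expected_cost` and `expected_qalys`; perspectives must agree when
#'   present.
#' @return The ICER in currency per QALY.
#' @examples
#' icer(list(expected_cost = 296949, expected_qalys = 27.0563),
#'      list(expected_cost = 294586, expected_qalys = 27.0084))
#' @export
icer <- function(higher, lower) {
  higher <- summary_pair(higher); lower <- summary_pair(lower)
  if (!is.null(higher$perspective) && !is.null(lower$perspective) &&
      higher$perspective != lower$perspective) {
    abort("Cannot compare summaries from different perspectives.")
  }
  d_cost <- higher$expected_cost - lower$expected_cost
  d_eff <- higher$expected_qalys - lower$expected_qalys
  if (d_eff == 0) {
    abort("Undefined ICER: the two strategies have equal expected QALYs.")
  }
  if (d_eff > 0 && d_cost < 0) {
    warn("More effective and less costly: the higher strategy dominates; no ratio reported.")
    return(NA_real_)
  }
  d_cost / d_eff
}

# Pairwise ICER that tolerates a zero effect difference (returns signed
# infinity); used internally by sensitivity analysis, where a risk ratio of
# exactly 1 makes the comparison pure added cost.
pairwise_icer <- function(d_cost, d_eff) {
  if (d_eff == 0) return(sign(d_cost) * Inf)
  d_cost / d_eff
}

#' Dominance frontier and incremental ICERs
#'
#' Orders the strategies by effectiveness, removes strongly dominated
#' entries (costlier and no more effective than another), then iteratively
#' removes extended-dominated entries (incremental ICER at least that of a
#' more effective successor) until ICERs increase strictly along the
#' frontier. Common-baseline ICERs versus the least effective non-dominated
#' strategy are reported for every entry.
#'
#' @param summaries a tibble from [summarize_strategies()] (>= 2 rows, one
#'   perspective).
#' @param baseline strategy for the common-baseline ICER column (default
#'   the least-cost non-dominated strategy).
#' @return An object of class `asd_cea`: the summary tibble ordered by
#'   `expected_qalys` with columns `dominance` (`"none"`, `"strong"`,
#'   `"extended"`), `icer` (incremental, non-dominated entries only) and
#'   `icer_vs_baseline`.
#' @export
cea_frontier <- function(summaries, baseline = NULL) {
  if (nrow(summaries) < 2) abort("Need at least two strategy summaries.")
  if (length(unique(summaries$perspective)) > 1) {
    abort("All summaries must share one perspective.")
  }
  tab <- arrange(summaries, .data$expected_qalys, .data$expected_cost)
  tab$dominance <- "none"

  # strong dominance: some other strategy costs no more and is at least as
  # effective, strictly better in one dimension
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(tab))) {
      if (i == j) next
      if (tab$expected_cost[j] <= tab$expected_cost[i] &&
          tab$expected_qalys[j] >= tab$expected_qalys[i] &&
          (tab$expected_cost[j] < tab$expected_cost[i] ||
           tab$expected_qalys[j] > tab$expected_qalys[i])) {
        tab$dominance[i] <- "strong"
        break
      }
    }
  }

  # extended dominance: along the survivors, a higher incremental ICER than
  # a more effective successor removes the entry; repeat to convergence
  repeat {
    alive <- which(tab$dominance == "none")
    if (length(alive) < 3) break
    icers <- vapply(seq_along(alive)[-1], function(k) {
      pairwise_icer(
        tab$expected_cost[alive[k]] - tab$expected_cost[alive[k - 1]],
        tab$expected_qalys[alive[k]] - tab$expected_qalys[alive[k - 1]]
      )
    }, numeric(1))
    worse <- which(diff(icers) <= 0)
    if (length(worse) == 0) break
    tab$dominance[alive[worse[1] + 1]] <- "extended"
  }

  alive <- which(tab$dominance == "none")
  tab$icer <- NA_real_
  if (length(alive) > 1) {
    for (k in seq_along(alive)[-1]) {
      tab$icer[alive[k]] <- pairwise_icer(
        tab$expected_cost[alive[k]] - tab$expected_cost[alive[k - 1]],
        tab$expected_qalys[alive[k]] - tab$expected_qalys[alive[k - 1]]
      )
    }
  }

  if (is.null(baseline)) baseline <- tab$strategy[alive[1]]
  base_row <- tab[tab$strategy == baseline, ]
  if (nrow(base_row) == 0) abort(paste0("Baseline `", baseline,
                                        "` is not among the summaries."))
  tab$icer_vs_baseline <- vapply(seq_len(nrow(tab)), function(i) {
    if (tab$strategy[i] == baseline) return(NA_real_)
    pairwise_icer(tab$expected_cost[i] - base_row$expected_cost,
                  tab$expected_qalys[i] - base_row$expected_qalys)
  }, numeric(1))

  structure(list(summaries = tab, baseline = baseline), class = "asd_cea")
}

#' Common-baseline ICERs
#'
#' The ICER of every strategy against one fixed baseline (rather than
#' against the previous strategy on the frontier). The baseline itself is
#' skipped.
#'
#' @param summaries a tibble from [summarize_strategies()].
#' @param baseline baseline strategy label.
#' @return A tibble `strategy`, `icer_vs_baseline` (baseline row omitted).
#' @export
common_baseline_icers <- function(summaries, baseline = "status_quo") {
  base <- summaries[summaries$strategy == baseline, ]
  if (nrow(base) != 1) abort(paste0("Baseline `", baseline, "` not found."))
  rest <- summaries[summaries$strategy != baseline, ]
  tibble(
    strategy = rest$strategy,
    icer_vs_baseline = vapply(seq_len(nrow(rest)), function(i) {
      pairwise_icer(rest$expected_cost[i] - base$expected_cost,
                    rest$expected_qalys[i] - base$expected_qalys)
    }, numeric(1))
  )
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' Among non-dominated strategies, the most effective whose incremental ICER
#' is at or below the threshold; when none qualifies, the least-cost
#' strategy.
#'
#' @param cea an `asd_cea` object from [cea_frontier()].
#' @param wtp willingness to pay, in currency per QALY.
#' @return The chosen strategy label.
#' @export
optimal_strategy <- function(cea, wtp) {
  stopifnot(inherits(cea, "asd_cea"))
  tab <- cea$summaries
  alive <- tab[tab$dominance == "none", ]
  ok <- is.na(alive$icer) | alive$icer <= wtp
  qualified <- alive[cumprod(ok) == 1, ]  # frontier prefix below threshold
  qualified$strategy[nrow(qualified)]
}

#' Net monetary benefit of each strategy
#'
#' `expected_qalys * wtp - expected_cost` per strategy; the frontier-optimal
#' strategy at a threshold maximizes this quantity.
#'
#' @param summaries a tibble from [summarize_strategies()].
#' @param wtp willingness to pay, currency per QALY.
#' @return The input tibble with an `nmb` column, sorted by `nmb` descending.
#' @export
net_monetary_benefit <- function(summaries, wtp) {
  out <- mutate(summaries, nmb = .data$expected_qalys * wtp -
                  .data$expected_cost)
  arrange(out, desc(.data$nmb))
}

#' @export
print.asd_cea <- function(x, ...) {
  cat("<asd_cea> dominance frontier (baseline: ", x$baseline, ")\n", sep = "")
  print(x$summaries, n = nrow(x$summaries))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.asd_cea <- function(x, ...) {
  x$summaries
}

#' @exportS3Method generics::glance
glance.asd_cea <- function(x, ...) {
  tab <- x$summaries
  tibble(
    n_strategies = nrow(tab),
    n_dominated = sum(tab$dominance != "none"),
    perspective = tab$perspective[1],
    baseline = x$baseline,
    max_qalys = max(tab$expected_qalys),
    min_cost = min(tab$expected_cost)
  )
}

#' Round a strategy table for reporting
#'
#' Costs to whole dollars; QALYs, prevalences and risk ratios to four
#' decimal places. Internal arithmetic elsewhere is always full precision.
#'
#' @param tab a strategy summary tibble (optionally with ICER columns).
#' @return The rounded tibble.
#' @export
round_for_report <- function(tab) {
  money <- intersect(c("upfront_cost", "expected_cost", "icer",
                       "icer_vs_baseline", "nmb"), names(tab))
  fine <- intersect(c("expected_qalys", "id_prevalence", "rr_vs_baseline"),
                    names(tab))
  for (cn in money) tab[[cn]] <- round(tab[[cn]])
  for (cn in fine) tab[[cn]] <- round(tab[[cn]], 4)
  tab
}
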