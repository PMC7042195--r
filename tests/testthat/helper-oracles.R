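# Independent oracles used across the suite. These deliberately re-derive
# quantities by enumeration or closed form, never by calling the code paths
# they check.

# Decision-tree oracle: enumerate every branch combination of a strategy
# explicitly and accumulate terminal masses path by path.
oracle_mixture <- function(params, strategy) {
  prev <- params$prevalence_asd
  p_ei <- params$p_early_intervention
  p_id <- params$p_id_without_ei
  rr <- params$rr_id_with_ei
  tc <- switch(strategy,
    test_treat_6 = c(params$sens_mri_6, params$spec_mri_6),
    test_treat_12 = c(params$sens_mri_12, params$spec_mri_12),
    NULL
  )
  f_id <- 0; f_asd <- 0; f_non <- 0; f_ei <- 0
  add_asd_leaf <- function(mass, treated) {
    p_id_here <- if (treated) p_id * rr else p_id
    f_id <<- f_id + mass * p_id_here
    f_asd <<- f_asd + mass * (1 - p_id_here)
    if (treated) f_ei <<- f_ei + mass
  }
  if (!is.null(tc)) {
    sens <- tc[1]; spec <- tc[2]
    add_asd_leaf(prev * sens, treated = TRUE)                   # true +
    add_asd_leaf(prev * (1 - sens) * p_ei, treated = TRUE)      # FN, usual care EI
    add_asd_leaf(prev * (1 - sens) * (1 - p_ei), treated = FALSE)
    f_non <- f_non + (1 - prev) * (1 - spec)                    # false +
    f_ei <- f_ei + (1 - prev) * (1 - spec)
    f_non <- f_non + (1 - prev) * spec                          # true -
  } else if (strategy == "status_quo") {
    add_asd_leaf(prev * p_ei, treated = TRUE)
    add_asd_leaf(prev * (1 - p_ei), treated = FALSE)
    f_non <- f_non + (1 - prev)
  } else {
    add_asd_leaf(prev, treated = TRUE)
    f_non <- f_non + (1 - prev)
    f_ei <- f_ei + (1 - prev)
  }
  c(f_asd_id = f_id, f_asd_only = f_asd, f_non_asd = f_non,
    f_received_ei = f_ei)
}

# Frontier oracle: a strategy is strongly dominated by a single rival, and
# extended-dominated by a convex blend of two rivals that is at least as
# effective and cheaper (or as cheap and more effective).
oracle_frontier_dominated <- function(cost, eff) {
  n <- length(cost)
  dominated <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && cost[j] <= cost[i] && eff[j] >= eff[i] &&
          (cost[j] < cost[i] || eff[j] > eff[i])) {
        dominated[i] <- TRUE
      }
    }
  }
  for (i in seq_len(n)) {
    if (dominated[i]) next
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i %in% c(j, k) || j == k) next
        if (dominated[j] || dominated[k]) next
        de <- eff[k] - eff[j]
        if (de == 0) next
        alpha <- (eff[i] - eff[j]) / de
        if (alpha <= 0 || alpha >= 1) next
        blend_cost <- (1 - alpha) * cost[j] + alpha * cost[k]
        if (blend_cost <= cost[i]) dominated[i] <- TRUE
      }
    }
  }
  dominated
}

# Finite geometric sums: the closed-form payoffs of a constant-hazard table
# truncated at the terminal age.
oracle_geometric_qalys <- function(q_adj, w, r, n_cycles) {
  x <- (1 - q_adj) / (1 + r)
  if (x == 1) return(w * n_cycles)
  w * (1 - x^n_cycles) / (1 - x)
}

oracle_geometric_le <- function(q_adj, n_cycles) {
  s <- (1 - q_adj)^(1:(n_cycles - 1))
  sum(s)
}

base_params <- function(...) asd_parameters(...)

const_life_table <- function(q, min_age = 0, terminal_age = 110) {
  ages <- min_age:terminal_age
  qx <- rep(q, length(ages))
  qx[length(qx)] <- 1
  validate_life_table(tibble::tibble(age = ages, qx = qx))
}
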