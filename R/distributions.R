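# Moment matching, derived parameters, and seeded parameter sampling.

#' Beta shapes from a mean and standard deviation
#'
#' Solves the two moment equations of the beta distribution,
#' `mean = a/(a+b)` and `var = ab / ((a+b)^2 (a+b+1))`, for the shape
#' parameters. Feasibility requires `sd^2 < mean * (1 - mean)`.
#'
#' @param mean mean in (0, 1).
#' @param sd standard deviation, same scale.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_from_moments(0.15, 0.01)
#' @export
beta_from_moments <- function(mean, sd) {
  if (!(mean > 0 && mean < 1)) abort("`mean` must lie strictly in (0, 1).")
  if (sd <= 0) abort("`sd` must be > 0.")
  v <- sd^2
  bound <- mean * (1 - mean)
  if (v >= bound) {
    abort(paste0(
      "Infeasible beta moments: need sd^2 < mean*(1-mean) = ",
      format(bound), ", got sd^2 = ", format(v), "."
    ))
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Gamma shape and scale from a mean and standard deviation
#'
#' Solves `shape * scale = mean`, `shape * scale^2 = sd^2`.
#'
#' @param mean positive mean.
#' @param sd positive standard deviation.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_from_moments(2.18, 0.10)
#' @export
gamma_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) abort("`mean` and `sd` must both be > 0.")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Decompose an overall QOL weight into ASD-only and ASD+ID weights
#'
#' Given a population mean utility for ASD, the prevalence of comorbid ID
#' within ASD, and the utility decrement attributable to ID, solves the
#' linear system `(1-p) w_asd + p w_id = overall` and `w_asd - w_id = d`.
#' With the model's inputs (overall 0.6096, ID prevalence 0.32, decrement
#' 0.22) this reproduces the base-case weights 0.68 and 0.46.
#'
#' @param overall_mean mean utility over the ASD population, in \[0, 1\].
#' @param id_prevalence prevalence of comorbid ID among ASD, in \[0, 1\].
#' @param id_decrement utility decrement for ID, in \[0, 1\].
#' @return Named numeric vector `c(qol_asd, qol_asd_id)`.
#' @export
decompose_qol_weights <- function(overall_mean, id_prevalence, id_decrement) {
  for (v in c(overall_mean, id_prevalence, id_decrement)) {
    if (v < 0 || v > 1) abort("All inputs must lie in [0, 1].")
  }
  qol_asd <- overall_mean + id_prevalence * id_decrement
  qol_asd_id <- qol_asd - id_decrement
  if (qol_asd > 1 || qol_asd_id < 0) {
    abort(paste0(
      "Decomposition leaves a weight outside [0, 1]: qol_asd = ",
      format(qol_asd), ", qol_asd_id = ", format(qol_asd_id), "."
    ))
  }
  c(qol_asd = qol_asd, qol_asd_id = qol_asd_id)
}

#' Risk ratio of ID implied by an IQ gain
#'
#' Early intervention is modelled as shifting the IQ distribution of
#' children with ASD upward by `iq_gain` points; the ID risk ratio is the
#' proportion below the ID threshold after the shift over the proportion
#' below it before, under a Gaussian base distribution:
#' `P(IQ + gain < threshold) / P(IQ < threshold)`.
#'
#' This derivation is informational: the pipeline uses the base-case risk
#' ratio 0.61 directly.
#'
#' @param base_iq_mean,base_iq_sd moments of the base IQ distribution.
#' @param iq_gain IQ points added by early intervention.
#' @param threshold ID threshold (default 70).
#' @return The risk ratio, in (0, 1\] for non-negative gains.
#' @export
derive_id_risk_ratio <- function(base_iq_mean, base_iq_sd, iq_gain,
                                 threshold = 70) {
  if (base_iq_sd <= 0) abort("`base_iq_sd` must be > 0.")
  p_base <- pnorm(threshold, mean = base_iq_mean, sd = base_iq_sd)
  if (p_base <= 0) abort("Baseline probability of ID is zero; ratio undefined.")
  p_shift <- pnorm(threshold, mean = base_iq_mean + iq_gain, sd = base_iq_sd)
  p_shift / p_base
}

# Deterministic per-parameter substream seed: master seed plus a polynomial
# hash of the parameter name, reduced mod 2^31 - 1. Adding a parameter to a
# spec therefore never perturbs the draws of the others.
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

validate_psa_specs <- function(specs) {
  required <- c("parameter", "family", "mean", "sd")
  if (!all(required %in% names(specs))) {
    abort("Distribution specs need columns parameter, family, mean, sd.")
  }
  bad <- setdiff(specs$family, c("beta", "gamma", "fixed"))
  if (length(bad) > 0) {
    abort(paste0("Unknown distribution family: ", paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(specs))) {
    fam <- specs$family[i]
    m <- specs$mean[i]; s <- specs$sd[i]
    if (fam == "beta") beta_from_moments(m, s)      # errors if infeasible
    if (fam == "gamma") gamma_from_moments(m, s)
  }
  invisible(specs)
}

#' Draw parameter values for probabilistic sensitivity analysis
#'
#' Draws `n` values per uncertain parameter, each from its moment-matched
#' beta or gamma distribution, using an independent deterministic substream
#' per parameter derived from the master seed. Columns for parameters with
#' `family = "fixed"` (and any parameter absent from `specs`) repeat the
#' base-case value.
#'
#' @param base an `asd_parameters` object supplying fixed values.
#' @param specs a tibble of distribution specs (see [default_psa_specs()]).
#' @param n number of draws.
#' @param seed master seed; identical seeds give identical draws.
#' @return A tibble with `n` rows, one column per sampled parameter.
#' @export
sample_parameter_draws <- function(base, specs = default_psa_specs(), n,
                                   seed) {
  if (missing(seed) || is.null(seed)) abort("A `seed` is required.")
  if (n < 1) abort("`n` must be >= 1.")
  validate_psa_specs(specs)
  draws <- purrr::pmap(specs, function(parameter, family, mean, sd, ...) {
    if (family == "fixed") return(rep(base[[parameter]], n))
    withr_seed <- substream_seed(seed, parameter)
    set.seed(withr_seed)
    if (family == "beta") {
      sh <- beta_from_moments(mean, sd)
      rbeta(n, sh[["shape1"]], sh[["shape2"]])
    } else {
      sh <- gamma_from_moments(mean, sd)
      rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
    }
  })
  names(draws) <- specs$parameter
  as_tibble(draws)
}

#' Sample one parameter set
#'
#' A single Monte Carlo realisation of the uncertain parameters layered on
#' the base case. Parameters marked fixed (test characteristics, costs) keep
#' their base values. The ordering check between the two QOL weights is
#' relaxed: the overlapping uncertainty ranges are allowed to cross, which
#' is what produces negative incremental QALYs in the PSA.
#'
#' @inheritParams sample_parameter_draws
#' @return A validated `asd_parameters` object.
#' @export
sample_parameter_set <- function(base, specs = default_psa_specs(), seed) {
  row <- sample_parameter_draws(base, specs, n = 1, seed = seed)
  out <- base
  for (nm in names(row)) out[[nm]] <- row[[nm]][1]
  validate_parameters(out, check_qol_order = FALSE)
  out
}
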