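# Base-case model parameters, validation, and configuration loading.

#' Base-case model parameters
#'
#' Construct the full parameter set of the screening model: ASD prevalence
#' among high-risk infant siblings, MRI test characteristics at 6 and 12
#' months, the probability of receiving early intensive behavioural
#' intervention (EIBI) under usual care, the risk of intellectual disability
#' (ID) without early intervention and the risk ratio with it, mortality
#' hazard ratios, quality-of-life (QOL) weights, upfront and annual costs,
#' and the discount rate. Defaults are the model's base case; any field can
#' be overridden by name.
#'
#' Annual ASD-related costs are age-banded (6-17, 18-21, 22+) and held in
#' `annual_costs` as societal totals; per-perspective accounting applies the
#' fractions in `perspectives`. `annual_cost_scale_asd` and
#' `annual_cost_scale_asd_id` rescale the two cost blocks (used by one-way
#' sensitivity analysis over a +/- 25% band).
#'
#' @param ... named overrides of any parameter field.
#' @param check logical; validate the result (default `TRUE`).
#'
#' @return A named list of class `"asd_parameters"`.
#' @examples
#' p <- asd_parameters()
#' p$prevalence_asd
#' asd_parameters(rr_id_with_ei = 1) # early intervention with no ID effect
#' @export
asd_parameters <- function(..., check = TRUE) {
  params <- default_parameter_list()
  overrides <- list(...)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("All overrides must be named.")
    }
    unknown <- setdiff(names(overrides), names(params))
    if (length(unknown) > 0) {
      abort(paste0(
        "Unknown parameter(s): ", paste(unknown, collapse = ", "),
        ". Valid names: ", paste(names(params), collapse = ", ")
      ))
    }
    params <- modifyList(params, overrides)
  }
  params <- structure(params, class = "asd_parameters")
  if (check) validate_parameters(params)
  params
}

default_parameter_list <- function() {
  list(
    prevalence_asd       = 0.15,
    sens_mri_6           = 0.82,
    sens_mri_12          = 0.88,
    spec_mri_6           = 1.00,
    spec_mri_12          = 0.95,
    p_early_intervention = 0.62,
    p_id_without_ei      = 0.37,
    rr_id_with_ei        = 0.61,
    hr_asd               = 2.18,
    hr_asd_id            = 5.78,
    qol_asd              = 0.68,
    qol_asd_id           = 0.46,
    cost_mri             = 1814,
    cost_ei              = 148367,
    annual_costs         = default_cost_schedule(),
    annual_cost_scale_asd    = 1,
    annual_cost_scale_asd_id = 1,
    discount_rate        = 0.03,
    perspectives         = default_perspectives(),
    # QOL weights stable in childhood; optional linear adult decline
    # (disabled by default: no quantified schedule is assumed).
    qol_decline_per_year = 0,
    qol_decline_start_age = 18,
    qol_floor            = 0,
    # Upfront (pre-age-6) costs enter undiscounted at model start by
    # default; set TRUE to discount them from age 6 back to birth.
    discount_upfront_to_birth = FALSE,
    start_age            = 6,
    terminal_age         = 110
  )
}

#' Age-banded annual cost schedule (societal totals, 2018 USD)
#'
#' Annual ASD-related costs by outcome class and age band. The non-ASD class
#' carries zero annual cost by construction: its members are identical
#' across strategies, so only differences matter.
#'
#' @return A tibble with columns `outcome_class`, `age_from`, `age_to`,
#'   `annual_cost`.
#' @export
default_cost_schedule <- function() {
  tibble(
    outcome_class = rep(c("asd_only", "asd_id", "non_asd"), times = c(3, 3, 1)),
    age_from = c(6, 18, 22, 6, 18, 22, 6),
    age_to   = c(17, 21, Inf, 17, 21, Inf, Inf),
    annual_cost = c(58526, 69889, 54154, 95983, 127718, 96247, 0)
  )
}

#' Cost perspectives
#'
#' The three cost ledgers used by the model. `annual_fraction` is the share
#' of the societal annual cost rows attributed to the perspective;
#' `include_mri` says whether the perspective bears the MRI screening cost;
#' `ei_fraction` is the share of the upfront early-intervention cost (100%
#' for every perspective: the direct costs of behavioural treatment are
#' assumed fully borne by each sector). The health-care and educational
#' fractions are loose calibrations, configurable via [load_parameters()].
#'
#' @return A tibble with one row per perspective.
#' @export
default_perspectives <- function() {
  tibble(
    perspective = c("societal", "health_care", "educational"),
    annual_fraction = c(1, 0.23, 0.12),
    include_mri = c(TRUE, TRUE, FALSE),
    ei_fraction = c(1, 1, 1)
  )
}

#' Validate a parameter set
#'
#' Checks probabilities and utility weights lie in \[0, 1\], hazard ratios
#' are positive, costs non-negative, the discount rate in \[0, 1\], and (by
#' default) that the ASD-only QOL weight is at least the ASD+ID weight.
#' Probabilistic sensitivity analysis relaxes the ordering check because
#' wide, overlapping QOL distributions can legitimately cross.
#'
#' @param params an `asd_parameters` object.
#' @param check_qol_order enforce `qol_asd >= qol_asd_id` (default `TRUE`).
#' @return `params`, invisibly, or an error describing the violated bound.
#' @export
validate_parameters <- function(params, check_qol_order = TRUE) {
  stopifnot(inherits(params, "asd_parameters") || is.list(params))
  prob_fields <- c(
    "prevalence_asd", "sens_mri_6", "sens_mri_12", "spec_mri_6",
    "spec_mri_12", "p_early_intervention", "p_id_without_ei",
    "rr_id_with_ei", "qol_asd", "qol_asd_id"
  )
  for (f in prob_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("`", f, "` must be a single value in [0, 1]; got ",
                   format(v), "."))
    }
  }
  for (f in c("hr_asd", "hr_asd_id")) {
    if (params[[f]] <= 0) {
      abort(paste0("`", f, "` must be > 0; got ", format(params[[f]]), "."))
    }
  }
  for (f in c("cost_mri", "cost_ei", "annual_cost_scale_asd",
              "annual_cost_scale_asd_id")) {
    if (params[[f]] < 0) {
      abort(paste0("`", f, "` must be >= 0; got ", format(params[[f]]), "."))
    }
  }
  if (params$discount_rate < 0 || params$discount_rate > 1) {
    abort("`discount_rate` must be in [0, 1].")
  }
  if (check_qol_order && params$qol_asd < params$qol_asd_id) {
    abort(paste0(
      "`qol_asd` (", params$qol_asd, ") must be >= `qol_asd_id` (",
      params$qol_asd_id, "): co-occurring ID cannot raise the QOL weight."
    ))
  }
  sched <- params$annual_costs
  if (any(sched$annual_cost < 0)) abort("Annual costs must be >= 0.")
  if (!all(c("asd_only", "asd_id", "non_asd") %in% sched$outcome_class)) {
    abort("Cost schedule must cover outcome classes asd_only, asd_id, non_asd.")
  }
  for (cls in unique(sched$outcome_class)) {
    bands <- sched[sched$outcome_class == cls, ]
    bands <- bands[order(bands$age_from), ]
    if (bands$age_from[1] > params$start_age) {
      abort(paste0("Cost bands for ", cls, " must start at or before age ",
                   params$start_age, "."))
    }
    if (nrow(bands) > 1 &&
        any(bands$age_from[-1] != bands$age_to[-nrow(bands)] + 1)) {
      abort(paste0("Cost bands for ", cls, " have gaps or overlaps."))
    }
    if (!is.infinite(bands$age_to[nrow(bands)])) {
      abort(paste0("Last cost band for ", cls, " must be open-ended (age_to = Inf)."))
    }
  }
  if (params$terminal_age <= params$start_age) {
    abort("`terminal_age` must exceed `start_age`.")
  }
  invisible(params)
}

#' @export
print.asd_parameters <- function(x, ...) {
  cat("<asd_parameters>\n")
  scalars <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  df <- tibble(parameter = names(scalars), value = unlist(scalars))
  print(df, n = nrow(df))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.asd_parameters <- function(x, ...) {
  scalars <- x[vapply(x, function(v) is.atomic(v) && length(v) == 1, logical(1))]
  tibble(parameter = names(scalars), value = unname(unlist(scalars)))
}

#' Load parameters from a configuration file
#'
#' Reads a hierarchical YAML (or JSON) document with optional sections
#' `parameters` (flat name/value overrides of [asd_parameters()] fields),
#' `cost_schedule` (rows `outcome_class`, `age_from`, `age_to`,
#' `annual_cost`), and `perspectives` (rows matching
#' [default_perspectives()]). Omitted keys keep their base-case defaults;
#' unknown keys are a configuration error naming the key.
#'
#' @param source path to a `.yaml`/`.yml`/`.json` file, or a list with the
#'   same structure.
#' @return A validated `asd_parameters` object.
#' @export
load_parameters <- function(source = NULL) {
  cfg <- read_config_document(source)
  build_parameters_from_config(cfg)
}

read_config_document <- function(source) {
  if (is.null(source)) return(list())
  if (is.list(source)) return(source)
  if (!file.exists(source)) abort(paste0("Config file not found: ", source))
  if (grepl("\\.json$", source, ignore.case = TRUE)) {
    jsonlite::read_json(source, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(source)
  }
}

build_parameters_from_config <- function(cfg) {
  known_sections <- c("parameters", "cost_schedule", "perspectives",
                      "distributions", "ranges", "run")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration section(s): ",
                 paste(unknown, collapse = ", ")))
  }
  overrides <- cfg$parameters %||% list()
  valid <- names(default_parameter_list())
  unknown <- setdiff(names(overrides), valid)
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter key(s) in configuration: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$cost_schedule)) {
    cs <- cfg$cost_schedule
    # YAML open-ended bands arrive as mixed int/Inf lists; flatten per column
    to_num <- function(x) {
      x <- unlist(x, use.names = FALSE)
      if (is.character(x)) x[x == ".inf"] <- "Inf"
      as.numeric(x)
    }
    overrides$annual_costs <- tibble(
      outcome_class = as.character(unlist(cs$outcome_class)),
      age_from = to_num(cs$age_from),
      age_to = to_num(cs$age_to),
      annual_cost = to_num(cs$annual_cost)
    )
  }
  if (!is.null(cfg$perspectives)) {
    overrides$perspectives <- as_tibble(as.data.frame(cfg$perspectives))
  }
  do.call(asd_parameters, overrides)
}

#' Replace a single parameter by name
#'
#' Used by one-way sensitivity analysis and scenario sweeps. Scale
#' parameters (`annual_cost_scale_asd`, `annual_cost_scale_asd_id`) rescale
#' the corresponding annual-cost rows at evaluation time, so the schedule
#' itself is never edited.
#'
#' @param params an `asd_parameters` object.
#' @param name a scalar parameter field name.
#' @param value the replacement value.
#' @param check_qol_order passed to [validate_parameters()].
#' @return A new validated `asd_parameters` object.
#' @export
set_parameter <- function(params, name, value, check_qol_order = TRUE) {
  valid <- names(default_parameter_list())
  if (!name %in% valid) {
    abort(paste0("Unknown parameter `", name, "`. Valid names: ",
                 paste(valid, collapse = ", ")))
  }
  params[[name]] <- value
  validate_parameters(params, check_qol_order = check_qol_order)
  params
}

#' One-way sensitivity ranges
#'
#' The low/high envelope tested for each parameter in one-way sensitivity
#' analysis. Annual cost blocks are varied through their scale parameters
#' over 0.75-1.25 (a +/- 25% band).
#'
#' @return A tibble with columns `parameter`, `low`, `high`.
#' @export
default_ranges <- function() {
  tibble(
    parameter = c(
      "prevalence_asd", "sens_mri_6", "sens_mri_12", "spec_mri_6",
      "spec_mri_12", "p_early_intervention", "p_id_without_ei",
      "rr_id_with_ei", "hr_asd", "hr_asd_id", "qol_asd", "qol_asd_id",
      "cost_mri", "cost_ei", "annual_cost_scale_asd",
      "annual_cost_scale_asd_id", "discount_rate"
    ),
    low = c(0.01, 0.48, 0.48, 0.90, 0.90, 0.48, 0.10, 0.32, 2.00, 4.94,
            0.47, 0.34, 1288, 112958, 0.75, 0.75, 0.01),
    high = c(0.19, 0.97, 0.97, 1.00, 1.00, 0.76, 0.63, 1.00, 2.38, 6.95,
             0.70, 0.58, 2464, 183777, 1.25, 1.25, 0.05)
  )
}

#' Distribution specifications for probabilistic sensitivity analysis
#'
#' Each uncertain parameter carries a distribution family and the (mean, sd)
#' moments it must match: beta for probabilities and utility weights, gamma
#' for hazard ratios. Test characteristics and all costs are held fixed in
#' PSA and varied only in one-way analysis.
#'
#' @return A tibble with columns `parameter`, `family`, `mean`, `sd`.
#' @export
default_psa_specs <- function() {
  tibble(
    parameter = c("prevalence_asd", "p_early_intervention",
                  "p_id_without_ei", "rr_id_with_ei", "hr_asd", "hr_asd_id",
                  "qol_asd", "qol_asd_id"),
    family = c("beta", "beta", "beta", "beta", "gamma", "gamma",
               "beta", "beta"),
    mean = c(0.15, 0.62, 0.37, 0.61, 2.18, 5.78, 0.68, 0.46),
    sd   = c(0.01, 0.07, 0.04, 0.20, 0.10, 0.46, 0.23, 0.17)
  )
}
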