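# Run orchestration: configuration loading, base-case / tornado / PSA runs
# with machine-readable outputs and a manifest.

#' Load a full run configuration
#'
#' Reads the hierarchical YAML/JSON configuration (sections `parameters`,
#' `cost_schedule`, `perspectives`, `distributions`, `ranges`, `run`) into a
#' validated parameter set plus run settings. The bundled default
#' configuration (`system.file("extdata", "default_config.yaml", package =
#' "asdscreen")`) reproduces the base case exactly; with `source = NULL`
#' everything defaults.
#'
#' @param source path to a config file, a list, or `NULL` for defaults.
#' @return A list of class `asd_config`: `params` (an `asd_parameters`),
#'   `specs`, `ranges`, and `run` (perspectives, wtp, psa_n, seed, baseline,
#'   comparator, life_table path or `NULL`).
#' @export
load_config <- function(source = NULL) {
  cfg <- read_config_document(source)
  params <- build_parameters_from_config(cfg)
  specs <- if (!is.null(cfg$distributions)) {
    validate_psa_specs(as_tibble(as.data.frame(cfg$distributions)))
  } else {
    default_psa_specs()
  }
  ranges <- if (!is.null(cfg$ranges)) {
    as_tibble(as.data.frame(cfg$ranges))
  } else {
    NULL
  }
  run_defaults <- list(
    perspectives = c("societal", "health_care", "educational"),
    wtp = c(50000, 100000),
    psa_n = 10000,
    seed = NULL,
    baseline = "status_quo",
    comparator = "test_treat_6",
    life_table = NULL
  )
  run <- modifyList(run_defaults, cfg$run %||% list())
  structure(list(params = params, specs = specs, ranges = ranges, run = run),
            class = "asd_config")
}

config_life_table <- function(config) {
  if (!is.null(config$run$life_table)) {
    read_life_table(config$run$life_table)
  } else {
    bundled_life_table()
  }
}

# Small deterministic content digest (a modular polynomial hash over the
# deparsed object), so a manifest identifies its inputs without external
# dependencies.
config_digest <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 131 + k) %% 2147483629
  sprintf("%08x", h)
}

write_manifest <- function(out_dir, config, outputs, extra = list()) {
  manifest <- c(list(
    config_digest = config_digest(list(
      tidy(config$params), config$specs, config$ranges,
      config$run[setdiff(names(config$run), "life_table")]
    )),
    seed = config$run$seed,
    perspectives = config$run$perspectives,
    strategies = strategy_labels(),
    wtp = config$run$wtp,
    psa_n = config$run$psa_n,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

write_result_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the base case and export per-perspective result tables
#'
#' Evaluates all four strategies under each configured perspective, assembles
#' the dominance frontier, and writes one CSV per perspective (strategy,
#' lifetime cost, QALYs, incremental ICER, common-baseline ICER, ID
#' prevalence and relative risk; ordered least to most effective, costs
#' rounded to whole dollars and fine quantities to 4 decimal places) plus a
#' run manifest.
#'
#' @param config an `asd_config` from [load_config()] (or `NULL` for
#'   defaults).
#' @param out_dir output directory (created if missing).
#' @return Named list of written file paths, invisibly.
#' @export
run_base_case <- function(config = load_config(), out_dir) {
  if (is.null(config)) config <- load_config()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lt <- config_life_table(config)
  outputs <- list()
  for (pv in config$run$perspectives) {
    summaries <- summarize_strategies(config$params, lt, pv,
                                      baseline = config$run$baseline)
    cea <- cea_frontier(summaries, baseline = config$run$baseline)
    tab <- round_for_report(tidy(cea))
    path <- file.path(out_dir, paste0("base_case_", pv, ".csv"))
    write_result_csv(tab, path)
    outputs[[paste0("base_case_", pv)]] <- path
  }
  outputs$manifest <- write_manifest(out_dir, config, outputs)
  invisible(outputs)
}

#' Run the tornado analysis and export the sorted bars
#'
#' @inheritParams run_base_case
#' @return Named list of written file paths, invisibly.
#' @export
run_tornado <- function(config = load_config(), out_dir) {
  if (is.null(config)) config <- load_config()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lt <- config_life_table(config)
  ranges <- config$ranges %||%
    default_tornado_ranges(config$run$comparator, config$run$baseline)
  tab <- if (nrow(ranges) == 0) {
    tibble(parameter = character(), low = numeric(), high = numeric(),
           icer_at_low = numeric(), icer_at_high = numeric(),
           bar_width = numeric())
  } else {
    tidy(tornado(config$params, lt, ranges,
                 comparator = config$run$comparator,
                 baseline = config$run$baseline,
                 perspective = config$run$perspectives[1]))
  }
  path <- file.path(out_dir, "tornado.csv")
  write_result_csv(tab, path)
  outputs <- list(tornado = path)
  outputs$manifest <- write_manifest(out_dir, config, outputs)
  invisible(outputs)
}

#' Run the PSA and export the scatter and its summary
#'
#' Writes `psa_scatter.csv` (draw, d_cost, d_qaly), `psa_summary.json`
#' (quadrant and threshold proportions) and the manifest. A missing seed is
#' an error: no silently nondeterministic runs.
#'
#' @inheritParams run_base_case
#' @return Named list of written file paths, invisibly.
#' @export
run_psa_report <- function(config = load_config(), out_dir) {
  if (is.null(config)) config <- load_config()
  if (is.null(config$run$seed)) {
    abort("The configuration must carry `run: seed:` for a PSA run.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lt <- config_life_table(config)
  psa <- run_psa(config$params, lt, n = config$run$psa_n,
                 seed = config$run$seed, specs = config$specs,
                 comparator = config$run$comparator,
                 baseline = config$run$baseline,
                 perspective = config$run$perspectives[1])
  scatter <- tibble(draw = psa$draw, d_cost = psa$d_cost,
                    d_qaly = psa$d_qalys)
  scatter_path <- file.path(out_dir, "psa_scatter.csv")
  write_result_csv(scatter, scatter_path)
  summary_tab <- ce_plane_summary(psa, config$run$wtp)
  summary_path <- file.path(out_dir, "psa_summary.json")
  jsonlite::write_json(
    as.list(setNames(summary_tab$value, summary_tab$measure)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  outputs <- list(psa_scatter = scatter_path, psa_summary = summary_path)
  outputs$manifest <- write_manifest(out_dir, config, outputs)
  invisible(outputs)
}
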