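# Life tables: Gompertz-Makeham synthesis, validation, and delimited I/O.

new_life_table <- function(age, qx) {
  lt <- tibble(age = as.numeric(age), qx = as.numeric(qx))
  class(lt) <- c("asd_life_table", class(lt))
  validate_life_table(lt)
}

#' Validate a life table
#'
#' A life table is a tibble of consecutive integer ages with annual death
#' probabilities `qx` in \[0, 1\] and `qx = 1` in the terminal row.
#'
#' @param lt a tibble with columns `age`, `qx`.
#' @return `lt`, invisibly classed as `asd_life_table`, or an error.
#' @export
validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    abort("A life table needs columns `age` and `qx`.")
  }
  if (nrow(lt) < 2) abort("A life table needs at least two ages.")
  if (any(diff(lt$age) != 1)) {
    gap <- lt$age[which(diff(lt$age) != 1)[1]] + 1
    abort(paste0("Life table has a gap: age ", gap, " is missing."))
  }
  if (any(lt$qx < 0 | lt$qx > 1)) abort("All `qx` must lie in [0, 1].")
  if (lt$qx[nrow(lt)] != 1) {
    abort("The terminal life-table row must carry qx = 1.")
  }
  if (!inherits(lt, "asd_life_table")) {
    class(lt) <- c("asd_life_table", class(lt))
  }
  invisible(lt)
}

#' Synthesize a life table from a Gompertz-Makeham hazard
#'
#' The mortality hazard at age `x` is `lambda + a * exp(b x)`: a flat
#' background component dominating childhood plus an exponentially rising
#' senescent component. Annual death probabilities are the exact integral of
#' the hazard over each year of age,
#' `q(x) = 1 - exp(-lambda - (a/b) e^{bx} (e^b - 1))`, with the terminal age
#' forced to `q = 1`.
#'
#' @param lambda background annual hazard (>= 0).
#' @param a baseline senescent hazard (>= 0).
#' @param b senescence rate per year (> 0 when `a > 0`).
#' @param terminal_age last age in the table (>= 100).
#' @param min_age first age (default 0).
#' @return An `asd_life_table` tibble.
#' @examples
#' lt <- make_life_table(0.0004, 3e-5, 0.095)
#' head(lt)
#' @export
make_life_table <- function(lambda = 4e-04, a = 2.4347972e-05, b = 0.0955,
                            terminal_age = 110, min_age = 0) {
  if (lambda < 0 || a < 0) abort("`lambda` and `a` must be >= 0.")
  if (a > 0 && b <= 0) abort("`b` must be > 0 when `a` > 0.")
  if (terminal_age < 100) abort("`terminal_age` must be >= 100.")
  age <- min_age:terminal_age
  cum_hazard <- if (a == 0) {
    rep(lambda, length(age))
  } else {
    lambda + (a / b) * exp(b * age) * (expm1(b))
  }
  qx <- -expm1(-cum_hazard)
  qx <- pmin(qx, 1)
  qx[length(qx)] <- 1
  new_life_table(age, qx)
}

#' Bundled synthetic life table
#'
#' A deterministic built-in table over ages 0-110 generated from the default
#' Gompertz-Makeham hazard, calibrated (by bisection on the senescent
#' hazard, see [calibrate_gompertz_makeham()]) so that remaining life
#' expectancy at age 6 falls in the 70-75 year window typical of a recent
#' U.S. period life table. It is an emulation of such a table's shape --
#' near-flat child mortality, exponential adult rise, terminal age with
#' death probability 1 -- not a transcription of any federal table; supply a
#' real table through [read_life_table()] for calibrated survival-dependent
#' results.
#'
#' @return An `asd_life_table` tibble, byte-identical across calls.
#' @export
bundled_life_table <- function() {
  make_life_table()
}

#' Calibrate the senescent hazard to a target life expectancy
#'
#' Bisects on the baseline senescent hazard `a` (log scale) until the
#' undiscounted remaining life expectancy at `at_age` matches `target_le`
#' within `tol`, holding `lambda` and `b` fixed.
#'
#' @param target_le target remaining life expectancy in years.
#' @param at_age age at which life expectancy is evaluated (default 6).
#' @inheritParams make_life_table
#' @param tol convergence tolerance in years.
#' @return The calibrated Gompertz-Makeham parameters as a named list.
#' @export
calibrate_gompertz_makeham <- function(target_le = 73, at_age = 6,
                                       lambda = 4e-04, b = 0.0955,
                                       terminal_age = 110, tol = 1e-6) {
  le_for <- function(log_a) {
    lt <- make_life_table(lambda, exp(log_a), b, terminal_age)
    life_expectancy(cohort_trace(lt, hr = 1, start_age = at_age))
  }
  lo <- log(1e-9); hi <- log(1e-2)
  if (le_for(lo) < target_le || le_for(hi) > target_le) {
    abort("Target life expectancy is outside the calibration bracket.")
  }
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (le_for(mid) > target_le) lo <- mid else hi <- mid
    if (abs(le_for(mid) - target_le) < tol) break
  }
  list(lambda = lambda, a = exp((lo + hi) / 2), b = b,
       terminal_age = terminal_age)
}

#' Read a life table from a delimited text file
#'
#' Expects a two-column header-bearing file (`age`, `qx`), comma- or
#' whitespace-delimited, and validates it (consecutive ages, terminal
#' `qx = 1`).
#'
#' @param path file path.
#' @return An `asd_life_table` tibble.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Life table file not found: ", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  df <- read.table(path, header = TRUE, sep = sep,
                   strip.white = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("age", "qx") %in% names(df))) {
    abort("Life table file must have header columns `age` and `qx`.")
  }
  validate_life_table(as_tibble(df[, c("age", "qx")]))
}

#' Write a life table to a CSV file
#'
#' @param lt an `asd_life_table` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  write.csv(as.data.frame(lt[, c("age", "qx")]), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Random parameter scenarios for property sweeps
#'
#' Draws `n` parameter sets uniformly and independently within the given
#' ranges (defaults: the one-way sensitivity envelope), using one
#' deterministic substream per parameter. Scenarios violating the
#' cross-parameter ordering `qol_asd >= qol_asd_id` are redrawn so every
#' returned set passes full validation.
#'
#' @param n number of scenarios (>= 1).
#' @param ranges tibble `parameter`, `low`, `high`; see [default_ranges()].
#' @param seed master seed.
#' @param base an `asd_parameters` object supplying unvaried fields.
#' @return A list of `n` validated `asd_parameters` objects.
#' @export
random_scenarios <- function(n, ranges = default_ranges(), seed,
                             base = asd_parameters()) {
  if (missing(seed) || is.null(seed)) abort("A `seed` is required.")
  if (n < 1) abort("`n` must be >= 1.")
  if (any(ranges$low > ranges$high)) {
    bad <- ranges$parameter[ranges$low > ranges$high][1]
    abort(paste0("Infeasible range for `", bad, "`: low > high."))
  }
  draws <- purrr::pmap(ranges, function(parameter, low, high, ...) {
    set.seed(substream_seed(seed, parameter))
    runif(n, low, high)
  })
  names(draws) <- ranges$parameter
  draws <- as_tibble(draws)
  if (all(c("qol_asd", "qol_asd_id") %in% names(draws))) {
    set.seed(substream_seed(seed, "qol_resample"))
    bad <- which(draws$qol_asd < draws$qol_asd_id)
    i <- ranges$parameter %in% c("qol_asd", "qol_asd_id")
    rng <- ranges[i, ]
    while (length(bad) > 0) {
      for (j in bad) {
        draws$qol_asd[j] <- runif(1, rng$low[rng$parameter == "qol_asd"],
                                  rng$high[rng$parameter == "qol_asd"])
        draws$qol_asd_id[j] <- runif(1, rng$low[rng$parameter == "qol_asd_id"],
                                     rng$high[rng$parameter == "qol_asd_id"])
      }
      bad <- which(draws$qol_asd < draws$qol_asd_id)
    }
  }
  purrr::map(seq_len(n), function(i) {
    out <- base
    for (nm in names(draws)) out[[nm]] <- draws[[nm]][i]
    validate_parameters(out)
    out
  })
}
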