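#' Default run configuration
#'
#' The full-scale reference configuration: 500 functional groups, 9
#' terraces, the default rate constants, and a 6-event, 100 mm regime.
#' All values are overridable from a YAML config file.
#'
#' @return A nested list (sections `pool`, `params`, `regime`, `scenario`,
#'   `numerics`, `output`, plus `schema`).
#' @export
default_config <- function() {
  list(
    schema = 1L,
    pool = list(m = 500L, K_min = 0.1, K_max = 3.5,
                E_min = 0.5, E_max = 3.5, epsilon = 1),
    params = list(Lambda0 = 0.3, B_R = 20, uptake_half_sat = 60, Gamma = 1,
                  M = 0.1, L = 2.5, I = 5, D = 0.64,
                  alpha1 = 0.0156, alpha2 = 0.0052, n_terraces = 9L),
    regime = list(k = 6L, T_event_days = 1, MAP = 100),
    scenario = list(spinup_years = 500L, drought_years = 60L,
                    MAP_drought = 40, recovery_years = 10L),
    numerics = list(dt = NA_real_, tol = 1e-6, max_years = 500L,
                    threshold = 0.01, inoculum = 0.01),
    output = list(dir = "."))
}

check_unknown_keys <- function(cfg, ref, path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(ref))
      stop(sprintf("unknown configuration key: %s", full))
    if (is.list(ref[[key]]) && !is.null(cfg[[key]])) {
      if (!is.list(cfg[[key]]))
        stop(sprintf("configuration section %s must be a mapping", full))
      check_unknown_keys(cfg[[key]], ref[[key]], full)
    }
  }
}

validate_config <- function(cfg) {
  with(cfg$pool, {
    if (K_min >= K_max) stop("invalid config: pool.K_min must be < pool.K_max")
    if (E_min >= E_max) stop("invalid config: pool.E_min must be < pool.E_max")
    if (epsilon <= 0) stop("invalid config: pool.epsilon must be > 0")
    if (m < 2) stop("invalid config: pool.m must be >= 2")
  })
  if (cfg$regime$k < 1) stop("invalid config: regime.k must be >= 1")
  if (cfg$regime$MAP < 0) stop("invalid config: regime.MAP must be >= 0")
  if (cfg$numerics$tol <= 0) stop("invalid config: numerics.tol must be > 0")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills every missing key from
#' [default_config()], rejects unknown keys, and validates the invariants
#' (trait ranges, event feasibility, positivity).
#'
#' @param path YAML file path; `NULL` returns the pure defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("configuration file must be a YAML mapping")
    check_unknown_keys(user, cfg)
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

#' @describeIn load_config write a configuration back to YAML;
#'   `load_config(write_config(cfg, f))` reproduces `cfg`.
#' @param cfg a configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param cfg a configuration list from [load_config()].
#' @return A list with `params` ([model_params()]), `regime`
#'   ([rainfall_regime()]), `scenario` ([drought_scenario()]), and
#'   `numerics` (with `dt` resolved to `T_event/4` when unset).
#' @export
config_to_objects <- function(cfg) {
  ranges <- trait_ranges(cfg$pool$K_min, cfg$pool$K_max,
                         cfg$pool$E_min, cfg$pool$E_max, cfg$pool$epsilon)
  pool <- build_pool(cfg$pool$m, ranges)
  params <- do.call(model_params, c(list(pool = pool), cfg$params))
  T_event <- cfg$regime$T_event_days / DAYS_PER_YEAR
  regime <- rainfall_regime(k = cfg$regime$k, T_event = T_event,
                            MAP = cfg$regime$MAP)
  scenario <- drought_scenario(cfg$scenario$spinup_years,
                               cfg$scenario$drought_years,
                               cfg$regime$MAP, cfg$scenario$MAP_drought,
                               cfg$scenario$recovery_years)
  numerics <- cfg$numerics
  if (is.na(numerics$dt)) numerics$dt <- T_event / 4
  list(params = params, regime = regime, scenario = scenario,
       numerics = numerics)
}

#' Read and write daily precipitation files
#'
#' The daily exchange format is a two-column whitespace-separated text file:
#' day index (1-based, consecutive) and precipitation in mm/day.  Rates are
#' converted between mm/day and the internal mm/year at this boundary only;
#' internally a file-based forcing is piecewise constant over each day.
#'
#' @param path file path.
#' @return `read_precip_file()` returns a [precip_series()].
#' @export
read_precip_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) stop("empty precipitation file")
  day <- numeric(n); mm <- numeric(n)
  for (ln in seq_len(n)) {
    fields <- strsplit(trimws(lines[ln]), "[ \t,]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2 || anyNA(vals))
      stop(sprintf("malformed precipitation row at line %d: '%s'",
                   ln, lines[ln]))
    if (vals[2] < 0)
      stop(sprintf("negative precipitation at line %d", ln))
    day[ln] <- vals[1]; mm[ln] <- vals[2]
  }
  if (any(day != seq_len(n)))
    stop("day indices must be consecutive starting at 1")
  precip_series(times = (day - 1) / DAYS_PER_YEAR, P = mm * DAYS_PER_YEAR,
                end = n / DAYS_PER_YEAR)
}

#' @rdname read_precip_file
#' @param x a [precip_series()] or [rainfall_regime()].
#' @param years for a regime, how many years of daily values to write.
#' @export
write_precip_file <- function(x, path, years = 1) {
  if (inherits(x, "rainfall_regime"))
    x <- build_series(x, years, dt = 1 / DAYS_PER_YEAR)
  if (!inherits(x, "precip_series"))
    stop("x must be a precip_series or rainfall_regime")
  ndays <- round(x$end * DAYS_PER_YEAR)
  t_days <- (seq_len(ndays) - 1) / DAYS_PER_YEAR
  mm_day <- series_at(t_days, x) / DAYS_PER_YEAR
  writeLines(sprintf("%d %.12g", seq_len(ndays), mm_day), path)
  invisible(path)
}

#' Ready-made configurations at three problem sizes
#'
#' `"tiny"` (5 groups x 2 terraces, seconds) for smoke tests, `"small"`
#' (100 groups x 9 terraces, relaxed tolerance) for property checks, and
#' `"full"` (500 groups x 9 terraces) for the full-scale reference runs.
#'
#' @param scale one of `"tiny"`, `"small"`, `"full"`.
#' @return A validated configuration list.
#' @export
make_fixture <- function(scale = c("tiny", "small", "full")) {
  scale <- match.arg(scale)
  cfg <- default_config()
  if (scale == "tiny") {
    cfg$pool$m <- 5L
    cfg$params$n_terraces <- 2L
    cfg$numerics$max_years <- 3L
    cfg$numerics$tol <- 1e-4
    cfg$scenario <- list(spinup_years = 3L, drought_years = 2L,
                         MAP_drought = 40, recovery_years = 2L)
  } else if (scale == "small") {
    cfg$pool$m <- 100L
    cfg$numerics$tol <- 1e-5
    cfg$numerics$max_years <- 300L
  }
  validate_config(cfg)
  cfg
}

#' Write community summaries as CSV
#'
#' One row per terrace plus a `"riverbed"` row, in the layout
#' (scenario id, year, terrace, B_total, diversity, centroid).
#'
#' @param summary a [community_summary()].
#' @param path CSV path.
#' @param scenario_id,year identifiers recorded in the output.
#' @export
write_summary_csv <- function(summary, path, scenario_id = "run", year = NA) {
  per <- summary$per_terrace
  df <- rbind(
    data.frame(scenario = scenario_id, year = year,
               terrace = as.character(per$terrace), B_total = per$B_total,
               diversity = per$diversity, centroid = per$centroid),
    data.frame(scenario = scenario_id, year = year, terrace = "riverbed",
               B_total = summary$riverbed_B_total,
               diversity = summary$riverbed_diversity,
               centroid = summary$riverbed_centroid))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
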