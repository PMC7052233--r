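DAYS_PER_YEAR <- 365

#' Annual square-wave rainfall regime
#'
#' Rainfall is modeled as `k` rectangular events per year, each of duration
#' `T_event` (years) and intensity `A` (mm/year while raining), all falling
#' in the first half of the year (the wet winter season); the second half is
#' dry.  The annual total satisfies `k * A * T_event = MAP` exactly.
#'
#' Default event start times are evenly spaced across the first half year
#' and snapped down to whole-day boundaries, so that daily-file export is
#' exact and event edges align with the integration grid.  Custom
#' `event_starts` (fractions of a year in `[0, 1/2)`) may be supplied.
#'
#' @param k number of rainfall events per year (>= 1).
#' @param T_event event duration in years (default one day, 1/365).
#' @param MAP mean annual precipitation in mm; exactly one of `MAP`, `A`
#'   must be given.
#' @param A event intensity in mm/year.
#' @param event_starts optional vector of k event start times (years).
#' @return An object of class `rainfall_regime` with fields `k`, `T_event`,
#'   `A` (mm/year), `A_mm_day` (mm/day), `MAP`, `event_starts`.
#' @examples
#' rainfall_regime(k = 6, MAP = 100)   # six one-day events of ~16.7 mm each
#' @export
rainfall_regime <- function(k, T_event = 1 / DAYS_PER_YEAR,
                            MAP = NULL, A = NULL, event_starts = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be an integer >= 1")
  k <- as.integer(k)
  if (T_event <= 0) stop("T_event must be > 0")
  if (is.null(MAP) == is.null(A))
    stop("give exactly one of MAP or A")
  if (is.null(A)) {
    if (MAP < 0) stop("MAP must be >= 0")
    A <- MAP / (k * T_event)
  } else {
    if (A < 0) stop("A must be >= 0")
    MAP <- k * A * T_event
  }
  if (k * T_event > 0.5)
    stop("events cannot fit in the first half year: need k * T_event <= 1/2")
  if (is.null(event_starts)) {
    # evenly spaced, snapped down to whole days
    event_starts <- floor((0:(k - 1)) * (DAYS_PER_YEAR / 2) / k) /
      DAYS_PER_YEAR
  }
  event_starts <- sort(as.numeric(event_starts))
  if (length(event_starts) != k)
    stop("event_starts must have length k")
  if (any(event_starts < 0) || event_starts[k] + T_event > 0.5 + 1e-12)
    stop("all events must lie within the first half year")
  if (k > 1 && any(diff(event_starts) < T_event - 1e-12))
    stop("rainfall events overlap")
  structure(list(k = k, T_event = T_event, A = A,
                 A_mm_day = A / DAYS_PER_YEAR, MAP = MAP,
                 event_starts = event_starts),
            class = "rainfall_regime")
}

#' @describeIn rainfall_regime build a regime from (k, T_event, MAP),
#'   trading event number against intensity at fixed annual total.
#' @export
regime_from_MAP <- function(k, T_event = 1 / DAYS_PER_YEAR, MAP = 100) {
  rainfall_regime(k = k, T_event = T_event, MAP = MAP)
}

#' @export
print.rainfall_regime <- function(x, ...) {
  cat(sprintf(
    "rainfall_regime: %d event(s)/yr of %.3g day(s) at %.4g mm/day (MAP %.4g mm)\n",
    x$k, x$T_event * DAYS_PER_YEAR, x$A_mm_day, x$MAP))
  invisible(x)
}

#' Instantaneous precipitation rate of a regime
#'
#' Evaluates the annual square wave at time `t` (years; reduced mod 1):
#' `A` mm/year inside any event window, 0 otherwise.  Vectorized over `t`.
#'
#' @param t time(s) in years.
#' @param regime a [rainfall_regime()].
#' @return Precipitation rate(s) in mm/year.
#' @export
precip_at <- function(t, regime) {
  tt <- t - floor(t)
  out <- numeric(length(tt))
  # 1e-12 y guard keeps samples that land on an event edge up to rounding
  # on the correct side of the half-open window
  for (s in regime$event_starts) {
    out[tt >= s - 1e-12 & tt < s + regime$T_event - 1e-12] <- regime$A
  }
  out
}

#' Hillslope runoff amplification
#'
#' The uppermost terrace receives, on top of direct rain, runoff from the
#' surrounding hillslopes modeled as `alpha(P) * P` with
#' `alpha(P) = alpha1 P^2 / (1 + alpha2 P^2)`.  The cubic small-P behavior
#' (`alpha * P ~ alpha1 P^3`) captures the near-zero yield of weak rain on
#' dry soil; the saturation `alpha -> alpha1/alpha2` the linear yield of
#' intense rain on saturated soil.  In the dynamics `P` is the event
#' intensity expressed in mm/day, for which the default coefficients place
#' the runoff-generation transition near `1/sqrt(alpha2) ~ 14` mm/day.
#'
#' @param P precipitation rate (>= 0), in the intensity units the
#'   coefficients were fitted for (mm/day at the defaults).
#' @param alpha1,alpha2 shape coefficients of the low- and high-intensity
#'   asymptotes.
#' @return Dimensionless amplification factor(s), bounded by `alpha1/alpha2`.
#' @export
alpha_runoff <- function(P, alpha1 = 0.0156, alpha2 = 0.0052) {
  if (any(P < 0)) stop("P must be >= 0")
  alpha1 * P^2 / (1 + alpha2 * P^2)
}

#' Sampled precipitation series
#'
#' A piecewise-constant precipitation signal: `P[i]` mm/year holds on
#' `[times[i], times[i+1])` and the last value holds until `end`.
#'
#' @param times strictly increasing sample times (years), starting at the
#'   beginning of the series.
#' @param P non-negative precipitation rates (mm/year), same length.
#' @param end end of the series horizon (years).
#' @return An object of class `precip_series`.
#' @export
precip_series <- function(times, P, end = NULL) {
  if (length(times) != length(P)) stop("times and P must have equal length")
  if (length(times) == 0L) stop("empty series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(P < 0)) stop("precipitation must be >= 0")
  if (is.null(end)) end <- times[length(times)] + mean(diff(c(0, times)))
  structure(list(times = as.numeric(times), P = as.numeric(P),
                 end = as.numeric(end)),
            class = "precip_series")
}

#' @describeIn precip_series evaluate the series at arbitrary times
#'   (0 before the first sample).
#' @param series a `precip_series`.
#' @param t time(s) in years.
#' @export
series_at <- function(t, series) {
  idx <- findInterval(t, series$times)
  out <- numeric(length(t))
  out[idx > 0] <- series$P[idx[idx > 0]]
  out
}

#' Sample a regime onto an integration grid
#'
#' Realizes the annual square wave of `regime` as a [precip_series()] over
#' `years` years, sampled every `dt` years.  `dt` must not exceed the event
#' duration or events could be skipped entirely.
#'
#' @param regime a [rainfall_regime()].
#' @param years horizon in whole years.
#' @param dt sampling step (years), `dt <= T_event`.
#' @return A `precip_series` spanning `[0, years)`.
#' @export
build_series <- function(regime, years, dt = regime$T_event / 4) {
  if (dt > regime$T_event)
    stop("dt must be <= T_event (events would be skipped)")
  n <- round(years / dt)
  times <- (seq_len(n) - 1) * dt
  precip_series(times, precip_at(times, regime), end = years)
}

#' Drought scenario description
#'
#' A spin-up block at normal rainfall, a drought block at reduced rainfall,
#' and a recovery block back at normal rainfall.
#'
#' @param spinup_years years of normal climate before the drought (used as
#'   the steady-state search horizon by [drought_experiment()]).
#' @param drought_years length of the drought block.
#' @param MAP_normal,MAP_drought mean annual precipitation (mm) in the
#'   normal and drought blocks; `MAP_drought <= MAP_normal`.
#' @param recovery_years years of normal climate after the drought.
#' @return An object of class `drought_scenario`.
#' @export
drought_scenario <- function(spinup_years = 500, drought_years = 60,
                             MAP_normal = 100, MAP_drought = 40,
                             recovery_years = 10) {
  for (v in list(spinup_years, drought_years, recovery_years))
    if (v < 0 || v != round(v)) stop("year counts must be non-negative integers")
  if (MAP_drought > MAP_normal)
    stop("MAP_drought must be <= MAP_normal")
  if (MAP_drought < 0) stop("MAP must be >= 0")
  structure(list(spinup_years = as.integer(spinup_years),
                 drought_years = as.integer(drought_years),
                 MAP_normal = MAP_normal, MAP_drought = MAP_drought,
                 recovery_years = as.integer(recovery_years)),
            class = "drought_scenario")
}

#' Precipitation series for a drought scenario
#'
#' Concatenates spin-up, drought, and recovery blocks, each an annual square
#' wave built via [regime_from_MAP()] with the same `k` and `T_event`; only
#' the per-event intensity changes between blocks.
#'
#' @param scenario a [drought_scenario()].
#' @param k events per year.
#' @param T_event event duration (years).
#' @param dt sampling step (years).
#' @return A `precip_series` covering all three blocks.
#' @export
build_drought_series <- function(scenario, k, T_event = 1 / DAYS_PER_YEAR,
                                 dt = T_event / 4) {
  blocks <- list(
    c(scenario$spinup_years, scenario$MAP_normal),
    c(scenario$drought_years, scenario$MAP_drought),
    c(scenario$recovery_years, scenario$MAP_normal))
  times <- numeric(0); P <- numeric(0); offset <- 0
  for (b in blocks) {
    if (b[1] == 0) next
    s <- build_series(regime_from_MAP(k, T_event, MAP = b[2]), b[1], dt)
    times <- c(times, s$times + offset)
    P <- c(P, s$P)
    offset <- offset + b[1]
  }
  precip_series(times, P, end = offset)
}
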