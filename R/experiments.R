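base_params_for <- function(epsilon, m, n_terraces, params = NULL) {
  if (is.null(params)) {
    model_params(pool = build_pool(m, trait_ranges(epsilon = epsilon)),
                 n_terraces = n_terraces)
  } else {
    # keep the caller's rate constants, swap in the requested pool
    params$pool <- build_pool(m, trait_ranges(
      K_min = params$pool$ranges$K_min, K_max = params$pool$ranges$K_max,
      E_min = params$pool$ranges$E_min, E_max = params$pool$ranges$E_max,
      epsilon = epsilon))
    params
  }
}

#' Downstream terrace-profile experiment
#'
#' Spins the riverbed to its annually periodic steady state under a fixed
#' rainfall regime and returns the asymptotic biomass distribution of every
#' terrace together with community summaries.  At the default parameters
#' total biomass and diversity decline going downstream from the uppermost
#' terrace while the composition centroid shifts to higher `chi`, the
#' changes concentrating in the top few terraces.
#'
#' @param epsilon tradeoff exponent of the pool.
#' @param k rainfall events per year.
#' @param MAP mean annual precipitation, mm.
#' @param m number of functional groups.
#' @param n_terraces number of terraces.
#' @param params optional [model_params()] whose rate constants override the
#'   defaults (its pool is replaced by one with the requested `epsilon`/`m`).
#' @param regime optional [rainfall_regime()] overriding `k`/`MAP`.
#' @param inoculum initial biomass of every group in every terrace, kg/m^2.
#' @param dt,tol,max_years numerics passed to [run_to_steady_state()].
#' @param threshold occupancy cutoff for the diversity metrics.
#' @return A list of class `terrace_profile`: `B` (m x n year-end biomass),
#'   `pool`, `summary` (a [community_summary()]), `convergence`.
#' @export
terrace_profile_experiment <- function(epsilon = 1, k = 6, MAP = 100,
                                       m = 500, n_terraces = 9,
                                       params = NULL, regime = NULL,
                                       inoculum = 0.01,
                                       dt = NULL, tol = 1e-6,
                                       max_years = 500, threshold = 0.01) {
  params <- base_params_for(epsilon, m, n_terraces, params)
  if (is.null(regime)) regime <- regime_from_MAP(k = k, MAP = MAP)
  if (is.null(dt)) dt <- regime$T_event / 4
  init <- riverbed_state(params, B = inoculum)
  ss <- run_to_steady_state(init, regime, params, dt = dt, tol = tol,
                            max_years = max_years)
  structure(list(B = ss$state$B, pool = params$pool, state = ss$state,
                 summary = community_summary(ss$state, params$pool, threshold),
                 convergence = ss[c("converged", "years", "delta")]),
            class = "terrace_profile")
}

#' Drought and recovery experiment
#'
#' Spins the riverbed to steady state at `MAP_normal`, applies
#' `drought_years` of reduced rainfall, resumes the normal climate for
#' `recovery_years`, and reports the riverbed biomass trajectory and the
#' recovery fraction: year-end riverbed biomass at the end of the recovery
#' block as a percentage of the pre-drought steady-state value.
#'
#' @inheritParams terrace_profile_experiment
#' @param scenario a [drought_scenario()]; its `spinup_years` bounds the
#'   steady-state search.
#' @return A list of class `drought_run`: `biomass` (data frame year /
#'   phase / B_total), `recovery_percent`, `pre_drought_B`, `spinup`
#'   (convergence info), `state` (final).
#' @export
drought_experiment <- function(epsilon = 1, scenario = drought_scenario(),
                               k = 6, m = 500, n_terraces = 9, params = NULL,
                               inoculum = 0.01, dt = NULL, tol = 1e-6,
                               threshold = 0.01) {
  params <- base_params_for(epsilon, m, n_terraces, params)
  normal <- regime_from_MAP(k = k, MAP = scenario$MAP_normal)
  dry <- regime_from_MAP(k = k, MAP = scenario$MAP_drought)
  if (is.null(dt)) dt <- normal$T_event / 4
  init <- riverbed_state(params, B = inoculum)
  ss <- run_to_steady_state(init, normal, params, dt = dt, tol = tol,
                            max_years = scenario$spinup_years)
  pre <- total_biomass(ss$state)
  state <- ss$state
  rows <- list(data.frame(year = 0, phase = "spinup", B_total = pre))
  if (scenario$drought_years > 0) {
    run <- simulate(state, dry, params, scenario$drought_years, dt = dt)
    state <- run$state
    rows <- c(rows, list(data.frame(year = seq_len(scenario$drought_years),
                                    phase = "drought",
                                    B_total = run$B_total)))
  }
  if (scenario$recovery_years > 0) {
    run <- simulate(state, normal, params, scenario$recovery_years, dt = dt)
    state <- run$state
    rows <- c(rows, list(data.frame(
      year = scenario$drought_years + seq_len(scenario$recovery_years),
      phase = "recovery", B_total = run$B_total)))
  }
  structure(list(biomass = do.call(rbind, rows),
                 recovery_percent = recovery_fraction(total_biomass(state), pre),
                 pre_drought_B = pre,
                 spinup = ss[c("converged", "years", "delta")],
                 state = state, params = params),
            class = "drought_run")
}

#' Rainfall-regime sweep at fixed annual total
#'
#' For every combination of tradeoff exponent and event count, trades event
#' number against per-event intensity at fixed MAP, runs to steady state,
#' and records riverbed-level summaries.  Failures at individual grid
#' points are recorded (`converged = NA`) and the sweep continues.
#'
#' @inheritParams terrace_profile_experiment
#' @param epsilon_values tradeoff exponents to sweep.
#' @param k_values event counts to sweep.
#' @return A data frame of class `rainfall_sweep` with one row per grid
#'   point: epsilon, k, A_mm_day, B_total, diversity (union-of-supports),
#'   diversity_summed, centroid, converged, years.
#' @export
rainfall_sweep <- function(epsilon_values = c(0.6, 1, 1.6),
                           k_values = c(1, 2, 3, 4, 6, 8, 12, 16, 24, 36, 50),
                           MAP = 100, m = 500, n_terraces = 9, params = NULL,
                           inoculum = 0.01, dt = NULL, tol = 1e-6,
                           max_years = 500, threshold = 0.01) {
  grid <- expand.grid(k = k_values, epsilon = epsilon_values)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    eps <- grid$epsilon[g]; k <- grid$k[g]
    out <- data.frame(epsilon = eps, k = k, A_mm_day = NA_real_,
                      B_total = NA_real_, diversity = NA_real_,
                      diversity_summed = NA_real_, centroid = NA_real_,
                      converged = NA, years = NA_integer_)
    tryCatch({
      p <- base_params_for(eps, m, n_terraces, params)
      regime <- regime_from_MAP(k = k, MAP = MAP)
      step <- if (is.null(dt)) regime$T_event / 4 else dt
      ss <- run_to_steady_state(riverbed_state(p, B = inoculum), regime, p,
                                dt = step, tol = tol, max_years = max_years)
      out$A_mm_day <- regime$A_mm_day
      out$B_total <- total_biomass(ss$state)
      out$diversity <- riverbed_diversity(ss$state, p$pool$chi, threshold)
      out$diversity_summed <- pulse_width(rowSums(ss$state$B), p$pool$chi,
                                          threshold)
      out$centroid <- composition_centroid(rowSums(ss$state$B), p$pool$chi)
      out$converged <- ss$converged
      out$years <- ss$years
      out
    }, error = function(e) {
      warning(sprintf("sweep point epsilon=%g k=%d failed: %s",
                      eps, k, conditionMessage(e)))
      out
    })
  })
  res <- do.call(rbind, rows)
  class(res) <- c("rainfall_sweep", class(res))
  res
}
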