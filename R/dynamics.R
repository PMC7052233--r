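#' Model parameters of the terraced-riverbed system
#'
#' Collects all rate constants of the coupled biomass/soil-water/surface-
#' water equations together with the functional-group pool and the number
#' of terraces.  Defaults are the reference dimensional parameter set used
#' throughout the simulations.
#'
#' @param pool a [build_pool()] object carrying `m`, `K_i`, `E_i`.
#' @param Lambda0 growth rate per unit biomass per unit available water,
#'   m^2/(kg y).
#' @param B_R reference above-ground biomass above which competition for
#'   light is significant, kg/m^2.
#' @param uptake_half_sat soil-water areal density at which water uptake is
#'   half-maximal, kg/m^2 (1 kg/m^2 of water = 1 mm depth); the
#'   saturation coefficient of the uptake factor `W/(1 + aW)` is its
#'   reciprocal, `a = 1/uptake_half_sat`.
#' @param Gamma water-uptake rate, m^2/(kg y), uniform across groups.
#' @param M biomass loss rate in dry soil, 1/y, uniform across groups.
#' @param L soil-water evaporation rate, 1/y.
#' @param I infiltration rate of surface water into the soil, 1/y.
#' @param D runoff rate between adjacent terraces, 1/y.
#' @param alpha1,alpha2 hillslope runoff coefficients, see [alpha_runoff()].
#' @param n_terraces number of terraces (terrace 1 is the lowest,
#'   `n_terraces` the uppermost, which receives the hillslope runoff).
#' @return An object of class `model_params`.
#' @export
model_params <- function(pool = build_pool(500), Lambda0 = 0.3, B_R = 20,
                         uptake_half_sat = 60, Gamma = 1, M = 0.1, L = 2.5,
                         I = 5, D = 0.64, alpha1 = 0.0156, alpha2 = 0.0052,
                         n_terraces = 9) {
  if (!inherits(pool, "trait_pool")) stop("pool must be a trait_pool")
  rates <- c(Lambda0 = Lambda0, B_R = B_R, uptake_half_sat = uptake_half_sat,
             Gamma = Gamma, M = M, L = L, I = I, D = D,
             alpha1 = alpha1, alpha2 = alpha2)
  if (any(rates < 0)) stop("all rate parameters must be >= 0")
  if (B_R <= 0) stop("B_R must be > 0")
  if (uptake_half_sat <= 0) stop("uptake_half_sat must be > 0")
  if (n_terraces < 1 || n_terraces != round(n_terraces))
    stop("n_terraces must be an integer >= 1")
  structure(list(pool = pool, Lambda0 = Lambda0, B_R = B_R,
                 uptake_half_sat = uptake_half_sat, a = 1 / uptake_half_sat,
                 Gamma = Gamma, M = M, L = L, I = I, D = D,
                 alpha1 = alpha1, alpha2 = alpha2,
                 n_terraces = as.integer(n_terraces)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: m = %d groups x n = %d terraces\n",
              x$pool$m, x$n_terraces))
  cat(sprintf("  Lambda0 %g, B_R %g, half-sat %g, Gamma %g, M %g\n",
              x$Lambda0, x$B_R, x$uptake_half_sat, x$Gamma, x$M))
  cat(sprintf("  L %g, I %g, D %g, alpha1 %g, alpha2 %g\n",
              x$L, x$I, x$D, x$alpha1, x$alpha2))
  invisible(x)
}

#' Dynamical state of the riverbed
#'
#' @param params a [model_params()] object (fixes the dimensions).
#' @param B biomass, either a scalar inoculum applied to all groups and
#'   terraces (kg/m^2) or an `m x n` matrix.  The default small uniform
#'   inoculum lets competition, not initialization, select the community.
#' @param W,H soil and surface water per terrace (kg/m^2, = mm of water),
#'   scalar or length-`n` vectors.
#' @param t time in years.
#' @return An object of class `riverbed_state` with fields `B`, `W`, `H`, `t`.
#' @export
riverbed_state <- function(params, B = 0.01, W = 0, H = 0, t = 0) {
  m <- params$pool$m; n <- params$n_terraces
  if (is.matrix(B)) {
    if (nrow(B) != m || ncol(B) != n)
      stop("B must be an m x n matrix matching params")
  } else {
    B <- matrix(B, m, n)
  }
  W <- rep_len(W, n); H <- rep_len(H, n)
  if (any(B < 0) || any(W < 0) || any(H < 0))
    stop("state variables must be >= 0")
  structure(list(B = B, W = W, H = H, t = t), class = "riverbed_state")
}

#' @export
print.riverbed_state <- function(x, ...) {
  cat(sprintf(
    "riverbed_state at t = %.4g y: %d groups x %d terraces, total biomass %.6g kg/m^2\n",
    x$t, nrow(x$B), ncol(x$B), sum(x$B)))
  invisible(x)
}

#' Light-competition growth factor
#'
#' The growth coefficient of group `i` in a terrace with biomass column
#' `B_column` is `Lambda0 * (1 - (B_T - B_i)/(B_T + B_R))` with
#' `B_T = sum(B_column)`: taller neighbors attenuate growth, and a group
#' alone in the terrace grows at the full rate `Lambda0`.
#'
#' @param B_column non-negative biomass of all m groups in one terrace.
#' @param i group index (may be a vector; defaults to all groups).
#' @param params a [model_params()].
#' @return Growth factor(s) Lambda_i, m^2/(kg y).
#' @export
light_factor <- function(B_column, i = seq_along(B_column), params) {
  if (any(B_column < 0)) stop("biomass must be >= 0")
  BT <- sum(B_column)
  params$Lambda0 * (1 - (BT - B_column[i]) / (BT + params$B_R))
}

#' Time derivative of the riverbed state
#'
#' Pure-R reference implementation of the coupled equations: logistic-type
#' biomass growth boosted by root investment (`(1 + E_i B)^2`) and limited
#' by light competition and the saturating water-uptake factor
#' `G = W/(1 + aW)`; soil water gains by infiltration `I H` and loses to
#' evaporation `L W` and uptake; surface water gains by rain `P` and the
#' upslope cascade `D (H[j+1] - H[j])`, the uppermost terrace receiving
#' `(1 + alpha) P` from its hillslopes.  The compiled integrator used by
#' [simulate()] evaluates the identical right-hand side.
#'
#' @param state a [riverbed_state()].
#' @param P_now instantaneous precipitation rate, mm/year.
#' @param params a [model_params()].
#' @return A list with elements `dB` (m x n), `dW`, `dH` (length n).
#' @export
rhs <- function(state, P_now, params) {
  B <- state$B; W <- state$W; H <- state$H
  m <- params$pool$m; n <- params$n_terraces
  if (nrow(B) != m || ncol(B) != n)
    stop("state dimensions do not match the pool/terrace count")
  if (P_now < 0) stop("P_now must be >= 0")
  K <- params$pool$K; E <- params$pool$E
  G <- W / (1 + params$a * W)                       # per-terrace uptake factor
  BT <- colSums(B)
  Lam <- params$Lambda0 *
    (1 - sweep(sweep(-B, 2, BT, "+"), 2, BT + params$B_R, "/"))
  g2 <- (1 + E * B)^2                               # E recycles over columns
  dB <- Lam * sweep(g2 * (1 - B / K) * B, 2, G, "*") - params$M * B
  uptake <- params$Gamma * G * colSums(B * g2)
  dW <- params$I * H - params$L * W - uptake
  alpha <- alpha_runoff(P_now / 365, params$alpha1, params$alpha2)
  dH <- numeric(n)
  if (n > 1) {
    j <- seq_len(n - 1)
    dH[j] <- P_now - params$I * H[j] + params$D * (H[j + 1] - H[j])
  }
  dH[n] <- (1 + alpha) * P_now - params$I * H[n] - params$D * H[n]
  list(dB = dB, dW = dW, dH = dH)
}

# normalize a forcing argument to a function of absolute time t (years)
forcing_fun <- function(forcing) {
  if (inherits(forcing, "rainfall_regime")) {
    function(t) precip_at(t, forcing)
  } else if (inherits(forcing, "precip_series")) {
    function(t) series_at(t, forcing)
  } else if (is.function(forcing)) {
    forcing
  } else stop("forcing must be a rainfall_regime, precip_series, or function")
}

#' One classical Runge-Kutta step
#'
#' Advances the state by `dt` with the classical fourth-order scheme,
#' evaluating the forcing at `t`, `t + dt/2`, `t + dt`.  Negative components
#' arising from truncation error are clamped to zero; the clamped mass is
#' accumulated on the `"clamped"` attribute of the returned state.
#'
#' @param state a [riverbed_state()].
#' @param dt step size in years.
#' @param forcing a [rainfall_regime()], [precip_series()], or function of
#'   time returning mm/year.
#' @param params a [model_params()].
#' @return The advanced `riverbed_state`.
#' @export
rk4_step <- function(state, dt, forcing, params) {
  if (dt <= 0) stop("dt must be > 0")
  Pf <- forcing_fun(forcing)
  t <- state$t
  k1 <- rhs(state, Pf(t), params)
  s2 <- state; Pm <- Pf(t + dt / 2)
  s2$B <- state$B + dt / 2 * k1$dB
  s2$W <- state$W + dt / 2 * k1$dW
  s2$H <- state$H + dt / 2 * k1$dH
  k2 <- rhs(s2, Pm, params)
  s2$B <- state$B + dt / 2 * k2$dB
  s2$W <- state$W + dt / 2 * k2$dW
  s2$H <- state$H + dt / 2 * k2$dH
  k3 <- rhs(s2, Pm, params)
  s2$B <- state$B + dt * k3$dB
  s2$W <- state$W + dt * k3$dW
  s2$H <- state$H + dt * k3$dH
  k4 <- rhs(s2, Pf(t + dt), params)
  out <- state
  out$B <- state$B + dt / 6 * (k1$dB + 2 * k2$dB + 2 * k3$dB + k4$dB)
  out$W <- state$W + dt / 6 * (k1$dW + 2 * k2$dW + 2 * k3$dW + k4$dW)
  out$H <- state$H + dt / 6 * (k1$dH + 2 * k2$dH + 2 * k3$dH + k4$dH)
  out$t <- t + dt
  if (any(!is.finite(out$B)) || any(!is.finite(out$W)) ||
      any(!is.finite(out$H)))
    stop(sprintf("integration failure: non-finite state at t = %g", out$t))
  clamped <- -(sum(pmin(out$B, 0)) + sum(pmin(out$W, 0)) +
               sum(pmin(out$H, 0)))
  out$B[out$B < 0] <- 0
  out$W[out$W < 0] <- 0
  out$H[out$H < 0] <- 0
  attr(out, "clamped") <- clamped
  out
}

default_dt <- function(forcing) {
  if (inherits(forcing, "rainfall_regime")) forcing$T_event / 4
  else 1 / (4 * DAYS_PER_YEAR)
}

forcing_breakpoints <- function(forcing) {
  if (inherits(forcing, "rainfall_regime")) {
    s <- forcing$event_starts
    bp <- sort(unique(c(0, s, s + forcing$T_event)))
    inside <- vapply(bp, function(b)
      any(b >= s - 1e-15 & b < s + forcing$T_event - 1e-15), logical(1))
    list(times = bp, rates = ifelse(inside, forcing$A, 0), periodic = TRUE,
         end = Inf)
  } else if (inherits(forcing, "precip_series")) {
    list(times = forcing$times, rates = forcing$P, periodic = FALSE,
         end = forcing$end)
  } else stop("forcing must be a rainfall_regime or precip_series")
}

#' Integrate the riverbed model over whole years
#'
#' Runs the compiled fourth-order Runge-Kutta integrator for `years` whole
#' years at a fixed step and records year-end quantities.  A year-end state
#' is the state at an integer time, i.e. just before the next year's first
#' rainfall event.
#'
#' @param initial a [riverbed_state()].
#' @param forcing a [rainfall_regime()] (annually periodic) or a
#'   [precip_series()] covering the horizon.
#' @param params a [model_params()].
#' @param years number of whole years to integrate.
#' @param dt requested step (years); rounded so that a year is a whole
#'   number of steps.  Default `T_event/4`, which resolves the rainfall
#'   pulses and the fastest linear rates with a wide stability margin.
#' @param record `"totals"` (default) records year-end riverbed and
#'   per-terrace biomass; `"full"` additionally keeps every year-end biomass
#'   matrix; `"none"` keeps only the final state.
#' @return An object of class `riverbed_run`: list with `state` (final),
#'   `year`, `B_total`, `terrace_B`, `clamped` (clamped mass per year),
#'   and `B_full` (list of matrices, if requested).
#' @export
simulate <- function(initial, forcing, params, years,
                     dt = default_dt(forcing),
                     record = c("totals", "full", "none")) {
  record <- match.arg(record)
  if (years < 0 || years != round(years)) stop("years must be a non-negative integer")
  if (years == 0)
    return(structure(list(state = initial, year = integer(0),
                          B_total = numeric(0),
                          terrace_B = matrix(0, 0, params$n_terraces),
                          clamped = numeric(0), B_full = list()),
                     class = "riverbed_run"))
  bp <- forcing_breakpoints(forcing)
  if (bp$end < initial$t + years)
    stop("forcing does not cover the requested horizon")
  steps_per_year <- max(1L, as.integer(round(1 / dt)))
  par <- list(Lambda0 = params$Lambda0, B_R = params$B_R, a = params$a,
              Gamma = params$Gamma, M = params$M, L = params$L,
              I = params$I, D = params$D, alpha1 = params$alpha1,
              alpha2 = params$alpha2)
  res <- simulate_core(initial$B, initial$W, initial$H, initial$t,
                       as.integer(years), steps_per_year, par,
                       params$pool$K, params$pool$E,
                       bp$times, bp$rates, bp$periodic,
                       switch(record, none = 0L, totals = 1L, full = 2L))
  state <- structure(list(B = res$B, W = res$W, H = res$H, t = res$t),
                     class = "riverbed_state")
  structure(list(state = state, year = seq_len(years) + round(initial$t),
                 B_total = res$B_total, terrace_B = res$terrace_B,
                 clamped = res$clamped, B_full = res$B_full),
            class = "riverbed_run")
}

#' Integrate to an annually periodic steady state
#'
#' Iterates whole years under the periodic regime until the year-end biomass
#' distribution stops changing: convergence is declared when the maximum
#' absolute change of year-end `B` between consecutive years, relative to
#' the largest standing biomass, falls below `tol`.  (A strictly
#' element-wise relative criterion never converges, because losing groups
#' decay exponentially forever at rate `M`; change relative to the standing
#' stock is the meaningful measure of community-level stationarity.)
#'
#' @inheritParams simulate
#' @param regime a [rainfall_regime()].
#' @param tol convergence tolerance on the relative year-end change.
#' @param max_years give up (flagging non-convergence) after this many years.
#' @param verbose print per-year convergence diagnostics.
#' @return A list with `state` (year-end state), `converged` (logical),
#'   `years` (years integrated), `delta` (last relative change), and
#'   `history` (data frame: year, delta, B_total, clamped).
#' @export
run_to_steady_state <- function(initial, regime, params,
                                dt = default_dt(regime), tol = 1e-6,
                                max_years = 500, verbose = FALSE) {
  if (tol <= 0) stop("tol must be > 0")
  state <- initial
  B_prev <- state$B
  hist <- vector("list", max_years)
  delta <- Inf
  yr <- 0L
  while (yr < max_years) {
    run <- simulate(state, regime, params, years = 1, dt = dt,
                    record = "totals")
    state <- run$state
    yr <- yr + 1L
    scale <- max(B_prev, state$B, 1e-300)
    delta <- max(abs(state$B - B_prev)) / scale
    hist[[yr]] <- data.frame(year = yr, delta = delta,
                             B_total = sum(state$B), clamped = run$clamped)
    if (verbose)
      message(sprintf("year %d: delta %.3e, riverbed biomass %.6g",
                      yr, delta, sum(state$B)))
    if (delta < tol) break
    B_prev <- state$B
  }
  list(state = state, converged = delta < tol, years = yr, delta = delta,
       history = do.call(rbind, hist[seq_len(yr)]))
}
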