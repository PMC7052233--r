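#' Total biomass of a state
#'
#' @param state a [riverbed_state()].
#' @param terrace optional terrace index (1 = lowest); by default the sum
#'   over the whole riverbed.
#' @return Biomass in kg/m^2 summed over groups (and terraces).
#' @export
total_biomass <- function(state, terrace = NULL) {
  if (is.null(terrace)) sum(state$B) else sum(state$B[, terrace])
}

#' Functional diversity as trait-axis pulse width
#'
#' The asymptotic biomass distribution over the tradeoff axis is a pulse;
#' its width measures how many functional groups persist.  Width is
#' operationalized as thresholded support: the number of grid points whose
#' biomass exceeds `threshold` times the distribution's maximum, times the
#' grid spacing, capped at 1 (the length of the trait axis).  The measure is
#' invariant under uniform rescaling of the distribution.  An all-zero
#' distribution has width 0.
#'
#' @param distribution non-negative biomass over the `chi` grid.
#' @param chi the uniform trait grid the distribution lives on.
#' @param threshold relative occupancy cutoff in (0, 1); default 0.01.
#' @return Dimensionless width in `[0, 1]`.
#' @seealso [moment_width()] for a moment-based cross-check.
#' @export
pulse_width <- function(distribution, chi, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (any(distribution < 0)) stop("distribution must be >= 0")
  if (length(distribution) != length(chi))
    stop("distribution and chi must have equal length")
  mx <- max(distribution)
  if (mx == 0) return(0)
  spacing <- 1 / (length(chi) - 1)
  min(sum(distribution > threshold * mx) * spacing, 1)
}

#' Moment-based pulse width
#'
#' Four biomass-weighted standard deviations of `chi` — for a Gaussian
#' pulse, roughly the width at ~14% of peak height.  Provided as a
#' threshold-free cross-check of [pulse_width()].
#'
#' @inheritParams pulse_width
#' @return Dimensionless width (0 for an all-zero distribution).
#' @export
moment_width <- function(distribution, chi) {
  tot <- sum(distribution)
  if (tot == 0) return(0)
  mu <- sum(chi * distribution) / tot
  4 * sqrt(sum((chi - mu)^2 * distribution) / tot)
}

occupied_sets <- function(B, threshold) {
  apply(B, 2, function(col) {
    mx <- max(col)
    if (mx == 0) rep(FALSE, length(col)) else col > threshold * mx
  })
}

#' Per-terrace functional diversity
#'
#' @param state a [riverbed_state()].
#' @param chi trait grid of the pool.
#' @inheritParams pulse_width
#' @return Vector of pulse widths, one per terrace.
#' @export
terrace_diversity <- function(state, chi, threshold = 0.01) {
  apply(state$B, 2, pulse_width, chi = chi, threshold = threshold)
}

#' Riverbed-level functional diversity
#'
#' The riverbed-wide width counts a `chi` grid point as occupied if it is
#' occupied (relative to that terrace's own peak) in *any* terrace, so that
#' shoot-investing groups in the water-rich upper terraces and
#' root-investing groups in the lower terraces both contribute.  It is
#' therefore at least as large as every single-terrace width.  (The width
#' of the terrace-summed distribution, in which a massive terrace can mask
#' the others, is available via `pulse_width(rowSums(state$B), chi)`.)
#'
#' @inheritParams terrace_diversity
#' @return Dimensionless width in `[0, 1]`.
#' @export
riverbed_diversity <- function(state, chi, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  occ <- occupied_sets(state$B, threshold)
  spacing <- 1 / (length(chi) - 1)
  min(sum(rowSums(occ) > 0) * spacing, 1)
}

#' Biomass-weighted composition centroid
#'
#' The pulse position: mean trait coordinate weighted by biomass.  A shift
#' toward higher `chi` marks a compositional change toward below-ground
#' investment.
#'
#' @inheritParams pulse_width
#' @return The centroid in `[0, 1]`, or `NaN` for an all-zero distribution.
#' @export
composition_centroid <- function(distribution, chi) {
  if (any(distribution < 0)) stop("distribution must be >= 0")
  tot <- sum(distribution)
  if (tot == 0) return(NaN)
  sum(chi * distribution) / tot
}

#' Post-drought recovery fraction
#'
#' @param biomass_after,biomass_before riverbed total biomass at the end of
#'   the recovery block and at the pre-drought steady state (kg/m^2).
#' @return Recovery in percent (`100 * after / before`); `NaN` with a
#'   warning when the reference biomass is zero.
#' @export
recovery_fraction <- function(biomass_after, biomass_before) {
  if (biomass_before <= 0) {
    warning("pre-drought biomass is zero: recovery fraction undefined")
    return(NaN)
  }
  100 * biomass_after / biomass_before
}

#' Community-level summary of a riverbed state
#'
#' @param state a [riverbed_state()].
#' @param pool the [build_pool()] the state was simulated with.
#' @inheritParams pulse_width
#' @return A list of class `community_summary` with `per_terrace` (data
#'   frame: terrace, B_total, diversity, centroid, W, H), `riverbed_B_total`,
#'   `riverbed_diversity`, `riverbed_centroid`, and the `threshold` used.
#' @export
community_summary <- function(state, pool, threshold = 0.01) {
  n <- ncol(state$B)
  per <- data.frame(
    terrace = seq_len(n),
    B_total = colSums(state$B),
    diversity = terrace_diversity(state, pool$chi, threshold),
    centroid = apply(state$B, 2, composition_centroid, chi = pool$chi),
    W = state$W, H = state$H)
  structure(list(
    per_terrace = per,
    riverbed_B_total = sum(state$B),
    riverbed_diversity = riverbed_diversity(state, pool$chi, threshold),
    riverbed_centroid = composition_centroid(rowSums(state$B), pool$chi),
    threshold = threshold), class = "community_summary")
}

#' @export
print.community_summary <- function(x, ...) {
  cat(sprintf("riverbed: biomass %.6g kg/m^2, diversity %.4g, centroid %.4g\n",
              x$riverbed_B_total, x$riverbed_diversity, x$riverbed_centroid))
  print(x$per_terrace, row.names = FALSE)
  invisible(x)
}
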