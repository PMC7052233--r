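#' Trait ranges of a tradeoff species pool
#'
#' The pool of functional groups is parameterized by a single tradeoff
#' coordinate `chi` in `[0, 1]`: `chi = 0` is the pure shoot strategy
#' (`K = K_max`, `E = E_min`), `chi = 1` the pure root strategy
#' (`K = K_min`, `E = E_max`).  The exponent `epsilon` sets the shape of the
#' tradeoff curve in the (E, K) trait plane: `epsilon < 1` convex (a few
#' intermediate groups lie close to the unconstrained "ideal" corner),
#' `epsilon = 1` linear, `epsilon > 1` concave (many groups are roughly
#' equidistant from it).
#'
#' @param K_min,K_max range of the maximal standing (shoot) biomass, kg/m^2.
#' @param E_min,E_max range of the root-to-shoot ratio, m^2/kg.
#' @param epsilon positive tradeoff exponent (dimensionless).
#' @return An object of class `trait_ranges`.
#' @examples
#' r <- trait_ranges()            # defaults of the reference parameter set
#' trait_K(0.5, r)                # 1.8 kg/m^2 for the linear tradeoff
#' @export
trait_ranges <- function(K_min = 0.1, K_max = 3.5,
                         E_min = 0.5, E_max = 3.5, epsilon = 1) {
  for (v in list(K_min, K_max, E_min, E_max, epsilon))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("trait ranges must be finite numeric scalars")
  if (K_min >= K_max) stop("invalid trait ranges: K_min must be < K_max")
  if (E_min >= E_max) stop("invalid trait ranges: E_min must be < E_max")
  if (epsilon <= 0) stop("invalid trait ranges: epsilon must be > 0")
  structure(list(K_min = K_min, K_max = K_max,
                 E_min = E_min, E_max = E_max, epsilon = epsilon),
            class = "trait_ranges")
}

check_chi <- function(chi) {
  if (!is.numeric(chi) || anyNA(chi) || any(chi < 0 | chi > 1))
    stop("chi must lie in [0, 1]")
  chi
}

#' Trait values along the tradeoff axis
#'
#' `trait_K()` returns the maximal shoot biomass
#' `K(chi) = K_min + (1 - chi)^epsilon (K_max - K_min)` and `trait_E()` the
#' root-to-shoot ratio `E(chi) = E_min + chi^epsilon (E_max - E_min)`.
#' Both are vectorized over `chi`.
#'
#' @param chi tradeoff coordinate(s) in `[0, 1]`.
#' @param ranges a [trait_ranges()] object.
#' @return Numeric vector of trait values (kg/m^2 for `K`, m^2/kg for `E`).
#' @export
trait_K <- function(chi, ranges) {
  check_chi(chi)
  ranges$K_min + (1 - chi)^ranges$epsilon * (ranges$K_max - ranges$K_min)
}

#' @rdname trait_K
#' @export
trait_E <- function(chi, ranges) {
  check_chi(chi)
  ranges$E_min + chi^ranges$epsilon * (ranges$E_max - ranges$E_min)
}

#' Build the pool of functional groups
#'
#' Places `m` functional groups at uniformly spaced `chi` values on
#' `[0, 1]`, endpoints included, so the two extreme strategies are members
#' of every pool.
#'
#' @param m number of functional groups (>= 2).
#' @param ranges a [trait_ranges()] object.
#' @return An object of class `trait_pool`: a list with elements `chi`, `K`,
#'   `E` (length-`m` vectors), `m`, and `ranges`.
#' @export
build_pool <- function(m, ranges = trait_ranges()) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != round(m))
    stop("m must be an integer >= 2")
  m <- as.integer(m)
  chi <- seq(0, 1, length.out = m)
  structure(list(chi = chi, K = trait_K(chi, ranges),
                 E = trait_E(chi, ranges), m = m, ranges = ranges),
            class = "trait_pool")
}

#' @export
print.trait_pool <- function(x, ...) {
  r <- x$ranges
  cat(sprintf(paste0("trait_pool: %d groups, epsilon = %g, ",
                     "K in [%g, %g] kg/m^2, E in [%g, %g] m^2/kg\n"),
              x$m, r$epsilon, r$K_min, r$K_max, r$E_min, r$E_max))
  invisible(x)
}

#' Distance to the ideal functional group
#'
#' Heuristic distance in the (E, K) trait plane between the group at `chi`
#' and the unconstrained "ideal" corner (`K_max`, `E_max`) that no real
#' group can occupy.  The two axes carry different units (kg/m^2 and
#' m^2/kg); the distance is computed on the numeric values as printed and is
#' a comparative index of competitive potential, not a physical quantity.
#'
#' @inheritParams trait_K
#' @return Numeric vector of trait-plane distances.
#' @export
distance_to_ideal <- function(chi, ranges) {
  check_chi(chi)
  sqrt((trait_K(chi, ranges) - ranges$K_max)^2 +
       (trait_E(chi, ranges) - ranges$E_max)^2)
}

#' Most competitive coordinate of a linear tradeoff
#'
#' For the linear tradeoff (`epsilon = 1`) the trait-plane distance to the
#' ideal group is minimized at the closed-form coordinate
#' `chi_mid = dE^2 / (dE^2 + dK^2)` with `dK = K_max - K_min`,
#' `dE = E_max - E_min`.  For `epsilon != 1` there is no closed form; use
#' [chi_most_competitive()] instead.
#'
#' @param ranges a [trait_ranges()] object.
#' @return The coordinate `chi_mid` in `[0, 1]`.
#' @export
chi_mid <- function(ranges) {
  dK <- ranges$K_max - ranges$K_min
  dE <- ranges$E_max - ranges$E_min
  if (dK^2 + dE^2 == 0) stop("degenerate trait ranges: both spans are zero")
  dE^2 / (dE^2 + dK^2)
}

#' @describeIn chi_mid numeric minimizer of [distance_to_ideal()] over a fine
#'   uniform `chi` grid, valid for any `epsilon`.
#' @param grid_points number of grid points used for the search.
#' @export
chi_most_competitive <- function(ranges, grid_points = 10001L) {
  chi <- seq(0, 1, length.out = grid_points)
  chi[which.min(distance_to_ideal(chi, ranges))]
}

#' Read and write a pool as a three-column table
#'
#' Plain-text serialization (columns `chi`, `K`, `E`, tab-separated, header
#' row) for inspection and test fixtures.
#'
#' @param pool a `trait_pool`.
#' @param path file path.
#' @return `read_pool()` returns a data frame with columns `chi`, `K`, `E`.
#' @export
write_pool <- function(pool, path) {
  df <- data.frame(chi = pool$chi, K = pool$K, E = pool$E)
  write.table(format(df, digits = 12, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!identical(names(df), c("chi", "K", "E")))
    stop("pool file must have columns chi, K, E")
  df
}
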