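need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the plotting helpers need the ggplot2 package")
}

#' Plot asymptotic biomass pulses per terrace
#'
#' Renders the year-end biomass distributions B(chi) of the requested
#' terraces from a [terrace_profile_experiment()] result.
#'
#' @param profile a `terrace_profile`.
#' @param terraces terrace indices to draw (default: the top three).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profile, terraces = NULL) {
  need_ggplot()
  n <- ncol(profile$B)
  if (is.null(terraces)) terraces <- seq(max(1, n - 2), n)
  df <- do.call(rbind, lapply(terraces, function(j)
    data.frame(chi = profile$pool$chi, B = profile$B[, j],
               terrace = factor(j))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chi, y = .data$B,
                                   colour = .data$terrace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(chi), y = expression(B ~ (kg/m^2)),
                  colour = "terrace j")
}

#' Plot riverbed biomass through a drought-recovery run
#'
#' @param drought a [drought_experiment()] result.
#' @return A ggplot object.
#' @export
plot_drought <- function(drought) {
  need_ggplot()
  ggplot2::ggplot(drought$biomass,
                  ggplot2::aes(x = .data$year, y = .data$B_total,
                               colour = .data$phase)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "year", y = expression(B[total] ~ (kg/m^2)))
}

#' Plot rainfall-regime sweep summaries
#'
#' Riverbed functional diversity and total biomass against the number of
#' annual rainfall events, one curve per tradeoff exponent.
#'
#' @param sweep a [rainfall_sweep()] result.
#' @param what `"diversity"` or `"B_total"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, what = c("diversity", "B_total")) {
  need_ggplot()
  what <- match.arg(what)
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$k, y = .data[[what]],
                               colour = factor(.data$epsilon))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "rainfall events per year", y = what,
                  colour = expression(epsilon))
}
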