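# Relative-probability-of-selection curves.

#' Relative probability of selection along one covariate
#'
#' Builds a hypothetical 4-alternative choice set in which the focal
#' alternative sweeps the covariate over its observed range while the other
#' three alternatives sit at the covariate means (standardized scale 0), all
#' other covariates held at their means everywhere (so they cancel within
#' the set). For each posterior draw of the season's population mean b, the
#' relative probability at standardized value z is
#' exp(b z) / (exp(b z) + 3). Reported per grid point: the posterior mean
#' curve, the equal-tailed 85% credible band, and companion curves evaluated
#' at the 7.5% and 92.5% posterior quantiles of the focal coefficient. At
#' the covariate mean (z = 0) every draw gives exactly 0.25.
#'
#' Uncertainty propagates the population-mean draws only: these are
#' population-level selection curves, not covey-specific predictions.
#'
#' @param fit A \code{dcm_fit}.
#' @param covariate A model covariate name.
#' @param season \code{"fall"} or \code{"winter"}.
#' @param grid_size Number of grid points over the observed range.
#' @param level Credible level for the band (default 0.85).
#' @return Object of class \code{selection_curve}: a data frame with the
#'   covariate value in original units (\code{value}), its standardized
#'   value (\code{z}), \code{mean}, \code{lower}, \code{upper},
#'   \code{at_q075}, \code{at_q925}; plus attributes for plotting.
#' @export
relative_probability_curve <- function(fit, covariate,
                                       season = c("fall", "winter"),
                                       grid_size = 100, level = 0.85) {
  stopifnot(inherits(fit, "dcm_fit"))
  season <- match.arg(season)
  if (!covariate %in% fit$spec$terms)
    stop("covariate '", covariate, "' is not in the fitted model")
  b <- pooled_draws(fit)[, sprintf("mu[%s,%s]", covariate, season)]
  rng <- fit$raw_range[[covariate]]
  value <- seq(rng[1L], rng[2L], length.out = grid_size)
  # the covariate mean is always on the grid (curves pass through 0.25 there)
  cmean <- fit$std_params$mean[[covariate]]
  if (cmean >= rng[1L] && cmean <= rng[2L])
    value <- sort(unique(c(value, cmean)))
  z <- (value - cmean) / fit$std_params$sd[[covariate]]
  alpha <- (1 - level) / 2
  P <- 1 / (1 + 3 * exp(-outer(z, b)))       # grid x draws
  qb <- stats::quantile(b, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- data.frame(
    value = value, z = z, mean = rowMeans(P),
    lower = apply(P, 1L, stats::quantile, probs = alpha, names = FALSE),
    upper = apply(P, 1L, stats::quantile, probs = 1 - alpha, names = FALSE),
    at_q075 = 1 / (1 + 3 * exp(-z * qb[1L])),
    at_q925 = 1 / (1 + 3 * exp(-z * qb[2L])))
  structure(out, class = c("selection_curve", "data.frame"),
            covariate = covariate, season = season, level = level)
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("selection_curve: %s (%s), %d grid points, %.0f%% CRI band\n",
              attr(x, "covariate"), attr(x, "season"), nrow(x),
              100 * attr(x, "level")))
  print.data.frame(utils::head(as.data.frame(x), 3L), digits = 4)
  cat("  ...\n")
  invisible(x)
}

#' Plot a relative-probability-of-selection curve
#'
#' Posterior-mean curve with shaded credible band and dashed companion
#' curves at the 7.5% and 92.5% posterior values of the focal coefficient.
#'
#' @param x A \code{selection_curve}.
#' @param ... Passed to \code{plot}.
#' @export
plot.selection_curve <- function(x, ...) {
  cov <- attr(x, "covariate"); season <- attr(x, "season")
  graphics::plot(x$value, x$mean, type = "n", ylim = c(0, 1),
                 xlab = cov, ylab = "Relative probability of selection",
                 main = sprintf("%s (%s)", cov, season), ...)
  graphics::polygon(c(x$value, rev(x$value)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$value, x$mean, lwd = 2)
  graphics::lines(x$value, x$at_q075, lty = 2)
  graphics::lines(x$value, x$at_q925, lty = 2)
  graphics::abline(h = 0.25, col = "grey60", lty = 3)
  invisible(x)
}
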