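# Synthetic choice-set generator with full truth records.
#
# The generator reproduces the statistical structure the estimator assumes:
# season-specific Normal population distributions of covariate effects,
# covey-level coefficients drawn from them, bounded covariate marginals
# emulating the field study's observed ranges, and choices sampled from the
# conditional-logit probabilities on standardized covariates.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the fall/winter bobwhite study design: 67 coveys, 650
#' choice sets with roughly a 40/60 fall/winter split, covariate marginals
#' calibrated to the observed minima/means/maxima of the field covariates,
#' and truth population means seeded from the study's reported posterior
#' means for the top model (GS, VO, SC, NG, TD, WE by season), e.g. GS fall
#' -3.77, VO winter 4.59, SC winter 3.35, TD winter -3.28. The population sd
#' defaults to 0.5 for every covariate-season, a modest covey-level
#' heterogeneity.
#'
#' @param n_coveys Number of coveys (default 67).
#' @param n_sets Total number of choice sets (default 650).
#' @param fall_fraction Fraction of sets in fall (November); default 0.4.
#' @param covariates Covariates entering the utility (default the top model's
#'   six terms).
#' @param mu Truth population means: matrix K x 2 (columns fall, winter),
#'   rows named by \code{covariates}.
#' @param sigma Truth population sds, same shape as \code{mu}; all >= 0.
#' @param marginals Named list of covariate marginal specifications; see
#'   Details. Covariates not listed use built-in defaults.
#' @param within_set_cor Gaussian-copula correlation of a covariate between
#'   alternatives of the same set, in [0, 1). The default 0.8 reflects the
#'   spatial autocorrelation of a used-available design in which the
#'   alternatives of a set lie 50-400 m apart and landscape covariates are
#'   computed over overlapping 50-m buffers; most covariate variance is then
#'   between choice sets rather than within them. Set to 0 for independent
#'   alternatives.
#' @param seed Integer RNG seed.
#' @details Marginal families (each spec is \code{list(family = ..., ...)}):
#'   \code{"tnorm"} (mean, sd, lower, upper; Normal truncated by inverse-CDF),
#'   \code{"nbinom"} (mu, size, upper; counts, capped), \code{"beta"}
#'   (shape1, shape2; proportions), \code{"texp"} (rate, upper; truncated
#'   exponential). Defaults approximate the pooled available-location
#'   distributions of the field study (Table-1-like ranges; SC within
#'   [0, 1000], TD within [0, 310] m, WE within [0, 2100] m/ha).
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_coveys = 67, n_sets = 650, fall_fraction = 0.4,
                             covariates = c("GS", "VO", "SC", "NG", "TD", "WE"),
                             mu = NULL, sigma = NULL, marginals = list(),
                             within_set_cor = 0.8, seed = 1L) {
  if (n_coveys < 1) stop("n_coveys must be >= 1")
  if (n_sets < n_coveys) stop("n_sets must be >= n_coveys")
  if (within_set_cor < 0 || within_set_cor >= 1)
    stop("within_set_cor must be in [0, 1)")
  K <- length(covariates)
  if (is.null(mu)) {
    # reported posterior means of the study's top model, by season
    tab <- list(GS = c(-3.77, -0.25), VO = c(2.48, 4.59), SC = c(2.67, 3.35),
                NG = c(0.21, -0.29), TD = c(-0.92, -3.28), WE = c(1.37, 0.87))
    mu <- t(vapply(covariates, function(k)
      if (k %in% names(tab)) tab[[k]] else c(0, 0), numeric(2L)))
    colnames(mu) <- c("fall", "winter")
  }
  mu <- matrix(mu, K, 2, dimnames = list(covariates, c("fall", "winter")))
  if (is.null(sigma)) sigma <- matrix(0.5, K, 2)
  sigma <- matrix(sigma, K, 2, dimnames = dimnames(mu))
  if (any(sigma < 0)) stop("sigma must be >= 0")

  defaults <- list(
    FB = list(family = "tnorm", mean = 8, sd = 12, lower = 0, upper = 100),
    GS = list(family = "tnorm", mean = 33, sd = 25, lower = 0, upper = 100),
    BR = list(family = "tnorm", mean = 10, sd = 12, lower = 0, upper = 100),
    VO = list(family = "tnorm", mean = 30, sd = 25, lower = 0, upper = 100),
    SC = list(family = "nbinom", mu = 22, size = 0.35, upper = 1000),
    NG = list(family = "beta", shape1 = 0.8, shape2 = 0.8),
    PG = list(family = "beta", shape1 = 0.8, shape2 = 0.8),
    TD = list(family = "texp", rate = 1 / 65, upper = 310),
    WE = list(family = "tnorm", mean = 350, sd = 300, lower = 0, upper = 2100))
  marg <- utils::modifyList(defaults, marginals)

  structure(list(n_coveys = as.integer(n_coveys), n_sets = as.integer(n_sets),
                 fall_fraction = fall_fraction, covariates = covariates,
                 mu = mu, sigma = sigma, marginals = marg,
                 within_set_cor = within_set_cor, seed = as.integer(seed)),
            class = "generator_config")
}

# quantile function for a marginal spec, applied to uniforms
marginal_quantile <- function(spec, u) {
  switch(spec$family,
    tnorm = {
      plo <- stats::pnorm(spec$lower, spec$mean, spec$sd)
      phi <- stats::pnorm(spec$upper, spec$mean, spec$sd)
      stats::qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
    },
    nbinom = pmin(stats::qnbinom(u, mu = spec$mu, size = spec$size),
                  spec$upper),
    beta = stats::qbeta(u, spec$shape1, spec$shape2),
    texp = {
      pmax <- 1 - exp(-spec$rate * spec$upper)
      -log(1 - u * pmax) / spec$rate
    },
    stop("unknown marginal family: ", spec$family))
}

# closed support bounds implied by a marginal spec
marginal_range <- function(spec) {
  switch(spec$family,
    tnorm = c(spec$lower, spec$upper),
    nbinom = c(0, spec$upper),
    beta = c(0, 1),
    texp = c(0, spec$upper))
}

#' Draw covey-level coefficients from the population distributions
#'
#' Independent draws beta[c, k, s] ~ Normal(mu[k, s], sigma[k, s]^2) for each
#' covey c, covariate k and season s. With sigma = 0 every covey's
#' coefficient equals the population mean exactly.
#'
#' @param config A \code{\link{generator_config}}.
#' @return Numeric array \code{n_coveys x K x 2} with dimnames.
#' @export
draw_covey_coefficients <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (any(config$sigma < 0)) stop("sigma must be >= 0")
  K <- length(config$covariates)
  beta <- array(NA_real_, c(config$n_coveys, K, 2),
                dimnames = list(paste0("covey_", seq_len(config$n_coveys)),
                                config$covariates, c("fall", "winter")))
  for (k in seq_len(K)) for (s in 1:2)
    beta[, k, s] <- stats::rnorm(config$n_coveys, config$mu[k, s],
                                 config$sigma[k, s])
  beta
}

#' Simulate choice sets (covariates only, no choices)
#'
#' Draws 4 alternatives per set with covariates from the configured bounded
#' marginals, assigns sets to coveys (balanced) and to seasons by
#' \code{fall_fraction}, and attaches plausible November / December-January
#' dates. Within-set correlation, when requested, is injected through a
#' Gaussian copula with a set-level factor.
#'
#' @param config A \code{\link{generator_config}}.
#' @return Long data frame (4 rows per set) without a \code{used} column.
#' @export
simulate_choice_sets <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_sets
  covey <- rep_len(seq_len(config$n_coveys), n)
  n_fall <- round(config$fall_fraction * n)
  season <- as.integer(seq_len(n) > n_fall)   # per covey round-robin -> mixed
  fall_days <- seq(as.Date("2018-11-01"), as.Date("2018-11-30"), by = "day")
  winter_days <- seq(as.Date("2018-12-01"), as.Date("2019-01-31"), by = "day")
  date <- as.Date(ifelse(season == 0L,
                         as.character(sample(fall_days, n, replace = TRUE)),
                         as.character(sample(winter_days, n, replace = TRUE))))
  rows <- data.frame(
    set_id = rep(sprintf("set_%04d", seq_len(n)), each = 4L),
    covey_id = rep(sprintf("covey_%d", covey), each = 4L),
    date = rep(date, each = 4L),
    season = rep(season, each = 4L))
  rho <- config$within_set_cor
  for (k in covariate_names()) {
    z_alt <- stats::rnorm(4L * n)
    if (rho > 0) {
      z_set <- rep(stats::rnorm(n), each = 4L)
      z_alt <- sqrt(rho) * z_set + sqrt(1 - rho) * z_alt
    }
    rows[[k]] <- marginal_quantile(config$marginals[[k]], stats::pnorm(z_alt))
  }
  rows$SC <- round(rows$SC)
  rows
}

#' Simulate choices from the conditional-logit model
#'
#' Standardizes the covariates over the pooled alternatives, computes each
#' alternative's utility from its covey-season coefficients, and draws the
#' used alternative from the softmax of utilities within each set. Every
#' sampled latent quantity is returned in the truth record.
#'
#' @param sets Output of \code{\link{simulate_choice_sets}}.
#' @param beta Coefficient array from \code{\link{draw_covey_coefficients}}.
#' @param config The \code{\link{generator_config}} used for both.
#' @return List: \code{data} (a validated \code{choice_data} with used
#'   flags, on the original covariate scale) and \code{truth} (class
#'   \code{truth_record}: mu, sigma, beta, standardization params, chosen
#'   slot per set, utilities, and the config).
#' @export
simulate_choices <- function(sets, beta, config) {
  stopifnot(inherits(config, "generator_config"))
  covs <- config$covariates
  n <- config$n_sets
  # standardize on the pooled simulated alternatives (the model's scale)
  tmp <- sets
  tmp$used <- rep(c(TRUE, FALSE, FALSE, FALSE), n)  # placeholder for assembly
  cd <- assemble_choice_sets(tmp)
  std <- standardize_covariates(cd)
  covey_idx <- as.integer(sub("covey_", "", std$data$covey_id))
  if (any(covey_idx > dim(beta)[1L]))
    stop("coefficient array does not cover every covey in the data")
  Z <- as.matrix(as.data.frame(std$data)[, covs, drop = FALSE])
  bmat <- matrix(NA_real_, nrow(Z), length(covs))
  for (j in seq_along(covs))
    bmat[, j] <- beta[cbind(covey_idx, match(covs[j], dimnames(beta)[[2L]]),
                            std$data$season + 1L)]
  util <- rowSums(Z * bmat)
  um <- matrix(util, nrow = 4L)                     # 4 x n_sets
  um <- sweep(um, 2L, apply(um, 2L, max))
  p <- sweep(exp(um), 2L, colSums(exp(um)), "/")
  chosen <- apply(p, 2L, function(pr) sample.int(4L, 1L, prob = pr))

  # write the used flags back on the *original-scale* rows (cd row order:
  # 4 consecutive rows per set, sets sorted by set_id)
  raw <- as.data.frame(cd)
  raw$used <- FALSE
  raw$used[(seq_len(n) - 1L) * 4L + chosen] <- TRUE
  data <- assemble_choice_sets(raw[, c("set_id", "covey_id", "date", "season",
                                       "used", covariate_names())])
  truth <- structure(
    list(mu = config$mu, sigma = config$sigma, beta = beta,
         std_params = std$params, chosen = chosen,
         utilities = t(um),          # n_sets x 4, max-shifted
         probabilities = t(p), set_id = unique(raw$set_id),
         seed = config$seed, config = config),
    class = "truth_record")
  list(data = data, truth = truth)
}

#' Simulate a complete dataset with known truth
#'
#' Convenience wrapper: seeds the RNG, draws covey coefficients, simulates
#' choice sets and choices, and returns the validated data plus truth record.
#'
#' @param config A \code{\link{generator_config}}.
#' @return As \code{\link{simulate_choices}}.
#' @examples
#' sim <- simulate_choice_data(generator_config(n_coveys = 5, n_sets = 20))
#' sim$data
#' @export
simulate_choice_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  beta <- draw_covey_coefficients(config)
  sets <- simulate_choice_sets(config)
  simulate_choices(sets, beta, config)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("truth_record:", nrow(x$beta), "coveys,", length(x$chosen),
      "choice sets,", length(x$config$covariates), "covariates\n")
  cat("  population means (fall/winter):\n")
  print(round(x$mu, 3))
  invisible(x)
}
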