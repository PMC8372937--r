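# Conditional multinomial-logit discrete-choice model with covey-level
# random coefficients and season-specific population distributions.
#
# Utility of alternative j in choice set i of covey c, season s:
#   U_ij = sum_k beta[k, c, s] * z_ijk          (z = standardized covariates)
# Choice probability: softmax of U over the 4 alternatives of the set.
# Hierarchy: beta[k, c, s] ~ Normal(mu[k, s], sigma[k, s]^2); vague Normal
# prior on mu (sd 10, i.e. precision 0.01) and half-Normal prior on sigma.

#' Model specification
#'
#' Defines which covariates enter the utility, whether covey-level random
#' coefficients are used, and optional quadratic terms. Quadratic terms are
#' squares of the standardized covariate, named \code{"<cov>^2"}; they are
#' off by default (at the field study's scale such models typically fail to
#' converge). The interaction \code{"NGxPG"} requires both \code{"NG"} and
#' \code{"PG"}. The empty specification (no covariates) is the null model:
#' every alternative has utility 0.
#'
#' @param covariates Character vector from
#'   \code{c(covariate_names(), "NGxPG")}; may be empty for the null model.
#' @param random_coveys Logical; covey-level random coefficients (default
#'   TRUE). With FALSE the population mean is the single coefficient shared
#'   by all coveys (non-hierarchical).
#' @param quadratic Covariates whose squared (standardized) term is added.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(covariates, random_coveys = TRUE,
                       quadratic = character()) {
  valid <- c(covariate_names(), "NGxPG")
  bad <- setdiff(covariates, valid)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  if ("NGxPG" %in% covariates && !all(c("NG", "PG") %in% covariates))
    stop("NGxPG requires NG and PG in the model")
  if (length(setdiff(quadratic, covariates)))
    stop("quadratic terms must be among the model covariates")
  terms <- c(covariates, if (length(quadratic)) paste0(quadratic, "^2"))
  if (anyDuplicated(terms)) stop("duplicated covariates")
  structure(list(covariates = covariates, quadratic = quadratic,
                 terms = terms, random_coveys = isTRUE(random_coveys)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(null model)",
      "\n  covey random coefficients:", x$random_coveys,
      "| season-specific population distributions\n")
  invisible(x)
}

#' MCMC configuration
#'
#' Defaults follow the study's sampler settings: 4 chains of 100,000
#' iterations including a 10,000-iteration burn-in, thinned by 50 (1,800
#' retained draws per chain), a vague Normal(0, sd 10) prior on each
#' population mean (precision 0.01), and a half-Normal(sd 5) prior on each
#' population sd.
#'
#' @param n_chains Number of chains (default 4).
#' @param n_iterations Total iterations per chain, including burn-in.
#' @param burn_in Iterations discarded at the start of each chain.
#' @param thin Keep every \code{thin}-th post-burn-in iteration.
#' @param prior_mu_sd Prior sd of each population mean (default 10).
#' @param prior_sigma_sd Scale of the half-Normal prior on each population
#'   sd (default 5).
#' @param seed Integer RNG seed.
#' @return An object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 100000,
                        burn_in = 10000, thin = 50, prior_mu_sd = 10,
                        prior_sigma_sd = 5, seed = 1L) {
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (n_iterations <= burn_in) stop("n_iterations must exceed burn_in")
  if (thin < 1) stop("thin must be >= 1")
  if (prior_mu_sd <= 0 || prior_sigma_sd <= 0) stop("priors must be proper")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_mu_sd = prior_mu_sd, prior_sigma_sd = prior_sigma_sd,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Internal: design arrays for the sampler and WAIC.
# Returns Z (4 x n_sets x K), chosen slot per set, per-set covey/season,
# group table (covey x season combinations present) and per-set group index.
dcm_design <- function(data, spec) {
  stopifnot(inherits(data, "choice_data"), inherits(spec, "model_spec"))
  if (!isTRUE(attr(data, "standardized")))
    stop("design requires standardized covariates")
  df <- as.data.frame(data)
  n_sets <- nrow(df) / 4L
  K <- length(spec$terms)
  Z <- array(0, c(4L, n_sets, max(K, 1L)))
  for (j in seq_along(spec$covariates))
    Z[, , j] <- matrix(df[[spec$covariates[j]]], nrow = 4L)
  for (j in seq_along(spec$quadratic))
    Z[, , length(spec$covariates) + j] <-
      matrix(df[[spec$quadratic[j]]], nrow = 4L)^2
  used <- matrix(df$used, nrow = 4L)
  chosen <- apply(used, 2L, which)
  set_rows <- seq(1L, nrow(df), by = 4L)
  covey <- df$covey_id[set_rows]
  season <- df$season[set_rows]
  grp_key <- paste(covey, season, sep = "\r")
  groups <- unique(data.frame(covey = covey, season = season,
                              key = grp_key, stringsAsFactors = FALSE))
  groups <- groups[order(groups$covey, groups$season), , drop = FALSE]
  list(Z = Z, chosen = as.integer(chosen), n_sets = n_sets, K = K,
       covey = covey, season = as.integer(season),
       set_group = match(grp_key, groups$key),
       group_covey = groups$covey, group_season = as.integer(groups$season),
       set_id = df$set_id[set_rows], terms = spec$terms)
}

#' Log-likelihood of one choice set
#'
#' Log of the softmax probability of the used alternative among the four,
#' computed with max-subtraction for overflow safety. With all coefficients
#' zero this is log(1/4) = -1.3862944. Reference (R) implementation of the
#' model likelihood; the sampler uses an equivalent compiled version.
#'
#' @param set A 4-row data frame for one choice set, with standardized
#'   covariate columns and a logical \code{used} column.
#' @param beta Named numeric vector of coefficients covering every model
#'   term (for quadratic terms name the entry \code{"<cov>^2"}).
#' @param spec A \code{\link{model_spec}}.
#' @return Log-probability (scalar, finite).
#' @export
choice_set_loglik <- function(set, beta, spec) {
  stopifnot(inherits(spec, "model_spec"), nrow(set) == 4L,
            sum(set$used) == 1L)
  miss <- setdiff(spec$terms, names(beta))
  if (length(miss)) stop("missing coefficient(s): ",
                         paste(miss, collapse = ", "))
  u <- numeric(4L)
  for (k in spec$covariates) u <- u + beta[[k]] * set[[k]]
  for (k in spec$quadratic) u <- u + beta[[paste0(k, "^2")]] * set[[k]]^2
  u <- u - max(u)
  u[set$used] - log(sum(exp(u)))
}

#' Unnormalized log-posterior density
#'
#' Sum of the choice-set log-likelihoods, the Normal population density of
#' the covey-level coefficients, the Normal(0, \code{prior_mu_sd}) prior on
#' each population mean, and the half-Normal(\code{prior_sigma_sd}) prior on
#' each population sd. Reference implementation used for validation; the
#' sampler evaluates the same density incrementally in compiled code.
#'
#' @param mu,sigma Matrices K x 2 (rows = model terms, columns fall/winter).
#' @param beta Matrix n_groups x K of covey-season coefficients, where the
#'   groups are the covey-season combinations of \code{design} (ignored when
#'   the model has no covey random coefficients; pass NULL).
#' @param data A standardized \code{choice_data}, or NULL for the prior-only
#'   density (no choice sets, no covey groups).
#' @param spec A \code{\link{model_spec}}.
#' @param prior_mu_sd,prior_sigma_sd Prior scales (defaults 10 and 5).
#' @return Scalar log-density (unnormalized).
#' @export
log_posterior <- function(mu, sigma, beta, data, spec,
                          prior_mu_sd = 10, prior_sigma_sd = 5) {
  if (is.null(data)) {
    K <- length(spec$terms)
    mu <- matrix(mu, K, 2)
    lp <- sum(stats::dnorm(mu, 0, prior_mu_sd, log = TRUE))
    if (spec$random_coveys) {
      sigma <- matrix(sigma, K, 2)
      if (any(sigma <= 0)) return(-Inf)
      lp <- lp +
        sum(stats::dnorm(sigma, 0, prior_sigma_sd, log = TRUE) + log(2))
    }
    return(lp)
  }
  d <- dcm_design(data, spec)
  K <- d$K
  mu <- matrix(mu, K, 2);
  lp <- sum(stats::dnorm(mu, 0, prior_mu_sd, log = TRUE))
  if (spec$random_coveys) {
    sigma <- matrix(sigma, K, 2)
    if (any(sigma <= 0)) return(-Inf)
    lp <- lp + sum(stats::dnorm(sigma, 0, prior_sigma_sd, log = TRUE) + log(2))
    beta <- matrix(beta, length(d$group_covey), K)
    for (g in seq_along(d$group_covey)) {
      s <- d$group_season[g] + 1L
      lp <- lp + sum(stats::dnorm(beta[g, ], mu[, s], sigma[, s], log = TRUE))
    }
    coef_of_set <- function(i) beta[d$set_group[i], ]
  } else {
    coef_of_set <- function(i) mu[, d$season[i] + 1L]
  }
  if (d$n_sets > 0 && K > 0) {
    for (i in seq_len(d$n_sets)) {
      u <- matrix(d$Z[, i, ], nrow = 4L) %*% coef_of_set(i)
      u <- u - max(u)
      lp <- lp + u[d$chosen[i]] - log(sum(exp(u)))
    }
  } else if (d$n_sets > 0) {
    lp <- lp + d$n_sets * log(0.25)
  }
  lp
}
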