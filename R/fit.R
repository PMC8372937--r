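#' Fit the hierarchical discrete-choice model by MCMC
#'
#' Samples the posterior of all population means mu[k, season], population
#' sds sigma[k, season] and covey-season coefficients beta by adaptive
#' Metropolis-within-Gibbs (population means use their exact conjugate Gibbs
#' draw). Chains are initialized over-dispersed and run sequentially under a
#' single seed, so a fit is fully reproducible. Covariates are standardized
#' internally (pooled over all alternatives) unless the data already are.
#'
#' A specification that fails the VIF screen (threshold 2.5) is fitted with
#' a warning, mirroring a collinearity screen done before modelling. The
#' null specification (no covariates) skips sampling entirely.
#'
#' @param data A \code{choice_data} object (raw or standardized scale).
#' @param spec A \code{\link{model_spec}}.
#' @param mcmc An \code{\link{mcmc_config}}.
#' @param vif_threshold Threshold for the collinearity warning (default 2.5).
#' @return An object of class \code{dcm_fit}: \code{draws} (array chains x
#'   retained x parameters, with parameter names like \code{mu[GS,fall]}),
#'   \code{spec}, \code{mcmc}, \code{std_params}, the internal design, and
#'   per-covariate observed ranges for prediction grids.
#' @seealso \code{\link{summarize_posterior}}, \code{\link{gelman_rubin}},
#'   \code{\link{compute_waic}}, \code{\link{relative_probability_curve}}
#' @export
fit_dcm <- function(data, spec, mcmc = mcmc_config(), vif_threshold = 2.5) {
  stopifnot(inherits(data, "choice_data"), inherits(spec, "model_spec"),
            inherits(mcmc, "mcmc_config"))
  covs <- attr(data, "covariates")
  if (isTRUE(attr(data, "standardized"))) {
    params <- attr(data, "std_params")
    if (is.null(params))
      stop("standardized data must carry its standardization_params attribute")
    std <- list(data = data, params = params)
    raw_range <- lapply(covs, function(k)
      unstandardize(range(as.data.frame(data)[[k]]), params, k))
  } else {
    std <- standardize_covariates(data)
    raw_range <- lapply(covs, function(k) range(as.data.frame(data)[[k]]))
  }
  names(raw_range) <- covs
  if (length(spec$covariates) >= 2L) {
    v <- vif_screen(std$data, spec$covariates, vif_threshold)
    if (!v$pass)
      warning("model covariates fail the VIF screen (max VIF = ",
              format(max(v$vif), digits = 4), ")")
  }
  d <- dcm_design(std$data, spec)
  K <- d$K
  seasons <- c("fall", "winter")
  par_names <- c(
    as.vector(outer(d$terms, seasons,
                    function(k, s) sprintf("mu[%s,%s]", k, s))),
    if (spec$random_coveys && K > 0)
      as.vector(outer(d$terms, seasons,
                      function(k, s) sprintf("sigma[%s,%s]", k, s))),
    if (spec$random_coveys && K > 0)
      unlist(lapply(seq_along(d$group_covey), function(g)
        sprintf("beta[%s,%s,%s]", d$terms, seasons[d$group_season[g] + 1L],
                d$group_covey[g]))))
  if (K == 0L) {
    draws <- array(numeric(0), c(mcmc$n_chains, 0L, 0L))
    fit <- list(draws = draws, par_names = character(0), spec = spec,
                mcmc = mcmc, std_params = std$params, design = d,
                raw_range = raw_range, data = std$data)
    class(fit) <- "dcm_fit"
    return(fit)
  }

  n_keep <- (mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thin
  if (n_keep < 1) stop("no retained draws; check n_iterations/burn_in/thin")
  draws <- array(NA_real_, c(mcmc$n_chains, n_keep, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  n_groups <- length(d$group_covey)
  set.seed(mcmc$seed)
  for (ch in seq_len(mcmc$n_chains)) {
    # over-dispersed initials
    mu0 <- matrix(stats::rnorm(2 * K, 0, 2), K, 2)
    sig0 <- matrix(stats::runif(2 * K, 0.3, 2), K, 2)
    beta0 <- matrix(0, max(n_groups, 1L), K)
    for (g in seq_len(n_groups)) {
      s <- d$group_season[g] + 1L
      beta0[g, ] <- stats::rnorm(K, mu0[, s], sig0[, s])
    }
    for (try in 1:3) {
      ch_draws <- dcm_mcmc_chain(
        as.numeric(d$Z[, , seq_len(K), drop = FALSE]), d$n_sets, K,
        d$chosen - 1L, d$set_group - 1L, d$season,
        d$group_season, n_groups, spec$random_coveys,
        mcmc$n_iterations, mcmc$burn_in, mcmc$thin,
        mcmc$prior_mu_sd, mcmc$prior_sigma_sd, mu0, sig0, beta0)
      if (all(is.finite(ch_draws))) break
      if (try == 3)
        stop("non-finite draws in chain ", ch, " after re-drawn initials; ",
             "check the data and priors")
      # re-draw initial values and retry
      mu0 <- matrix(stats::rnorm(2 * K, 0, 1), K, 2)
      sig0 <- matrix(stats::runif(2 * K, 0.3, 1), K, 2)
      for (g in seq_len(n_groups))
        beta0[g, ] <- stats::rnorm(K, mu0[, d$group_season[g] + 1L], 0.5)
    }
    draws[ch, , ] <- ch_draws
  }
  fit <- list(draws = draws, par_names = par_names, spec = spec, mcmc = mcmc,
              std_params = std$params, design = d, raw_range = raw_range,
              data = std$data)
  class(fit) <- "dcm_fit"
  fit
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("dcm_fit:",
      if (length(x$spec$terms)) paste(x$spec$terms, collapse = " + ")
      else "(null model)", "\n")
  cat(sprintf("  %d choice sets, %d covey-season groups, %d chains x %d draws\n",
              x$design$n_sets, length(x$design$group_covey),
              dim(x$draws)[1L], dim(x$draws)[2L]))
  if (length(x$par_names)) {
    gr <- gelman_rubin(x)
    pop <- grepl("^(mu|sigma)\\[", names(gr))
    cat(sprintf("  max Gelman-Rubin: %.3f (population-level: %.3f)\n",
                max(gr), max(gr[pop])))
  }
  invisible(x)
}

# population-level parameter draws pooled across chains: matrix draws x params
pooled_draws <- function(fit, pattern = NULL) {
  d <- fit$draws
  m <- matrix(d, prod(dim(d)[1:2]), dim(d)[3L])
  colnames(m) <- fit$par_names
  if (!is.null(pattern)) m <- m[, grepl(pattern, colnames(m)), drop = FALSE]
  m
}

#' Gelman-Rubin convergence statistic
#'
#' Potential scale reduction factor per parameter: with m chains of n draws,
#' W the mean within-chain variance and B/n the variance of chain means,
#' Rhat = sqrt(((n-1)/n W + B/n) / W). Values below 1.1 are conventionally
#' taken as converged; parameters at or above 1.1 are flagged.
#'
#' @param x A \code{dcm_fit}, or a 3-d array (chains x draws x parameters).
#' @return Named vector of Rhat values, with attribute \code{"flagged"}
#'   listing parameters >= 1.1.
#' @export
gelman_rubin <- function(x) {
  a <- if (inherits(x, "dcm_fit")) x$draws else x
  if (length(dim(a)) != 3L) stop("need a chains x draws x parameters array")
  m <- dim(a)[1L]; n <- dim(a)[2L]
  if (m < 2L) stop("need at least 2 chains")
  if (n < 10L) stop("need at least 10 retained draws per chain")
  rhat <- apply(a, 3L, function(ch) {
    ch <- matrix(ch, m, n)  # chains x draws
    W <- mean(apply(ch, 1L, stats::var))
    B_over_n <- stats::var(rowMeans(ch))
    if (W == 0) return(if (B_over_n == 0) sqrt((n - 1) / n) else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
  names(rhat) <- dimnames(a)[[3L]]
  attr(rhat, "flagged") <- names(rhat)[rhat >= 1.1]
  rhat
}

#' Posterior summary table
#'
#' Per parameter: posterior mean (PM), equal-tailed credible interval at the
#' given level (default 85%, i.e. the 7.5th and 92.5th percentiles, linearly
#' interpolated with R's default type-7 quantile rule), the proportion of
#' draws that are positive and negative, a support flag when either
#' proportion exceeds 0.85, and (with >= 2 chains) the Gelman-Rubin
#' statistic.
#'
#' @param x A \code{dcm_fit} or a 3-d draws array with named parameters.
#' @param level Credible level (default 0.85).
#' @param population_only Keep only mu and sigma parameters (default TRUE
#'   for fits; covey-level coefficients are nuisance detail).
#' @return Data frame with one row per parameter.
#' @export
summarize_posterior <- function(x, level = 0.85, population_only = TRUE) {
  a <- if (inherits(x, "dcm_fit")) x$draws else x
  if (length(dim(a)) != 3L) stop("need a chains x draws x parameters array")
  if (dim(a)[3L] == 0L) stop("no parameters to summarize")
  nms <- dimnames(a)[[3L]]
  keep <- if (population_only && any(grepl("^(mu|sigma)\\[", nms)))
    grepl("^(mu|sigma)\\[", nms) else rep(TRUE, length(nms))
  alpha <- (1 - level) / 2
  rows <- lapply(which(keep), function(j) {
    v <- as.vector(a[, , j])
    q <- stats::quantile(v, c(alpha, 1 - alpha), names = FALSE, type = 7)
    pp <- mean(v > 0); pn <- mean(v < 0)
    data.frame(parameter = nms[j], PM = mean(v), lower = q[1L],
               upper = q[2L], prop_pos = pp, prop_neg = pn,
               support = if (pp > 0.85) "+" else if (pn > 0.85) "-" else "0")
  })
  out <- do.call(rbind, rows)
  if (dim(a)[1L] >= 2L && dim(a)[2L] >= 10L)
    out$rhat <- unname(gelman_rubin(a)[keep])
  rownames(out) <- NULL
  out
}
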