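# Conditional-logit likelihood, log-posterior, sampler, diagnostics.

test_that("model_spec enforces its invariants", {
  expect_error(model_spec(c("NG", "NGxPG")), "requires NG and PG")
  expect_error(model_spec("XX"), "unknown covariate")
  expect_error(model_spec(c("VO"), quadratic = "GS"), "quadratic")
  s <- model_spec(c("VO", "SC"), quadratic = "VO")
  expect_identical(s$terms, c("VO", "SC", "VO^2"))
  expect_identical(model_spec(character(0))$terms, character(0))
})

test_that("choice-set log-likelihood matches closed forms", {
  set <- data.frame(FB = c(log(3), 0, 0, 0), used = c(TRUE, rep(FALSE, 3)))
  spec <- model_spec("FB")
  # utilities (ln 3, 0, 0, 0), used = first -> log(3/6)
  expect_equal(choice_set_loglik(set, c(FB = 1), spec), log(0.5),
               tolerance = 1e-12)
  # all-zero coefficients -> log(1/4)
  expect_equal(choice_set_loglik(set, c(FB = 0), spec), -1.3862944,
               tolerance = 1e-7)
  # shift invariance: adding a constant to the covariate shifts all four
  # utilities equally and leaves the probability unchanged
  set2 <- set; set2$FB <- set2$FB + 37.5
  expect_equal(choice_set_loglik(set2, c(FB = 1.3), spec),
               choice_set_loglik(set, c(FB = 1.3), spec), tolerance = 1e-12)
  # overflow safety at extreme utilities
  set3 <- data.frame(FB = c(900, 0, 0, 0), used = c(TRUE, rep(FALSE, 3)))
  expect_true(is.finite(choice_set_loglik(set3, c(FB = 2), spec)))
  expect_error(choice_set_loglik(set, c(GS = 1), spec), "missing coefficient")
})

test_that("log-posterior decomposes and matches a direct evaluation", {
  rows <- make_choice_rows(3, n_coveys = 2, seed = 41, season = c(0, 1, 0))
  cd <- standardize_covariates(assemble_choice_sets(rows))$data
  spec <- model_spec("VO")
  d <- coveysel:::dcm_design(cd, spec)
  G <- length(d$group_covey)
  mu <- matrix(c(0.6, -0.4), 1, 2)
  sigma <- matrix(c(0.9, 1.4), 1, 2)
  beta <- matrix(seq(-0.5, 0.7, length.out = G), G, 1)

  # independent direct evaluation, coded from the model definition
  df <- as.data.frame(cd)
  direct <- sum(dnorm(mu, 0, 10, log = TRUE)) +
    sum(dnorm(sigma, 0, 5, log = TRUE) + log(2))
  for (g in seq_len(G))
    direct <- direct + dnorm(beta[g, 1], mu[1, d$group_season[g] + 1],
                             sigma[1, d$group_season[g] + 1], log = TRUE)
  for (i in seq_len(3)) {
    r <- df[(4 * i - 3):(4 * i), ]
    b <- beta[d$set_group[i], 1]
    pr <- exp(b * r$VO) / sum(exp(b * r$VO))
    direct <- direct + log(pr[r$used])
  }
  got <- log_posterior(mu, sigma, beta, cd, spec)
  expect_equal(got, direct, tolerance = 1e-10)

  # additivity: likelihood-only part equals the sum of set log-likelihoods
  prior_only <- log_posterior(mu, sigma, beta, NULL, spec) +
    sum(vapply(seq_len(3), function(i) {
      r <- df[(4 * i - 3):(4 * i), ]
      choice_set_loglik(r, c(VO = beta[d$set_group[i], 1]), spec)
    }, numeric(1))) +
    sum(vapply(seq_len(G), function(g)
      dnorm(beta[g, 1], mu[1, d$group_season[g] + 1],
            sigma[1, d$group_season[g] + 1], log = TRUE), numeric(1)))
  expect_equal(got, prior_only, tolerance = 1e-10)

  # zero data -> prior alone
  expect_equal(log_posterior(mu, sigma, NULL, NULL, spec),
               sum(dnorm(mu, 0, 10, log = TRUE)) +
                 sum(dnorm(sigma, 0, 5, log = TRUE) + log(2)),
               tolerance = 1e-12)
  expect_identical(log_posterior(mu, matrix(c(-1, 1), 1, 2), NULL, NULL, spec),
                   -Inf)
})

test_that("softmax probabilities across each set sum to one", {
  sim <- simulate_choice_data(generator_config(n_coveys = 6, n_sets = 40,
                                               seed = 3))
  expect_true(all(abs(rowSums(sim$truth$probabilities) - 1) < 1e-12))
})

test_that("the likelihood is invariant to within-set alternative order", {
  rows <- make_choice_rows(1, seed = 51)
  spec <- model_spec(c("VO", "SC"))
  set <- rows[, c("VO", "SC", "used")]
  b <- c(VO = 0.8, SC = -0.5)
  base <- choice_set_loglik(set, b, spec)
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2)))
    expect_equal(choice_set_loglik(set[perm, ], b, spec), base,
                 tolerance = 1e-12)
})

test_that("the sampler is reproducible and matches grid quadrature", {
  # 1-covariate, non-hierarchical model; dense grid integration as oracle
  cfg <- generator_config(n_coveys = 10, n_sets = 200, covariates = "VO",
                          mu = matrix(c(1.2, 1.2), 1, 2),
                          sigma = matrix(0, 1, 2), fall_fraction = 1,
                          seed = 61)
  sim <- simulate_choice_data(cfg)
  spec <- model_spec("VO", random_coveys = FALSE)
  mc <- mcmc_config(n_chains = 4, n_iterations = 8000, burn_in = 2000,
                    thin = 5, seed = 62)
  fit <- fit_dcm(sim$data, spec, mc)
  fit2 <- fit_dcm(sim$data, spec, mc)
  expect_identical(fit$draws, fit2$draws)  # determinism

  # grid oracle for the fall coefficient
  std <- standardize_covariates(sim$data)$data
  df <- as.data.frame(std)
  vo <- matrix(df$VO, nrow = 4)
  used <- matrix(df$used, nrow = 4)
  loglik_of <- function(b) {
    u <- b * vo
    u <- sweep(u, 2, apply(u, 2, max))
    sum((u[used] - log(colSums(exp(u)))))
  }
  grid <- seq(0, 3, length.out = 4001)
  lp <- vapply(grid, function(b)
    loglik_of(b) + dnorm(b, 0, 10, log = TRUE), numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  post_mean <- sum(grid * w)
  post_sd <- sqrt(sum(grid^2 * w) - post_mean^2)

  mu_draws <- coveysel:::pooled_draws(fit)[, "mu[VO,fall]"]
  ess <- coda::effectiveSize(mu_draws)
  mcse <- post_sd / sqrt(ess)
  expect_lt(abs(mean(mu_draws) - post_mean), 3 * mcse)
  expect_lt(abs(stats::sd(mu_draws) - post_sd), 0.1 * post_sd)
})

test_that("a within-set-constant covariate carries no information", {
  # conditional-logit identifiability: only within-set contrasts matter, so
  # a covariate constant inside every set leaves its coefficient at the prior
  rows <- make_choice_rows(40, seed = 71, season = rep(0L, 40))
  rows$VO <- rep(runif(40, 10, 90), each = 4)  # constant within each set
  cd <- assemble_choice_sets(rows)
  fit <- fit_dcm(cd, model_spec("VO", random_coveys = FALSE),
                 mcmc_config(n_chains = 2, n_iterations = 30000,
                             burn_in = 5000, thin = 10, seed = 72))
  mu_draws <- coveysel:::pooled_draws(fit)[, "mu[VO,fall]"]
  # posterior approximately equals the Normal(0, 10) prior
  expect_lt(abs(mean(mu_draws)), 2.5)
  expect_gt(stats::sd(mu_draws), 7)
  expect_lt(stats::sd(mu_draws), 13)
})

test_that("non-hierarchical posterior agrees with conditional-logistic MLE", {
  # with a vague prior and ample data the posterior mode matches clogit
  cfg <- generator_config(n_coveys = 10, n_sets = 300,
                          covariates = c("VO", "SC"),
                          mu = matrix(c(0.8, -0.6, 0.8, -0.6), 2, 2),
                          sigma = matrix(0, 2, 2), fall_fraction = 1, seed = 81)
  sim <- simulate_choice_data(cfg)
  fit <- fit_dcm(sim$data, model_spec(c("VO", "SC"), random_coveys = FALSE),
                 mcmc_config(n_chains = 2, n_iterations = 8000,
                             burn_in = 2000, thin = 5, seed = 82))
  s <- summarize_posterior(fit, population_only = FALSE)
  std <- as.data.frame(standardize_covariates(sim$data)$data)
  std$stratum <- match(std$set_id, unique(std$set_id))
  cl <- survival::coxph(survival::Surv(rep(1, nrow(std)), std$used) ~ VO +
                          SC + survival::strata(stratum),
                        data = std, method = "exact")
  expect_equal(s$PM[s$parameter == "mu[VO,fall]"], unname(coef(cl)["VO"]),
               tolerance = 0.08)
  expect_equal(s$PM[s$parameter == "mu[SC,fall]"], unname(coef(cl)["SC"]),
               tolerance = 0.12)
})

test_that("Gelman-Rubin statistic behaves across null and divergent cases", {
  # 4 chains from one Normal: statistic near 1
  set.seed(91)
  a <- array(rnorm(4 * 1000 * 3), c(4, 1000, 3),
             dimnames = list(NULL, NULL, c("p1", "p2", "p3")))
  gr <- gelman_rubin(a)
  expect_true(all(gr > 0.99 & gr < 1.05))
  expect_length(attr(gr, "flagged"), 0)

  # two chains centered 100 apart: dominated by between-chain variance
  set.seed(92)
  n <- 500
  b <- aperm(array(c(rnorm(n, 0), rnorm(n, 100)), c(n, 2, 1)), c(2, 1, 3))
  dimnames(b) <- list(NULL, NULL, "p")
  ch <- matrix(b[, , 1], 2, n)
  W <- mean(apply(ch, 1, var))
  B_over_n <- var(rowMeans(ch))
  expected <- sqrt(((n - 1) / n * W + B_over_n) / W)
  got <- gelman_rubin(b)
  expect_equal(unname(got["p"]), expected, tolerance = 1e-12)
  expect_gt(got["p"], 10)
  expect_identical(attr(got, "flagged"), "p")

  # identical chains with nonzero spread: sqrt((n-1)/n) < 1
  one <- rnorm(n)
  cc <- aperm(array(rep(one, 2), c(n, 2, 1)), c(2, 1, 3))
  dimnames(cc) <- list(NULL, NULL, "p")
  expect_equal(unname(gelman_rubin(cc)["p"]), sqrt((n - 1) / n),
               tolerance = 1e-12)

  expect_error(gelman_rubin(a[1, , , drop = FALSE]), "2 chains")
})

test_that("Gelman-Rubin agrees with coda on real draws", {
  sim <- simulate_choice_data(generator_config(n_coveys = 5, n_sets = 40,
                                               seed = 95))
  fit <- fit_dcm(sim$data, model_spec(c("VO", "SC")),
                 mcmc_config(n_chains = 3, n_iterations = 3000,
                             burn_in = 500, thin = 5, seed = 96))
  idx <- match(c("mu[VO,fall]", "mu[SC,winter]"), fit$par_names)
  ml <- coda::mcmc.list(lapply(1:3, function(ch)
    coda::mcmc(fit$draws[ch, , idx])))
  ours <- gelman_rubin(fit)[idx]
  coda_gr <- coda::gelman.diag(ml, autoburnin = FALSE,
                               multivariate = FALSE)$psrf[, 1]
  # formulas differ by a small degrees-of-freedom correction
  expect_equal(unname(ours), unname(coda_gr), tolerance = 0.05)
})

test_that("posterior summaries use the declared percentile rule", {
  a <- array(rep(1:1000, each = 1), c(1, 1000, 1),
             dimnames = list(NULL, NULL, "p"))
  s <- summarize_posterior(a, population_only = FALSE)
  # type-7 linear interpolation: h = (n-1)p + 1 -> 75.925 and 925.075
  expect_equal(s$lower, 75.925, tolerance = 1e-9)
  expect_equal(s$upper, 925.075, tolerance = 1e-9)
  expect_equal(s$PM, 500.5)
  expect_equal(s$prop_pos, 1); expect_equal(s$support, "+")

  sym <- array(c(-(1:100) / 10, (1:100) / 10), c(1, 200, 1),
               dimnames = list(NULL, NULL, "p"))
  s2 <- summarize_posterior(sym, population_only = FALSE)
  expect_equal(s2$PM, 0, tolerance = 1e-12)
  expect_equal(s2$lower, -s2$upper, tolerance = 1e-12)
  expect_equal(s2$prop_pos, 0.5)
  expect_equal(s2$support, "0")
})

test_that("mcmc_config and retained-draw accounting are consistent", {
  expect_error(mcmc_config(n_iterations = 100, burn_in = 200), "exceed")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(prior_mu_sd = 0), "proper")
  cfg <- mcmc_config()
  expect_equal((cfg$n_iterations - cfg$burn_in) / cfg$thin, 1800)
  sim <- simulate_choice_data(generator_config(n_coveys = 4, n_sets = 20,
                                               seed = 97))
  fit <- fit_dcm(sim$data, model_spec("VO"),
                 mcmc_config(n_chains = 2, n_iterations = 1000, burn_in = 200,
                             thin = 4, seed = 98))
  expect_equal(dim(fit$draws)[2], (1000 - 200) / 4)
  expect_equal(dim(fit$draws)[1], 2)
  # parameter names are unique and cover mu, sigma, beta
  expect_false(anyDuplicated(fit$par_names) > 0)
  expect_true(all(grepl("^(mu|sigma|beta)\\[", fit$par_names)))
})
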