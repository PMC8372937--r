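# WAIC model comparison with the uninformative-model filter.

# per-draw, per-set log-likelihood matrix (n_sets x n_draws) for a fit
pointwise_loglik <- function(fit) {
  d <- fit$design
  n <- d$n_sets
  if (d$K == 0L || length(fit$par_names) == 0L) {
    # null model: utilities all zero
    return(matrix(log(0.25), n, 1L))
  }
  K <- d$K
  draws <- pooled_draws(fit)
  D <- nrow(draws)
  ll <- matrix(NA_real_, n, D)
  seasons <- c("fall", "winter")
  if (fit$spec$random_coveys) {
    for (g in seq_along(d$group_covey)) {
      cols <- sprintf("beta[%s,%s,%s]", d$terms,
                      seasons[d$group_season[g] + 1L], d$group_covey[g])
      bg <- draws[, cols, drop = FALSE]           # D x K
      sets <- which(d$set_group == g)
      Zg <- matrix(aperm(d$Z[, sets, seq_len(K), drop = FALSE],
                         c(1L, 2L, 3L)), nrow = 4L * length(sets))  # (4m) x K
      U <- Zg %*% t(bg)                           # (4m) x D
      for (t in seq_along(sets)) {
        u <- U[(t - 1L) * 4L + 1:4, , drop = FALSE]
        um <- apply(u, 2L, max)
        u <- sweep(u, 2L, um)
        ll[sets[t], ] <- u[d$chosen[sets[t]], ] - log(colSums(exp(u)))
      }
    }
  } else {
    for (s in 0:1) {
      cols <- sprintf("mu[%s,%s]", d$terms, seasons[s + 1L])
      bs <- draws[, cols, drop = FALSE]
      sets <- which(d$season == s)
      if (!length(sets)) next
      Zs <- matrix(d$Z[, sets, seq_len(K)], nrow = 4L * length(sets))
      U <- Zs %*% t(bs)
      for (t in seq_along(sets)) {
        u <- U[(t - 1L) * 4L + 1:4, , drop = FALSE]
        um <- apply(u, 2L, max)
        u <- sweep(u, 2L, um)
        ll[sets[t], ] <- u[d$chosen[sets[t]], ] - log(colSums(exp(u)))
      }
    }
  }
  ll
}

#' Watanabe-Akaike information criterion
#'
#' Computed from the pointwise posterior log-likelihood of each choice set:
#' lppd_i = log mean_d p(set_i | draw_d), the effective-parameter term is
#' the posterior variance of the set-level log-likelihood (the variance
#' form, pWAIC2), and WAIC = -2 * sum_i (lppd_i - pWAIC_i). Lower is better.
#'
#' @param fit A \code{dcm_fit}.
#' @param loglik_matrix Optional precomputed matrix (n_sets x n_draws) of
#'   set-level log-likelihoods; by default computed from the fit's draws.
#' @return Object of class \code{waic_result}: \code{lppd_i}, \code{pwaic_i}
#'   (pointwise vectors), \code{lppd}, \code{p_waic}, \code{waic}, and the
#'   fit's \code{model_spec}.
#' @export
compute_waic <- function(fit, loglik_matrix = NULL) {
  ll <- if (is.null(loglik_matrix)) pointwise_loglik(fit) else loglik_matrix
  if (inherits(fit, "dcm_fit") && nrow(ll) != fit$design$n_sets)
    stop("log-likelihood matrix does not match the fitted data")
  # lppd via log-sum-exp for stability
  lppd_i <- apply(ll, 1L, function(v) {
    m <- max(v)
    m + log(mean(exp(v - m)))
  })
  pwaic_i <- if (ncol(ll) > 1L) apply(ll, 1L, stats::var) else
    rep(0, nrow(ll))
  structure(list(lppd_i = lppd_i, pwaic_i = pwaic_i,
                 lppd = sum(lppd_i), p_waic = sum(pwaic_i),
                 waic = -2 * (sum(lppd_i) - sum(pwaic_i)),
                 spec = if (inherits(fit, "dcm_fit")) fit$spec else NULL),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (lppd %.2f, pWAIC %.2f)",
              x$waic, x$lppd, x$p_waic))
  if (!is.null(x$spec))
    cat(" -", if (length(x$spec$terms))
      paste(x$spec$terms, collapse = " + ") else "(null model)")
  cat("\n")
  invisible(x)
}

#' Rank candidate models by WAIC and filter uninformative ones
#'
#' Sorts models ascending by WAIC and computes each model's difference from
#' the best (dWAIC). Among competitive models (dWAIC < 2), a model is
#' removed from consideration when a simpler competitive model (strictly
#' fewer terms) shares one or more of its terms — the more complex model is
#' taken as uninformative. Models with dWAIC >= 2 are retained but
#' uncompetitive.
#'
#' @param results List of \code{waic_result} objects (each carrying its
#'   \code{model_spec}).
#' @param names Optional model names (default m1, m2, ... in input order).
#' @return Data frame of class \code{model_ranking}: name, terms, WAIC,
#'   dWAIC, competitive flag, removed flag, reason.
#' @export
rank_models <- function(results, names = NULL) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1L), "waic_result")))
  terms <- lapply(results, function(r) r$spec$terms)
  key <- vapply(terms, function(t) paste(sort(t), collapse = "+"), character(1L))
  if (anyDuplicated(key)) stop("duplicate model specifications")
  if (is.null(names)) names <- paste0("m", seq_along(results))
  waic <- vapply(results, function(r) r$waic, numeric(1L))
  ord <- order(waic)
  waic <- waic[ord]; terms <- terms[ord]; names <- names[ord]
  dwaic <- waic - waic[1L]
  competitive <- dwaic < 2
  removed <- logical(length(waic))
  reason <- character(length(waic))
  for (i in which(competitive)) {
    for (j in which(competitive)) {
      if (length(terms[[j]]) < length(terms[[i]]) &&
          length(intersect(terms[[i]], terms[[j]])) >= 1L) {
        removed[i] <- TRUE
        reason[i] <- paste0("more complex than competitive ", names[j])
        break
      }
    }
  }
  out <- data.frame(
    model = names,
    terms = vapply(terms, function(t)
      if (length(t)) paste(t, collapse = "+") else "(null)", character(1L)),
    waic = waic, dwaic = dwaic, competitive = competitive,
    removed = removed, reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("model_ranking", "data.frame")
  out
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Model ranking by WAIC (dWAIC < 2 competitive; complex competitive\n",
      "models sharing terms with a simpler one are removed):\n", sep = "")
  print.data.frame(x, digits = 6)
  invisible(x)
}
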