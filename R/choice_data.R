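# Choice-set data model.
#
# The exchange representation is a long data frame: one row per alternative,
# four rows per choice set (1 used + 3 available), with columns
# set_id, covey_id, date (optional), season, used, and the nine measured
# covariates. The derived interaction NGxPG is added at assembly time.

#' Covariate names used by the discrete-choice model
#'
#' The nine measured covariates, in canonical order: percent forbs (FB),
#' percent grass (GS), percent bare ground (BR) in a 0.50-m2 frame; visual
#' obstruction of a 2-m pole (VO, percent); woody stems >1 m within 5 m (SC,
#' count); proportion native grass (NG) and proportion burned/grazed within
#' 12 months (PG) within 50 m; distance to nearest tree (TD, m); woody edge
#' density within 50 m (WE, m/ha). \code{"NGxPG"} denotes the derived
#' NG-by-PG interaction.
#'
#' @return Character vector of covariate names.
#' @export
covariate_names <- function() c("FB", "GS", "BR", "VO", "SC",
                                "NG", "PG", "TD", "WE")

# closed bounds for range validation; NA = unbounded above
covariate_bounds <- function() {
  list(FB = c(0, 100), GS = c(0, 100), BR = c(0, 100), VO = c(0, 100),
       SC = c(0, NA), NG = c(0, 1), PG = c(0, 1), TD = c(0, NA),
       WE = c(0, NA))
}

#' Sample available locations around a used location
#'
#' Draws points uniformly in distance on [\code{min_dist}, \code{max_dist}]
#' and uniformly in azimuth on (0, 360] degrees (measured clockwise from
#' north) around a used location. The defaults mirror a used-available
#' telemetry design in which three available locations are offered per used
#' location, constrained between 50 m (so locations do not overlap) and 400 m
#' (a 90% movement quantile).
#'
#' @param x,y Coordinates of the used location (m).
#' @param n Number of available locations (default 3).
#' @param min_dist,max_dist Distance bounds in m (defaults 50 and 400).
#' @param seed Optional integer; if supplied, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Data frame with columns \code{x}, \code{y}, \code{distance},
#'   \code{azimuth}.
#' @export
sample_available_locations <- function(x, y, n = 3, min_dist = 50,
                                       max_dist = 400, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  if (!(min_dist > 0) || !(max_dist > min_dist))
    stop("need 0 < min_dist < max_dist")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d <- stats::runif(n, min_dist, max_dist)
  a <- 360 - stats::runif(n, 0, 360)   # uniform on (0, 360]
  rad <- a * pi / 180
  data.frame(x = x + d * sin(rad), y = y + d * cos(rad),
             distance = d, azimuth = a)
}

#' Season code from a date
#'
#' November maps to fall (0); December and January map to winter (1). Any
#' other month is outside the fall-winter study window and is rejected.
#'
#' @param date A \code{Date} (or anything \code{as.Date} accepts).
#' @return Integer vector of 0 (fall) / 1 (winter).
#' @export
season_from_date <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  out <- ifelse(m == 11L, 0L, ifelse(m %in% c(12L, 1L), 1L, NA_integer_))
  if (anyNA(out))
    stop("dates outside the November-January study window: ",
         paste(unique(format(as.Date(date)[is.na(out)])), collapse = ", "))
  out
}

#' Assemble and validate choice sets
#'
#' Groups a long covariate table into choice sets, enforcing the design
#' invariants: exactly 4 alternatives per set, exactly 1 of them used, season
#' coded 0 (fall) / 1 (winter), and every covariate present, finite and within
#' its physical range. The derived interaction column \code{NGxPG} is added.
#' Validation failures name the offending set.
#'
#' @param rows Data frame with columns \code{set_id}, \code{covey_id},
#'   \code{season} (or \code{date}, from which season is derived),
#'   \code{used}, and the nine covariates of \code{\link{covariate_names}}.
#' @return A \code{choice_data} object: the validated long data frame (rows
#'   ordered by set, used alternative first within each set) with attributes
#'   recording the covariate columns.
#' @export
assemble_choice_sets <- function(rows) {
  rows <- as.data.frame(rows)
  covs <- covariate_names()
  need <- c("set_id", "covey_id", "used", covs)
  if (!"season" %in% names(rows)) {
    if (!"date" %in% names(rows))
      stop("need a 'season' or 'date' column")
    rows$season <- season_from_date(rows$date)
  }
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(rows$season %in% c(0L, 1L)))
    stop("season must be coded 0 (fall) or 1 (winter)")
  rows$used <- as.logical(rows$used)

  bounds <- covariate_bounds()
  for (k in covs) {
    v <- rows[[k]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("covariate ", k, " has missing or non-finite values in set(s) ",
           paste(unique(rows$set_id[!is.finite(v) | is.na(v)]), collapse = ", "))
    b <- bounds[[k]]
    bad <- v < b[1L] | (!is.na(b[2L]) & v > b[2L])
    if (any(bad))
      stop("covariate ", k, " out of range in set(s) ",
           paste(unique(rows$set_id[bad]), collapse = ", "))
  }
  if (any(rows$SC != round(rows$SC)))
    stop("SC (stem count) must be integer-valued")

  sets <- split(seq_len(nrow(rows)), rows$set_id)
  for (sid in names(sets)) {
    idx <- sets[[sid]]
    if (length(idx) != 4L)
      stop("choice set ", sid, " has ", length(idx),
           " alternatives; expected exactly 4 (1 used + 3 available)")
    if (sum(rows$used[idx]) != 1L)
      stop("choice set ", sid, " has ", sum(rows$used[idx]),
           " used alternatives; expected exactly 1")
    if (length(unique(rows$covey_id[idx])) != 1L)
      stop("choice set ", sid, " spans multiple covey IDs")
    if (length(unique(rows$season[idx])) != 1L)
      stop("choice set ", sid, " spans multiple seasons")
  }

  rows$NGxPG <- rows$NG * rows$PG
  # canonical order: sets sorted by id, within-set input order preserved
  ord <- order(match(rows$set_id, names(sets)))
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("choice_data", "data.frame"),
            covariates = c(covs, "NGxPG"), standardized = FALSE)
}

#' @export
print.choice_data <- function(x, ...) {
  n_sets <- length(unique(x$set_id))
  cat(sprintf(
    "choice_data: %d choice sets (%d rows), %d coveys, %d fall / %d winter sets%s\n",
    n_sets, nrow(x), length(unique(x$covey_id)),
    sum(x$season == 0 & x$used), sum(x$season == 1 & x$used),
    if (isTRUE(attr(x, "standardized"))) ", standardized covariates" else ""))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ... ", nrow(x) - 4L, " more rows\n", sep = "")
  invisible(x)
}

#' Read / write choice-set data as CSV
#'
#' Long CSV, one row per alternative, round-tripping through
#' \code{\link{assemble_choice_sets}} validation on read.
#'
#' @param file Path to the CSV file.
#' @export
read_choice_csv <- function(file) {
  assemble_choice_sets(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_choice_csv
#' @param data A \code{choice_data} object (or compatible data frame).
#' @export
write_choice_csv <- function(data, file) {
  cols <- intersect(c("set_id", "covey_id", "date", "season", "used",
                      covariate_names()), names(data))
  utils::write.csv(as.data.frame(data)[, cols], file, row.names = FALSE)
  invisible(file)
}

#' Standardize covariates to pooled mean 0, sd 1
#'
#' Centres and scales each covariate over the pooled alternatives (used and
#' available together, across all choice sets) — the only pooling that keeps
#' within-choice-set contrasts meaningful. The interaction NGxPG is
#' standardized as its own column after forming the product on the raw scale.
#' Pass a previous \code{params} to apply an existing standardization (e.g.
#' to new prediction data).
#'
#' @param data A \code{choice_data} object.
#' @param params Optional \code{standardization_params} from a previous call.
#' @return List with elements \code{data} (standardized \code{choice_data})
#'   and \code{params} (per-covariate means and sds, class
#'   \code{standardization_params}).
#' @export
standardize_covariates <- function(data, params = NULL) {
  stopifnot(inherits(data, "choice_data"))
  covs <- attr(data, "covariates")
  if (is.null(params)) {
    mu <- vapply(covs, function(k) mean(data[[k]]), numeric(1L))
    sd_ <- vapply(covs, function(k) stats::sd(data[[k]]), numeric(1L))
    degenerate <- covs[sd_ == 0 | !is.finite(sd_)]
    if (length(degenerate))
      stop("zero-variance covariate(s): ", paste(degenerate, collapse = ", "))
    params <- structure(list(mean = mu, sd = sd_, covariates = covs),
                        class = "standardization_params")
  }
  for (k in covs) data[[k]] <- (data[[k]] - params$mean[[k]]) / params$sd[[k]]
  attr(data, "standardized") <- TRUE
  attr(data, "std_params") <- params
  list(data = data, params = params)
}

#' @export
print.standardization_params <- function(x, ...) {
  cat("standardization_params (pooled over all alternatives):\n")
  print(data.frame(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Back-transform standardized covariate values
#'
#' Inverse of \code{\link{standardize_covariates}} for a single covariate
#' axis; used to label prediction curves in original units.
#'
#' @param z Standardized values.
#' @param params A \code{standardization_params}.
#' @param covariate Covariate name.
#' @export
unstandardize <- function(z, params, covariate) {
  stopifnot(inherits(params, "standardization_params"))
  z * params$sd[[covariate]] + params$mean[[covariate]]
}

#' Variance-inflation-factor screen for a covariate combination
#'
#' VIF_k = 1 / (1 - R^2_k), where R^2_k is from the ordinary least-squares
#' regression (with intercept) of covariate k on the other covariates of the
#' combination, over the pooled alternatives. The combination passes when the
#' largest VIF is below the threshold (default 2.5). Exactly collinear
#' combinations report infinite VIF and fail.
#'
#' @param data A \code{choice_data} object (raw or standardized; VIF is
#'   scale-invariant).
#' @param combo Character vector of >= 2 covariate names (may include
#'   \code{"NGxPG"}).
#' @param threshold Pass threshold (default 2.5).
#' @return List with \code{vif} (named vector), \code{pass} (logical), and
#'   \code{threshold}; class \code{vif_screen}.
#' @export
vif_screen <- function(data, combo, threshold = 2.5) {
  stopifnot(inherits(data, "choice_data"))
  if (length(combo) < 2L) stop("need at least 2 covariates")
  bad <- setdiff(combo, attr(data, "covariates"))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  X <- as.data.frame(data)[, combo, drop = FALSE]
  if (nrow(X) <= length(combo)) stop("fewer pooled rows than covariates")
  vif <- vapply(combo, function(k) {
    fit <- stats::lm(stats::reformulate(setdiff(combo, k), response = k),
                     data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  structure(list(vif = vif, pass = all(is.finite(vif)) && max(vif) < threshold,
                 threshold = threshold),
            class = "vif_screen")
}

#' @export
print.vif_screen <- function(x, ...) {
  cat("VIF screen (threshold ", x$threshold, "):\n", sep = "")
  print(round(x$vif, 3))
  cat(if (x$pass) "PASS" else "FAIL",
      "- max VIF =", format(max(x$vif), digits = 4), "\n")
  invisible(x)
}
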