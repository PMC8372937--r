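# Shared fixtures and independent brute-force oracles.

# A valid long table of n_sets choice sets with random in-range covariates.
make_choice_rows <- function(n_sets, n_coveys = 4, seed = 1,
                             season = NULL) {
  set.seed(seed)
  n <- 4L * n_sets
  if (is.null(season)) season <- sample(0:1, n_sets, replace = TRUE)
  data.frame(
    set_id = rep(sprintf("s%03d", seq_len(n_sets)), each = 4L),
    covey_id = rep(sprintf("c%d", rep_len(seq_len(n_coveys), n_sets)),
                   each = 4L),
    season = rep(season, each = 4L),
    used = rep(c(TRUE, FALSE, FALSE, FALSE), n_sets),
    FB = runif(n, 0, 100), GS = runif(n, 0, 100), BR = runif(n, 0, 100),
    VO = runif(n, 0, 100), SC = rpois(n, 20), NG = runif(n), PG = runif(n),
    TD = runif(n, 0, 300), WE = runif(n, 0, 1500))
}

# Exhaustive cell-by-cell oracles for the landscape metrics.
bf_percent <- function(cover, x, y, radius, cls) {
  k <- match(cls, cover$classes)
  hit <- 0L; tot <- 0L
  for (i in seq_len(nrow(cover$values))) for (j in seq_len(ncol(cover$values))) {
    cx <- cover$xmin + (j - 0.5) * cover$res
    cy <- cover$ymin + (i - 0.5) * cover$res
    if ((cx - x)^2 + (cy - y)^2 <= radius^2) {
      tot <- tot + 1L
      if (cover$values[i, j] == k) hit <- hit + 1L
    }
  }
  hit / tot
}

bf_edge <- function(cover, x, y, radius, woody = c("shrub", "tree")) {
  ks <- match(woody, cover$classes)
  w <- matrix(cover$values %in% ks, nrow(cover$values), ncol(cover$values))
  res <- cover$res; len <- 0
  nr <- nrow(w); nc <- ncol(w)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cx <- cover$xmin + (j - 0.5) * res
    cy <- cover$ymin + (i - 0.5) * res
    if (i < nr && w[i, j] != w[i + 1L, j]) {
      mx <- cx; my <- cover$ymin + i * res
      if ((mx - x)^2 + (my - y)^2 <= radius^2) len <- len + res
    }
    if (j < nc && w[i, j] != w[i, j + 1L]) {
      mx <- cover$xmin + j * res; my <- cy
      if ((mx - x)^2 + (my - y)^2 <= radius^2) len <- len + res
    }
  }
  len / (pi * radius^2 / 1e4)
}

bf_dist <- function(cover, x, y, cls) {
  k <- match(cls, cover$classes)
  best <- Inf
  for (i in seq_len(nrow(cover$values))) for (j in seq_len(ncol(cover$values))) {
    if (cover$values[i, j] != k) next
    cx <- cover$xmin + (j - 0.5) * cover$res
    cy <- cover$ymin + (i - 0.5) * cover$res
    lo_x <- cover$xmin + (j - 1) * cover$res; hi_x <- lo_x + cover$res
    lo_y <- cover$ymin + (i - 1) * cover$res; hi_y <- lo_y + cover$res
    if (x >= lo_x && x <= hi_x && y >= lo_y && y <= hi_y) return(0)
    best <- min(best, sqrt((cx - x)^2 + (cy - y)^2))
  }
  best
}

# random cover raster
random_cover <- function(nr, nc, seed, res = 3.6,
                         probs = c(0.6, 0.25, 0.15)) {
  set.seed(seed)
  cover_raster(matrix(sample(1:3, nr * nc, TRUE, probs), nr, nc), res = res)
}
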