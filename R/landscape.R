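# Point-buffered landscape metrics on cover rasters.
#
# Buffer membership is by cell-center-in-disc: a cell belongs to the buffer
# iff its centre lies within `radius` of the focal point. This matches common
# landscape-metric implementations and makes every metric cheap to verify by
# exhaustive enumeration.

# Validate the point/radius against the raster extent. Returns (invisibly)
# TRUE when the disc extends beyond the raster, after warning.
check_buffer <- function(r, x, y, radius) {
  if (!is.finite(x) || !is.finite(y)) stop("point coordinates must be finite")
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  xmax <- r$xmin + ncol(r$values) * r$res
  ymax <- r$ymin + nrow(r$values) * r$res
  # closest point of the extent rectangle to (x, y)
  cx <- min(max(x, r$xmin), xmax)
  cy <- min(max(y, r$ymin), ymax)
  if ((cx - x)^2 + (cy - y)^2 > radius^2)
    stop("buffer lies entirely outside the raster extent")
  partial <- (x - radius < r$xmin) || (x + radius > xmax) ||
    (y - radius < r$ymin) || (y + radius > ymax)
  if (partial)
    warning("buffer extends beyond the raster extent; metric computed over in-raster cells")
  invisible(partial)
}

# logical vector (column-major over cells): class membership for a class name
# or a caller-supplied logical mask matrix of the same shape.
class_mask <- function(cover, cls) {
  if (is.matrix(cls)) {
    if (!identical(dim(cls), dim(cover$values)))
      stop("mask dimensions do not match the raster")
    as.vector(cls)
  } else {
    k <- match(cls, cover$classes)
    if (is.na(k)) stop("unknown class: ", cls)
    as.vector(cover$values == k)
  }
}

#' Percent cover of a class within a buffer
#'
#' Fraction of raster cells whose centre falls within \code{radius} of the
#' point and whose class matches \code{cls}. Used for the proportion of e.g.
#' native grass (NG) or recently burned/grazed land (PG) within 50 m of a
#' covey's location.
#'
#' @param cover A \code{\link{cover_raster}}.
#' @param x,y Point coordinates (m, same projected system as the raster).
#' @param radius Buffer radius in m (default 50).
#' @param cls A class name, or a logical matrix mask of the raster's shape
#'   (for caller-supplied vegetation/management layers).
#' @return Proportion in [0, 1].
#' @export
percent_class_within <- function(cover, x, y, radius = 50, cls) {
  stopifnot(inherits(cover, "cover_raster"))
  check_buffer(cover, x, y, radius)
  ctr <- cell_centers(cover)
  inside <- (ctr$x - x)^2 + (ctr$y - y)^2 <= radius^2
  if (!any(inside)) stop("no cell centers inside the buffer")
  mean(class_mask(cover, cls)[inside])
}

#' Woody edge density within a buffer
#'
#' Total length (m) of boundaries between woody (shrub or tree) and non-woody
#' cells whose edge midpoints fall within the buffer disc, divided by the disc
#' area in hectares. A higher value means more interspersion of woody
#' vegetation. Only interior cell-to-cell boundaries count; the raster should
#' extend past the buffer.
#'
#' @inheritParams percent_class_within
#' @param woody_classes Classes counted as woody (default shrub and tree).
#' @return Edge density in m/ha.
#' @examples
#' m <- matrix(1L, 31, 31); m[16, 16] <- 3L  # one tree cell in open ground
#' cov <- cover_raster(m, res = 3.6)
#' edge_density_within(cov, 16 * 3.6 - 1.8, 16 * 3.6 - 1.8, 50)
#' @export
edge_density_within <- function(cover, x, y, radius = 50,
                                woody_classes = c("shrub", "tree")) {
  stopifnot(inherits(cover, "cover_raster"))
  check_buffer(cover, x, y, radius)
  woody <- woody_classes_mask(cover, woody_classes)
  res <- cover$res
  nr <- nrow(woody); nc <- ncol(woody)
  total <- 0
  # vertical neighbours (rows i, i+1 share a horizontal edge)
  if (nr > 1L) {
    diff_v <- woody[-nr, , drop = FALSE] != woody[-1L, , drop = FALSE]
    if (any(diff_v)) {
      idx <- which(diff_v, arr.ind = TRUE)
      mx <- cover$xmin + (idx[, 2L] - 0.5) * res
      my <- cover$ymin + idx[, 1L] * res   # boundary between rows i and i+1
      total <- total + res * sum((mx - x)^2 + (my - y)^2 <= radius^2)
    }
  }
  # horizontal neighbours (cols j, j+1 share a vertical edge)
  if (nc > 1L) {
    diff_h <- woody[, -nc, drop = FALSE] != woody[, -1L, drop = FALSE]
    if (any(diff_h)) {
      idx <- which(diff_h, arr.ind = TRUE)
      mx <- cover$xmin + idx[, 2L] * res
      my <- cover$ymin + (idx[, 1L] - 0.5) * res
      total <- total + res * sum((mx - x)^2 + (my - y)^2 <= radius^2)
    }
  }
  total / (pi * radius^2 / 1e4)
}

# Build a logical mask for "any of these classes".
woody_classes_mask <- function(cover, classes) {
  if (is.matrix(classes)) return(classes)
  ks <- match(classes, cover$classes)
  if (anyNA(ks)) stop("unknown class: ",
                      paste(classes[is.na(ks)], collapse = ", "))
  matrix(cover$values %in% ks, nrow(cover$values), ncol(cover$values))
}

#' Distance from a point to the nearest cell of a class
#'
#' Euclidean distance (m) from the point to the nearest cell centre of class
#' \code{cls}; 0 when the point lies inside a cell of that class. Distances
#' are point-to-cell-centre, not to polygonised cell edges, so values can
#' differ from GIS outputs by up to half a cell diagonal.
#'
#' @inheritParams percent_class_within
#' @param cls Class name (e.g. \code{"tree"} for the TD covariate).
#' @return Distance in m.
#' @export
distance_to_class <- function(cover, x, y, cls = "tree") {
  stopifnot(inherits(cover, "cover_raster"))
  if (!is.finite(x) || !is.finite(y)) stop("point coordinates must be finite")
  mask <- class_mask(cover, cls)
  if (!any(mask))
    stop("no cells of class '", cls,
         "' in the raster; widen the extent before measuring distance")
  # containing cell, if the point is on the raster
  j <- floor((x - cover$xmin) / cover$res) + 1
  i <- floor((y - cover$ymin) / cover$res) + 1
  if (i >= 1 && i <= nrow(cover$values) && j >= 1 && j <= ncol(cover$values)) {
    k <- if (is.matrix(cls)) cls[i, j] else
      cover$classes[cover$values[i, j]] %in% cls
    if (isTRUE(k)) return(0)
  }
  ctr <- cell_centers(cover)
  sqrt(min((ctr$x[mask] - x)^2 + (ctr$y[mask] - y)^2))
}

#' Landscape covariates for a table of points
#'
#' Convenience wrapper computing, for each point, the percent cover of every
#' raster class within the buffer, woody edge density (WE, m/ha) and distance
#' to the nearest tree (TD, m). Additional caller-supplied logical masks (e.g.
#' native grass or recently managed land) are reported as percent covers under
#' their list names.
#'
#' @param cover A \code{\link{cover_raster}} with classes open/shrub/tree.
#' @param points Data frame with columns \code{id}, \code{x}, \code{y}.
#' @param radius Buffer radius in m (default 50).
#' @param masks Optional named list of logical matrices (raster shape).
#' @return Data frame: one row per point with percent covers, WE and TD.
#' @export
landscape_covariates <- function(cover, points, radius = 50, masks = NULL) {
  stopifnot(inherits(cover, "cover_raster"),
            all(c("x", "y") %in% names(points)))
  out <- data.frame(id = if ("id" %in% names(points)) points$id
                    else seq_len(nrow(points)))
  for (cl in cover$classes)
    out[[paste0("pct_", cl)]] <- mapply(function(x, y)
      percent_class_within(cover, x, y, radius, cl), points$x, points$y)
  for (nm in names(masks))
    out[[nm]] <- mapply(function(x, y)
      percent_class_within(cover, x, y, radius, masks[[nm]]),
      points$x, points$y)
  out$WE <- mapply(function(x, y)
    edge_density_within(cover, x, y, radius), points$x, points$y)
  out$TD <- mapply(function(x, y)
    distance_to_class(cover, x, y, "tree"), points$x, points$y)
  out
}
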