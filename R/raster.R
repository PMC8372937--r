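#' Vegetation-height raster
#'
#' A minimal in-memory raster of vegetation heights on a regular planar grid
#' (projected coordinates in metres). Row 1 of the value matrix is the
#' southernmost (lowest-y) row; column 1 is the westernmost column. The centre
#' of cell \code{[i, j]} is at \code{(xmin + (j - 0.5) * res,
#' ymin + (i - 0.5) * res)}.
#'
#' @param values Numeric matrix of vegetation heights in metres. All values
#'   must be finite and non-negative.
#' @param xmin,ymin Coordinates (m) of the lower-left corner of the grid.
#' @param res Cell size in metres (default 3.6, typical of height models
#'   derived from airborne LiDAR).
#' @return An object of class \code{height_raster}.
#' @examples
#' r <- height_raster(matrix(runif(100, 0, 20), 10, 10))
#' r
#' @export
height_raster <- function(values, xmin = 0, ymin = 0, res = 3.6) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("height values must be numeric")
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "non-finite or negative height at cell [%d, %d] (%d offending cell%s)",
      ij[1L], ij[2L], length(bad), if (length(bad) > 1L) "s" else ""))
  }
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0)
    stop("res must be a single positive number")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         res = as.numeric(res)),
    class = "height_raster")
}

#' Categorical cover raster
#'
#' Shares the grid of its source \code{\link{height_raster}}; each cell holds
#' exactly one cover class. Usually produced by \code{\link{classify_heights}},
#' but can be built directly, e.g. for caller-supplied vegetation-type or
#' management layers.
#'
#' @param values Integer matrix of class codes, or a character matrix of class
#'   names.
#' @param classes Character vector naming the classes; code \code{k} in
#'   \code{values} means \code{classes[k]}.
#' @param xmin,ymin,res Grid geometry, as in \code{\link{height_raster}}.
#' @return An object of class \code{cover_raster}.
#' @export
cover_raster <- function(values, classes = c("open", "shrub", "tree"),
                         xmin = 0, ymin = 0, res = 3.6) {
  values <- as.matrix(values)
  if (is.character(values)) {
    codes <- match(values, classes)
    if (anyNA(codes)) stop("class name not in 'classes': ",
                           paste(unique(values[is.na(codes)]), collapse = ", "))
    values <- matrix(codes, nrow(values), ncol(values))
  }
  storage.mode(values) <- "integer"
  if (anyNA(values) || any(values < 1L) || any(values > length(classes)))
    stop("every cell must carry exactly one class code in 1..",
         length(classes))
  structure(
    list(values = values, classes = classes, xmin = as.numeric(xmin),
         ymin = as.numeric(ymin), res = as.numeric(res)),
    class = "cover_raster")
}

#' @export
print.height_raster <- function(x, ...) {
  cat(sprintf("height_raster: %d x %d cells, %.1f m resolution\n",
              nrow(x$values), ncol(x$values), x$res))
  cat(sprintf("  extent: x [%.1f, %.1f], y [%.1f, %.1f] m\n",
              x$xmin, x$xmin + ncol(x$values) * x$res,
              x$ymin, x$ymin + nrow(x$values) * x$res))
  cat(sprintf("  heights: %.2f to %.2f m\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.cover_raster <- function(x, ...) {
  cat(sprintf("cover_raster: %d x %d cells, %.1f m resolution\n",
              nrow(x$values), ncol(x$values), x$res))
  tab <- tabulate(x$values, nbins = length(x$classes))
  cat("  classes:",
      paste(sprintf("%s (%d)", x$classes, tab), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a height raster into open / shrub / tree cover
#'
#' Thresholds vegetation height into cover classes: heights in
#' \code{shrub_range} become shrub, heights in \code{tree_range} become tree,
#' everything else (including heights above the tree ceiling) is open. The
#' shrub interval is half-open at its upper bound and the tree interval closed,
#' so the shared 3.5 m boundary belongs to the tree class and no cell is ever
#' both.
#'
#' @param raster A \code{\link{height_raster}}.
#' @param shrub_range Numeric length-2, shrub heights \code{[lo, hi)} in m.
#' @param tree_range Numeric length-2, tree heights \code{[lo, hi]} in m.
#' @return A \code{\link{cover_raster}} with classes open/shrub/tree.
#' @examples
#' r <- height_raster(matrix(c(0.3, 2, 10, 50), 2, 2))
#' classify_heights(r)$classes
#' @export
classify_heights <- function(raster, shrub_range = c(0.7, 3.5),
                             tree_range = c(3.5, 40)) {
  stopifnot(inherits(raster, "height_raster"))
  if (length(shrub_range) != 2L || length(tree_range) != 2L ||
      shrub_range[1L] >= shrub_range[2L] || tree_range[1L] >= tree_range[2L])
    stop("shrub_range and tree_range must each be increasing length-2 intervals")
  if (shrub_range[2L] > tree_range[1L] && tree_range[2L] > shrub_range[1L] &&
      shrub_range[2L] != tree_range[1L] && tree_range[2L] != shrub_range[1L])
    stop("shrub_range and tree_range overlap")
  h <- raster$values
  cls <- matrix(1L, nrow(h), ncol(h))                      # open
  cls[h >= shrub_range[1L] & h < shrub_range[2L]] <- 2L    # shrub [lo, hi)
  cls[h >= tree_range[1L] & h <= tree_range[2L]] <- 3L     # tree  [lo, hi]
  cover_raster(cls, classes = c("open", "shrub", "tree"),
               xmin = raster$xmin, ymin = raster$ymin, res = raster$res)
}

# x/y coordinates of all cell centers, as ncell-length vectors matching
# as.vector(values) (column-major).
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xmin + (rep(seq_len(nc), each = nr) - 0.5) * r$res,
       y = r$ymin + (rep(seq_len(nr), times = nc) - 0.5) * r$res)
}

#' Read / write a raster as an Esri ASCII grid
#'
#' Plain-text exchange format for single-band rasters (header lines
#' \code{ncols}, \code{nrows}, \code{xllcorner}, \code{yllcorner},
#' \code{cellsize}, then rows of values from north to south). Height rasters
#' round-trip through \code{read_ascii_grid(..., type = "height")}; categorical
#' cover rasters store their integer class codes and need the class names
#' re-supplied on read.
#'
#' @param file Path to the ASCII grid.
#' @param type \code{"height"} or \code{"cover"}.
#' @param classes Class names for \code{type = "cover"}.
#' @return A \code{height_raster} or \code{cover_raster}.
#' @export
read_ascii_grid <- function(file, type = c("height", "cover"),
                            classes = c("open", "shrub", "tree")) {
  type <- match.arg(type)
  lines <- readLines(file)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid: value count does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1L, , drop = FALSE]  # file is north-to-south; internal row 1 is south
  if (type == "height")
    height_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
                  res = hdr$cellsize)
  else
    cover_raster(m, classes = classes, xmin = hdr$xllcorner,
                 ymin = hdr$yllcorner, res = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param raster A \code{height_raster} or \code{cover_raster} to write.
#' @export
write_ascii_grid <- function(raster, file) {
  v <- raster$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", raster$xmin),
           sprintf("yllcorner %.10g", raster$ymin),
           sprintf("cellsize %.10g", raster$res))
  body <- apply(v[nrow(v):1L, , drop = FALSE], 1L, paste, collapse = " ")
  writeLines(c(hdr, body), file)
  invisible(file)
}
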