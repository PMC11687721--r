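# Inverse-distance-weighted occupancy surface on a regular planar grid,
# serialized as an ESRI ASCII raster.

#' Construct an occupancy surface object
#'
#' A regular planar grid in the ESRI ASCII convention: `values` is an
#' `n_rows x n_cols` matrix stored top row first (northernmost); the grid
#' origin is the lower-left corner.
#'
#' @param values Numeric matrix, top row first; `NA` marks NODATA cells.
#' @param xll,yll Lower-left corner coordinates (m).
#' @param cellsize Cell edge length (m).
#' @return Object of class `occupancy_surface`.
#' @export
occupancy_surface <- function(values, xll, yll, cellsize) {
  structure(list(values = as.matrix(values), xll = xll, yll = yll,
                 cellsize = cellsize,
                 n_rows = nrow(values), n_cols = ncol(values)),
            class = "occupancy_surface")
}

#' @export
print.occupancy_surface <- function(x, ...) {
  cat("occupancy_surface:", x$n_rows, "x", x$n_cols, "cells of",
      x$cellsize, "m; origin (", x$xll, ",", x$yll, ")\n")
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat("value range:", round(min(v), 4), "-",
                     round(max(v), 4), "\n")
  invisible(x)
}

# Cell-center coordinates of a surface grid, row-major from the top row.
.surface_centers <- function(xll, yll, cellsize, n_rows, n_cols) {
  cx <- xll + (seq_len(n_cols) - 0.5) * cellsize
  cy <- yll + (n_rows - seq_len(n_rows) + 0.5) * cellsize
  list(x = rep(cx, times = n_rows), y = rep(cy, each = n_cols))
}

#' Inverse distance weighting interpolation
#'
#' Each grid cell takes the weighted average of the sample values with
#' weights `d^(-power)`: nearby points dominate, and a cell whose centre
#' coincides with a sample point (distance < 1e-9 m) takes that point's
#' value exactly. Weights are computed on distances normalized by the
#' nearest distance per cell, so large powers (nearest-neighbour limit) stay
#' numerically stable.
#'
#' @param points Data frame with `x`, `y`, `value` (values in \[0, 1\] for
#'   occupancy surfaces).
#' @param cellsize Grid cell size in metres; ignored if `n_cols` is given.
#' @param margin Margin added around the points' bounding box (m).
#' @param power IDW power (> 0); default 2, the conventional choice.
#' @param max_points If set, only the `max_points` nearest samples
#'   contribute to each cell.
#' @param n_cols Optional: fix the number of columns instead of `cellsize`.
#' @return An [occupancy_surface()].
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 1000), y = c(0, 0), value = c(0.2, 0.8))
#' s <- idw_interpolate(pts, cellsize = 250)
idw_interpolate <- function(points, cellsize = NULL, margin = 0,
                            power = 2, max_points = NULL, n_cols = 100) {
  if (!nrow(points)) stop2("need at least one sample point")
  if (power <= 0) stop2("power must be positive")
  xr <- range(points$x) + c(-margin, margin)
  yr <- range(points$y) + c(-margin, margin)
  if (is.null(cellsize))
    cellsize <- max(diff(xr) / n_cols, diff(yr) / n_cols,
                    .Machine$double.eps)
  nc <- max(1L, ceiling(diff(xr) / cellsize))
  nr <- max(1L, ceiling(diff(yr) / cellsize))
  ctr <- .surface_centers(xr[1], yr[1], cellsize, nr, nc)
  vals <- idw_at(points, ctr$x, ctr$y, power = power,
                 max_points = max_points)
  occupancy_surface(matrix(vals, nr, nc, byrow = TRUE),
                    xll = xr[1], yll = yr[1], cellsize = cellsize)
}

#' Evaluate IDW at arbitrary locations
#'
#' The interpolator behind [idw_interpolate()], exposed for point-wise
#' evaluation.
#'
#' @inheritParams idw_interpolate
#' @param x,y Coordinates of the evaluation locations.
#' @return Numeric vector of interpolated values.
#' @export
idw_at <- function(points, x, y, power = 2, max_points = NULL) {
  if (!nrow(points)) stop2("need at least one sample point")
  if (power <= 0) stop2("power must be positive")
  px <- points$x; py <- points$y; pv <- points$value
  k <- if (is.null(max_points)) length(pv) else min(max_points, length(pv))
  vals <- numeric(length(x))
  for (i in seq_along(x)) {
    d <- sqrt((px - x[i])^2 + (py - y[i])^2)
    if (k < length(pv)) {
      keep <- order(d)[seq_len(k)]
      dd <- d[keep]; v <- pv[keep]
    } else { dd <- d; v <- pv }
    hit <- dd < 1e-9
    if (any(hit)) { vals[i] <- v[which(hit)[1]]; next }
    w <- (dd / min(dd))^(-power)   # normalized: max weight is 1
    vals[i] <- sum(w * v) / sum(w)
  }
  vals
}

#' Write / read an ESRI ASCII grid
#'
#' Standard `.asc` layout: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' top-to-bottom. Values are printed with 17 significant digits so a
#' write-read cycle is bit-exact; `NA` cells are serialized as the NODATA
#' sentinel and restored as `NA`.
#'
#' @param surface An [occupancy_surface()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata NODATA sentinel value.
#' @export
write_surface <- function(surface, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", surface$n_cols),
               paste("nrows", surface$n_rows),
               paste("xllcorner", sprintf("%.17g", surface$xll)),
               paste("yllcorner", sprintf("%.17g", surface$yll)),
               paste("cellsize", sprintf("%.17g", surface$cellsize)),
               paste("NODATA_value", nodata)), con)
  v <- surface$values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, character(1), 1)
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  h <- setNames(vals, keys)
  nc <- as.integer(h["ncols"]); nr <- as.integer(h["nrows"])
  body <- lapply(lines[6 + seq_len(nr)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  m[m == h["nodata_value"]] <- NA
  occupancy_surface(m, xll = unname(h["xllcorner"]),
                    yll = unname(h["yllcorner"]),
                    cellsize = unname(h["cellsize"]))
}
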