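# Minimal single-band planar raster container. Values are stored as a matrix
# with row 1 at the top (north-up); cell values refer to cell centers and
# coordinates are planar meters. NA is the nodata value.

#' Create a grid layer
#'
#' A `grid_layer` is the package's raster container: a numeric matrix plus an
#' origin (lower-left corner), a square cell size in meters, and NA as nodata.
#' Row 1 of the matrix is the northernmost row.
#'
#' @param values numeric matrix (row 1 = top/north)
#' @param xmin,ymin planar coordinates of the lower-left corner, meters
#' @param cellsize cell edge length, meters (> 0)
#' @param name optional layer name
#' @return an object of class `grid_layer`
#' @export
grid_layer <- function(values, xmin = 0, ymin = 0, cellsize = 1, name = NULL) {
  if (!is.matrix(values)) stop2("grid_layer: `values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0) {
    stop2("grid_layer: configuration error, cellsize must be a positive scalar")
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize,
         name = name),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_layer%s> %d x %d cells of %g m, origin (%g, %g)\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

gl_nrow <- function(g) nrow(g$values)
gl_ncol <- function(g) ncol(g$values)
gl_xmax <- function(g) g$xmin + gl_ncol(g) * g$cellsize
gl_ymax <- function(g) g$ymin + gl_nrow(g) * g$cellsize

#' Cell center coordinates of a grid layer
#'
#' @param g a `grid_layer`
#' @return `gl_xcenters`/`gl_ycenters` give center coordinates (y descending,
#'   matching matrix row order); `gl_centers` a 2-column matrix over all cells
#'   in column-major matrix order.
#' @export
gl_xcenters <- function(g) g$xmin + (seq_len(gl_ncol(g)) - 0.5) * g$cellsize

#' @rdname gl_xcenters
#' @export
gl_ycenters <- function(g) gl_ymax(g) - (seq_len(gl_nrow(g)) - 0.5) * g$cellsize

#' @rdname gl_xcenters
#' @export
gl_centers <- function(g) {
  xs <- gl_xcenters(g); ys <- gl_ycenters(g)
  cbind(x = rep(xs, each = gl_nrow(g)), y = rep(ys, times = gl_ncol(g)))
}

#' Do two grid layers share the same grid?
#' @param a,b `grid_layer` objects
#' @param tol coordinate tolerance, meters
#' @return logical
#' @export
gl_same_grid <- function(a, b, tol = 1e-6) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Look up grid values at point coordinates
#'
#' Returns the value of the cell containing each point (NA outside the extent).
#' Points exactly on the right/top edge are assigned to the last cell.
#'
#' @param g a `grid_layer`
#' @param x,y point coordinates, meters
#' @return numeric vector of cell values
#' @export
gl_extract <- function(g, x, y) {
  cs <- g$cellsize
  col <- floor((x - g$xmin) / cs) + 1L
  row <- floor((gl_ymax(g) - y) / cs) + 1L
  col[x == gl_xmax(g)] <- gl_ncol(g)
  row[y == g$ymin] <- gl_nrow(g)
  ok <- !is.na(col) & !is.na(row) &
    col >= 1L & col <= gl_ncol(g) & row >= 1L & row <= gl_nrow(g)
  out <- rep(NA_real_, length(x))
  out[ok] <- g$values[cbind(row[ok], col[ok])]
  out
}

#' Nearest-neighbor resampling to a coarser grain
#'
#' Builds a grid at `coarse_cell` resolution covering the same extent (anchored
#' at the top-left corner); each coarse cell takes the value of the fine cell
#' whose center is nearest the coarse cell center. Equidistant ties are broken
#' toward the lower (first, row-major) index.
#'
#' @param g fine `grid_layer`
#' @param coarse_cell target cell size, meters
#' @return a coarse `grid_layer`
#' @export
resample_to_grain <- function(g, coarse_cell) {
  if (coarse_cell <= 0) stop2("resample_to_grain: coarse_cell must be positive")
  cs <- g$cellsize
  width <- gl_ncol(g) * cs
  height <- gl_nrow(g) * cs
  ncc <- max(1L, round(width / coarse_cell))
  nrc <- max(1L, round(height / coarse_cell))
  ymax <- gl_ymax(g)
  xc <- g$xmin + (seq_len(ncc) - 0.5) * coarse_cell
  yc <- ymax - (seq_len(nrc) - 0.5) * coarse_cell
  # nearest fine center; ceiling() realizes the tie-toward-lower-index rule
  j <- pmin(pmax(ceiling((xc - g$xmin) / cs), 1L), gl_ncol(g))
  i <- pmin(pmax(ceiling((ymax - yc) / cs), 1L), gl_nrow(g))
  grid_layer(g$values[i, j, drop = FALSE],
             xmin = g$xmin, ymin = ymax - nrc * coarse_cell,
             cellsize = coarse_cell, name = g$name)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange (`.asc`): a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from north to
#' south, which matches the internal matrix layout.
#'
#' @param g a `grid_layer`
#' @param path file path
#' @param digits significant digits written (full precision by default)
#' @return `write_asc` returns `path` invisibly; `read_asc` a `grid_layer`.
#' @export
write_asc <- function(g, path, digits = 15) {
  v <- g$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    "NODATA_value -9999"
  ), con)
  vv <- v
  vv[is.na(vv)] <- -9999
  writeLines(apply(signif(vv, digits), 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- utils::read.table(path, skip = 6)
  v <- as.matrix(body)
  dimnames(v) <- NULL
  v[v == h[["nodata_value"]]] <- NA_real_
  grid_layer(v, xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
             cellsize = h[["cellsize"]])
}
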