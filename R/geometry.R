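# Planar vector geometry primitives: point-in-polygon, polygon scanline
# rasterization, and exact segment-circle clipping. All coordinates in meters.

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates
#' @param poly 2-column matrix of polygon vertices (closed implicitly)
#' @return logical vector, TRUE for points inside
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

# Rasterize the union of polygons onto a template grid: TRUE where the cell
# center falls inside any polygon (even-odd rule), by horizontal scanlines.
rasterize_polygons <- function(polys, template) {
  nr <- gl_nrow(template); nc <- gl_ncol(template)
  xs <- gl_xcenters(template)
  ys <- gl_ycenters(template)
  out <- matrix(FALSE, nr, nc)
  for (poly in polys) {
    bb <- apply(poly, 2, range)
    rows <- which(ys >= bb[1, 2] & ys <= bb[2, 2])
    for (r in rows) {
      y <- ys[r]
      xv <- poly[, 1]; yv <- poly[, 2]
      xs2 <- c(xv[-1], xv[1]); ys2 <- c(yv[-1], yv[1])
      cr <- (yv > y) != (ys2 > y)
      if (!any(cr)) next
      xint <- sort(xv[cr] + (y - yv[cr]) * (xs2[cr] - xv[cr]) / (ys2[cr] - yv[cr]))
      # fill between successive pairs of crossings
      for (k in seq(1, length(xint) - 1, by = 2)) {
        out[r, xs > xint[k] & xs < xint[k + 1]] <- TRUE
      }
    }
  }
  out
}

# Length of the part of segment p1-p2 lying inside circles of radius r
# centered at `centers` (n x 2). Returns a vector of lengths, one per center.
seg_circle_len <- function(p1, p2, centers, r) {
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  if (L == 0) return(rep(0, nrow(centers)))
  u <- d / L
  fx <- p1[1] - centers[, 1]
  fy <- p1[2] - centers[, 2]
  b <- fx * u[1] + fy * u[2]          # signed projection of center->p1 on u
  c0 <- fx^2 + fy^2 - r^2
  disc <- b^2 - c0
  len <- numeric(nrow(centers))
  hit <- disc > 0
  if (any(hit)) {
    s <- sqrt(disc[hit])
    t1 <- -b[hit] - s
    t2 <- -b[hit] + s
    len[hit] <- pmax(0, pmin(L, t2) - pmax(0, t1))
  }
  len
}
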