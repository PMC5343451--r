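#' Planar polygon ring
#'
#' A simple planar polygon given as a ring of vertices (km). Used for the
#' species' native range and for the buffer ring from which background
#' (pseudo-absence) locations are drawn. The ring may be supplied open or
#' closed; it is stored open (last vertex != first).
#'
#' @param xy two-column numeric matrix (or data frame) of vertices.
#' @return Object of class `planar_polygon`.
#' @export
planar_polygon <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 3 || !all(is.finite(xy))) {
    stop("geometry error: polygon needs >= 3 finite (x, y) vertices",
         call. = FALSE)
  }
  if (all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12)) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 3) {
    stop("geometry error: degenerate polygon", call. = FALSE)
  }
  colnames(xy) <- c("x", "y")
  structure(list(xy = xy), class = "planar_polygon")
}

#' Read a polygon from a delimited text file
#'
#' Expects a header line and columns `x`, `y` (km); the ring may be open or
#' closed.
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [planar_polygon()].
#' @export
read_polygon <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  planar_polygon(d[, c("x", "y")])
}

#' Polygon area (shoelace formula)
#'
#' @param poly a [planar_polygon()].
#' @return Area in km^2 (always positive).
#' @export
polygon_area <- function(poly) {
  p <- poly$xy
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

polygon_perimeter <- function(poly) {
  p <- poly$xy
  j <- c(2:nrow(p), 1)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}

polygon_is_convex <- function(poly) {
  p <- poly$xy
  n <- nrow(p)
  i <- seq_len(n); j <- c(2:n, 1); k <- c(3:n, 1, 2)
  cross <- (p[j, 1] - p[i, 1]) * (p[k, 2] - p[j, 2]) -
           (p[j, 2] - p[i, 2]) * (p[k, 1] - p[j, 1])
  all(cross >= -1e-9) || all(cross <= 1e-9)
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param poly a [planar_polygon()].
#' @param x,y planar coordinates (km), vectorised.
#' @return Logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(poly, x, y) {
  p <- poly$xy
  n <- nrow(p)
  inside <- logical(length(x))
  for (q in seq_along(x)) {
    px <- x[q]; py <- y[q]
    ins <- FALSE
    jv <- n
    for (iv in seq_len(n)) {
      xi <- p[iv, 1]; yi <- p[iv, 2]; xj <- p[jv, 1]; yj <- p[jv, 2]
      if ((yi > py) != (yj > py)) {
        xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
        if (px < xint) ins <- !ins
        if (abs(px - xint) < 1e-12) { ins <- TRUE; break }
      }
      jv <- iv
    }
    inside[q] <- ins
  }
  inside
}

# Distance from points to the polygon boundary (min over edge segments).
dist_to_boundary <- function(poly, x, y) {
  p <- poly$xy
  n <- nrow(p)
  j <- c(2:n, 1)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- p[j, 1]; by <- p[j, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  out <- numeric(length(x))
  for (q in seq_along(x)) {
    t <- ((x[q] - ax) * dx + (y[q] - ay) * dy) / len2
    t <- pmin(1, pmax(0, t))
    out[q] <- sqrt(min((x[q] - (ax + t * dx))^2 + (y[q] - (ay + t * dy))^2))
  }
  out
}

#' Distance from points to a polygon region
#'
#' Zero for points inside (or on) the polygon, else the Euclidean distance to
#' the nearest boundary point. This is the planar stand-in the buffer ring is
#' defined on.
#'
#' @param poly a [planar_polygon()].
#' @param x,y planar coordinates (km), vectorised.
#' @return Numeric vector of distances (km).
#' @export
dist_to_polygon <- function(poly, x, y) {
  d <- dist_to_boundary(poly, x, y)
  d[point_in_polygon(poly, x, y)] <- 0
  d
}

#' Buffer-ring membership
#'
#' A point belongs to the ring if it lies outside the polygon at a distance
#' between `inner_km` and `outer_km` (inclusive) from the polygon.
#'
#' @param poly a [planar_polygon()].
#' @param x,y planar coordinates (km), vectorised.
#' @param inner_km,outer_km ring bounds, `0 < inner < outer`.
#' @return Logical vector.
#' @export
in_buffer_ring <- function(poly, x, y, inner_km, outer_km) {
  d <- dist_to_polygon(poly, x, y)
  d >= inner_km & d <= outer_km & !point_in_polygon(poly, x, y)
}

#' Area of the buffer ring around a polygon
#'
#' For a convex polygon the Minkowski (Steiner) formula is exact:
#' `area(dilate(P, r)) = A + P*r + pi*r^2`, so the ring area is
#' `P*(outer - inner) + pi*(outer^2 - inner^2)`. For non-convex polygons the
#' ring area is integrated numerically on a fine grid of the membership
#' predicate.
#'
#' @param poly a [planar_polygon()].
#' @param inner_km,outer_km ring bounds, `0 < inner < outer`.
#' @param n_grid grid resolution per axis for the numerical fallback.
#' @return Ring area in km^2.
#' @export
ring_area <- function(poly, inner_km, outer_km, n_grid = 400) {
  if (!(inner_km > 0 && outer_km > inner_km)) {
    stop("argument error: need 0 < inner_km < outer_km", call. = FALSE)
  }
  if (polygon_is_convex(poly)) {
    per <- polygon_perimeter(poly)
    return(per * (outer_km - inner_km) + pi * (outer_km^2 - inner_km^2))
  }
  bb <- apply(poly$xy, 2, range)
  xs <- seq(bb[1, 1] - outer_km, bb[2, 1] + outer_km, length.out = n_grid)
  ys <- seq(bb[1, 2] - outer_km, bb[2, 2] + outer_km, length.out = n_grid)
  cellA <- diff(xs[1:2]) * diff(ys[1:2])
  g <- expand.grid(x = xs, y = ys)
  sum(in_buffer_ring(poly, g$x, g$y, inner_km, outer_km)) * cellA
}
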