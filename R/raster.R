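#' Regular planar raster grid
#'
#' Lightweight container for a regular, north-up planar grid of real values:
#' the unit of every covariate and density surface in the package. Values are
#' stored as a numeric matrix with rows running north to south (row 1 is the
#' northern edge, matching the ESRI ASCII grid convention); coordinates are
#' planar kilometres.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll coordinates (km) of the lower-left corner of the grid.
#' @param cellsize cell edge length in km (cells are square).
#' @param nodata value written to file for missing cells; internally missing
#'   cells are `NA`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cellsize) || cellsize <= 0) {
    stop("config error: cellsize must be a positive number", call. = FALSE)
  }
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols, cellsize %g km\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] km\n",
              x$xll, x$xll + ncol(v) * x$cellsize,
              x$yll, x$yll + nrow(v) * x$cellsize))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d NA)\n",
                min(fin), mean(fin), max(fin), sum(is.na(v))))
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stopifnot_same_geometry <- function(grids) {
  ref <- grids[[1]]
  for (g in grids) {
    if (!grid_same_geometry(ref, g)) {
      stop("geometry error: covariate grids do not share one extent/cell size",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' @param grid a [raster_grid()].
#' @return List with vectors `x` (per column) and `y` (per row, row 1 first,
#'   i.e. northernmost).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  list(
    x = grid$xll + (seq_len(nc) - 0.5) * cs,
    y = grid$yll + (nr - seq_len(nr) + 0.5) * cs
  )
}

# Map planar coordinates to (row, col); points outside the extent get NA.
cell_index <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  col <- floor((x - grid$xll) / cs) + 1L
  row <- nr - floor((y - grid$yll) / cs)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read a value at planar coordinates
#'
#' @param grid a [raster_grid()].
#' @param x,y planar coordinates (km), vectorised.
#' @return Numeric vector of cell values; an error if any point falls outside
#'   the grid extent.
#' @export
grid_value_at <- function(grid, x, y) {
  idx <- cell_index(grid, x, y)
  if (anyNA(idx$row)) {
    stop("geometry error: point(s) outside the grid extent", call. = FALSE)
  }
  grid$values[cbind(idx$row, idx$col)]
}

#' Read an ESRI ASCII grid (.asc)
#'
#' Parses the standard six-line header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by row-major values, north row first.
#'
#' @param path file path.
#' @return A [raster_grid()]; NODATA cells become `NA`.
#' @export
read_asc <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- readLines(con, n = 1L)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  }
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ESRI ASCII body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @param digits significant digits for the body.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, digits = 8) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(v, 1L, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Offsets (di, dj) of cells whose centres lie within `radius` of a cell
# centre; distance inclusive (<=), so radius < cellsize gives the singleton.
disc_offsets <- function(radius, cellsize) {
  r_cells <- floor(radius / cellsize + 1e-9)
  span <- -r_cells:r_cells
  off <- expand.grid(di = span, dj = span)
  keep <- (off$di^2 + off$dj^2) * cellsize^2 <= radius^2 + 1e-9
  off[keep, , drop = FALSE]
}

#' Moving-window (focal) mean of a raster
#'
#' Each output cell holds the mean of all input cells whose centres lie within
#' `radius_km` of that cell's centre (distance inclusive). Missing cells are
#' excluded from the mean; a cell whose whole neighbourhood is missing (or
#' that falls outside the grid) becomes `NA`. Neighbourhoods are truncated at
#' the grid edge rather than wrapped.
#'
#' @param grid a [raster_grid()].
#' @param radius_km neighbourhood radius in km; `radius_km < cellsize`
#'   returns the input unchanged (singleton neighbourhood).
#' @return A [raster_grid()] with the same geometry.
#' @export
focal_mean <- function(grid, radius_km) {
  if (!is.finite(radius_km) || radius_km < 0) {
    stop("argument error: radius must be >= 0", call. = FALSE)
  }
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  off <- disc_offsets(radius_km, grid$cellsize)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    src_r <- max(1, 1 - di):min(nr, nr - di)
    src_c <- max(1, 1 - dj):min(nc, nc - dj)
    dst_r <- src_r + di; dst_c <- src_c + dj
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + v0[src_r, src_c]
    cnt[dst_r, dst_c] <- cnt[dst_r, dst_c] + ok[src_r, src_c]
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  raster_grid(out, xll = grid$xll, yll = grid$yll,
              cellsize = grid$cellsize, nodata = grid$nodata)
}
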