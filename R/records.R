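#' Average repeated density estimates per site
#'
#' Study areas with more than one density estimate (several seasons or
#' years) are collapsed to a single record whose density is the arithmetic
#' mean of the group. Coordinates, island flag and region must agree within
#' a site group; conflicting island flags are a data error. The operation is
#' idempotent.
#'
#' @param records data frame of density records with a `site_key` column
#'   grouping repeated estimates.
#' @return A data frame with one record per `site_key`, in order of first
#'   appearance.
#' @export
aggregate_records <- function(records) {
  if (is.null(records$site_key)) {
    stop("data error: records need a site_key column", call. = FALSE)
  }
  keys <- unique(records$site_key)
  out <- lapply(keys, function(k) {
    g <- records[records$site_key == k, , drop = FALSE]
    if (length(unique(g$is_island)) != 1) {
      stop("data error: conflicting island flags within site_key '", k, "'",
           call. = FALSE)
    }
    if (length(unique(g$region)) != 1) {
      stop("data error: conflicting region tags within site_key '", k, "'",
           call. = FALSE)
    }
    if (max(g$x) - min(g$x) > 1e-6 || max(g$y) - min(g$y) > 1e-6) {
      stop("data error: conflicting coordinates within site_key '", k, "'",
           call. = FALSE)
    }
    r <- g[1, , drop = FALSE]
    r$density <- mean(g$density)
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch comparison of island and mainland density
#'
#' Two-sample t-test with unequal variances (Welch–Satterthwaite degrees of
#' freedom) comparing island against mainland density records. Background
#' (zero-density pseudo-absence) records are excluded. Optionally the test
#' is run on natural-log densities, in which case zero densities are a
#' domain error.
#'
#' @param records data frame of density records.
#' @param log_scale compare `log(density)` instead of raw density.
#' @return A list of class `welch_result`: `t`, `df`, `p`, per-group `mean`,
#'   `se` and `n` (island first).
#' @export
compare_island_mainland <- function(records, log_scale = FALSE) {
  records <- records[records$region != "background", , drop = FALSE]
  isl <- records$density[records$is_island]
  mld <- records$density[!records$is_island]
  if (length(isl) < 2 || length(mld) < 2) {
    stop("insufficient-data error: both groups need >= 2 records",
         call. = FALSE)
  }
  if (log_scale) {
    if (any(isl <= 0) || any(mld <= 0)) {
      stop("domain error: zero or negative density cannot be log-transformed",
           call. = FALSE)
    }
    isl <- log(isl); mld <- log(mld)
  }
  tt <- stats::t.test(isl, mld, var.equal = FALSE)
  structure(list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    mean = c(island = mean(isl), mainland = mean(mld)),
    se = c(island = stats::sd(isl) / sqrt(length(isl)),
           mainland = stats::sd(mld) / sqrt(length(mld))),
    n = c(island = length(isl), mainland = length(mld)),
    log_scale = log_scale
  ), class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test (%s scale)\n",
              if (x$log_scale) "log" else "raw"))
  cat(sprintf("  island:   mean %.3f (se %.3f), n = %d\n",
              x$mean[1], x$se[1], x$n[1]))
  cat(sprintf("  mainland: mean %.3f (se %.3f), n = %d\n",
              x$mean[2], x$se[2], x$n[2]))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Welch t-statistic from group summaries
#'
#' `t = (m1 - m2) / sqrt(se1^2 + se2^2)`; when group sizes are supplied the
#' Welch–Satterthwaite degrees of freedom are returned as well. Useful for
#' checking a published comparison from its printed means and standard
#' errors.
#'
#' @param mean1,se1,n1 first group: mean, standard error of the mean, size.
#' @param mean2,se2,n2 second group.
#' @return List with `t` and (if `n1`, `n2` given) `df`.
#' @export
welch_from_summary <- function(mean1, se1, mean2, se2, n1 = NULL, n2 = NULL) {
  stopifnot(se1 > 0 || se2 > 0)
  t <- unname((mean1 - mean2) / sqrt(se1^2 + se2^2))
  df <- NULL
  if (!is.null(n1) && !is.null(n2)) {
    df <- unname((se1^2 + se2^2)^2 /
                   (se1^4 / (n1 - 1) + se2^4 / (n2 - 1)))
  }
  list(t = t, df = df)
}

# Round half away from zero (used for the proportional background count;
# base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Sample zero-density background locations
#'
#' Three-step pseudo-absence procedure: (1) form the buffer ring between
#' `buffer_inner_km` and `buffer_outer_km` around the native-range polygon;
#' (2) compute the areas of the native range and of the ring; (3) draw a
#' uniform random sample of ring locations whose size is proportional to the
#' number of density estimates inside the native range,
#' `n = round(n_native_estimates * area(ring) / area(native))` (half rounded
#' up). Returned records carry density exactly 0 and region `"background"`.
#'
#' @param native_polygon a [planar_polygon()].
#' @param buffer_inner_km,buffer_outer_km ring bounds (km), inner < outer.
#' @param n_native_estimates number of density estimates in the native range.
#' @param seed integer seed.
#' @param n_grid resolution of the numerical ring-area integration for
#'   non-convex polygons (see [ring_area()]).
#' @param bbox optional `c(xmin, xmax, ymin, ymax)` window (km) clipping the
#'   ring, e.g. to the covariate grid extent; the proportional count then
#'   uses the clipped ring area (integrated numerically).
#' @return Data frame of background density records.
#' @export
sample_background <- function(native_polygon, buffer_inner_km = 100,
                              buffer_outer_km = 1000, n_native_estimates,
                              seed = 1L, n_grid = 400, bbox = NULL) {
  stopifnot(inherits(native_polygon, "planar_polygon"))
  if (!(buffer_inner_km > 0 && buffer_outer_km > buffer_inner_km)) {
    stop("argument error: need 0 < inner < outer buffer", call. = FALSE)
  }
  a_native <- polygon_area(native_polygon)
  if (a_native <= 0) stop("geometry error: degenerate polygon", call. = FALSE)
  if (is.null(bbox)) {
    a_ring <- ring_area(native_polygon, buffer_inner_km, buffer_outer_km,
                        n_grid = n_grid)
    bb <- apply(native_polygon$xy, 2, range)
    xlim <- bb[, 1] + c(-1, 1) * buffer_outer_km
    ylim <- bb[, 2] + c(-1, 1) * buffer_outer_km
  } else {
    xlim <- bbox[1:2]; ylim <- bbox[3:4]
    xs <- seq(xlim[1], xlim[2], length.out = n_grid)
    ys <- seq(ylim[1], ylim[2], length.out = n_grid)
    gg <- expand.grid(x = xs, y = ys)
    a_ring <- sum(in_buffer_ring(native_polygon, gg$x, gg$y,
                                 buffer_inner_km, buffer_outer_km)) *
      diff(xs[1:2]) * diff(ys[1:2])
  }
  n_bg <- round_half_up(n_native_estimates * a_ring / a_native)
  set.seed(seed)
  xs <- ys <- numeric(0)
  while (length(xs) < n_bg) {
    m <- max(4L * (n_bg - length(xs)), 64L)
    px <- stats::runif(m, xlim[1], xlim[2])
    py <- stats::runif(m, ylim[1], ylim[2])
    keep <- in_buffer_ring(native_polygon, px, py,
                           buffer_inner_km, buffer_outer_km)
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
  }
  xs <- xs[seq_len(n_bg)]; ys <- ys[seq_len(n_bg)]
  data.frame(
    id = sprintf("bg%03d", seq_len(n_bg)),
    x = xs, y = ys,
    density = 0,
    is_island = FALSE,
    region = "background",
    site_key = sprintf("bg%03d", seq_len(n_bg)),
    stringsAsFactors = FALSE
  )
}
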