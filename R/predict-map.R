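#' Model-averaged prediction map
#'
#' Applies a fitted density model to covariate rasters, producing a map of
#' potential population density. For each cell: the covariate surfaces are
#' first summarised at each covariate's chosen moving-window radius, then
#' standardised with the training centring and scale, block terms (with
#' quadratics) are formed, the model-averaged coefficients and intercept
#' give the log-scale prediction, and the back-transform
#' `exp(eta) - log_offset` (floored at zero) returns animals/km^2.
#' Missing-data cells propagate untouched.
#'
#' @param object a [mmi_fit()] result.
#' @param grids named list of [raster_grid()], one raw surface per block
#'   covariate, sharing one geometry.
#' @param apply_focal summarise each surface at its chosen radius before
#'   predicting (set `FALSE` when the grids are already focal means).
#' @param smearing apply the log-normal back-transform correction
#'   `exp(eta + sigma^2/2)` using the weighted residual variance.
#' @return A [raster_grid()] of predicted density (>= 0 where not missing).
#' @export
predict_map <- function(object, grids, apply_focal = TRUE,
                        smearing = FALSE) {
  stopifnot(inherits(object, "density_mmi"))
  blocks <- object$model_set$blocks
  need <- vapply(blocks, `[[`, "", "name")
  if (!all(need %in% names(grids))) {
    stop("configuration error: missing covariate grid(s): ",
         paste(setdiff(need, names(grids)), collapse = ", "), call. = FALSE)
  }
  stopifnot_same_geometry(grids[need])
  ref <- grids[[need[1]]]
  b <- object$averaged$coefficients
  sc <- object$design$scaling
  eta <- matrix(b[["(Intercept)"]], nrow(ref$values), ncol(ref$values))
  for (nm in need) {
    g <- grids[[nm]]
    r <- 0
    if (apply_focal && !is.null(object$design$chosen_radius)) {
      r <- object$design$chosen_radius[nm]
      if (is.na(r) || is.null(r)) r <- 0
    }
    if (r >= g$cellsize) g <- focal_mean(g, r)
    i <- match(nm, sc$column)
    z <- (g$values - sc$center[i]) / sc$scale[i]
    eta <- eta + b[[nm]] * z
    blk <- blocks[[nm]]
    if (blk$quadratic) {
      eta <- eta + b[[paste0(nm, ".q")]] * (z^2 - blk$q_center) / blk$q_scale
    }
  }
  if (smearing) eta <- eta + object$averaged$residual_sd^2 / 2
  dens <- pmax(exp(eta) - object$design$log_offset, 0)
  raster_grid(dens, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
              nodata = ref$nodata)
}

#' Classify a density map into low / moderate / high
#'
#' The map legend anchors the three classes at point densities (by default
#' 1, 6 and >= 11 animals/km^2); cells are binned by the midpoints between
#' consecutive anchors, so with the defaults: low `[0, 3.5)`, moderate
#' `[3.5, 8.5)`, high `>= 8.5` (every cell at or above the top anchor is
#' guaranteed high). Classification is monotone in density.
#'
#' @param density_grid a [raster_grid()] of density.
#' @param breaks strictly increasing anchor densities, length 3.
#' @return A [raster_grid()] of integer codes 1 = low, 2 = moderate,
#'   3 = high (attribute `labels`); missing cells stay missing.
#' @export
classify_density <- function(density_grid, breaks = c(1, 6, 11)) {
  if (length(breaks) != 3 || any(diff(breaks) <= 0)) {
    stop("argument error: breaks must be 3 strictly increasing anchors",
         call. = FALSE)
  }
  mids <- c((breaks[1] + breaks[2]) / 2, (breaks[2] + breaks[3]) / 2)
  v <- density_grid$values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[!is.na(v)] <- 1
  cls[!is.na(v) & v >= mids[1]] <- 2
  cls[!is.na(v) & (v >= mids[2] | v >= breaks[3])] <- 3
  out <- raster_grid(cls, xll = density_grid$xll, yll = density_grid$yll,
                     cellsize = density_grid$cellsize,
                     nodata = density_grid$nodata)
  attr(out, "labels") <- c("low", "moderate", "high")
  out
}
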