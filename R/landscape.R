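#' Covariate specification for the synthetic landscape
#'
#' Describes one landscape covariate: its ecological category, the spatial
#' smoothness of the synthetic surface, the value range the surface is mapped
#' into, the candidate moving-window radii at which it may be summarised, and
#' the form (linear or quadratic) its relationship with log density is
#' allowed to take.
#'
#' @param name unique covariate name.
#' @param category one of `"biotic-vegetation"`, `"biotic-predation"`,
#'   `"abiotic-climate"`.
#' @param smoothness_km spatial autocorrelation scale of the generated
#'   surface (km); larger is smoother.
#' @param range length-2 numeric, the value range of the surface.
#' @param candidate_radii_km candidate focal radii (km), subset of 10/20/40.
#' @param allow_quadratic whether a quadratic term is considered for this
#'   covariate.
#' @param expected_sign `"positive"`, `"negative"` or `"quadratic"` — the
#'   hypothesised relationship with density.
#' @param integer_valued round the surface to whole numbers (species counts).
#' @param trend shift (in latent standard deviations) applied to the
#'   surface inside the arid belt surrounding the native range (see
#'   `trend_ring_km` in [landscape_config()]); positive values push the
#'   covariate toward its upper range there. Emulates the belt of
#'   unfavourable conditions in which the zero-density background ring
#'   sits.
#' @return Object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, category, smoothness_km = 50,
                           range = c(0, 1), candidate_radii_km = 10,
                           allow_quadratic = FALSE,
                           expected_sign = c("positive", "negative",
                                             "quadratic"),
                           integer_valued = FALSE, trend = 0) {
  expected_sign <- match.arg(expected_sign)
  category <- match.arg(category, c("biotic-vegetation", "biotic-predation",
                                    "abiotic-climate"))
  stopifnot(length(range) == 2, range[1] < range[2],
            length(candidate_radii_km) >= 1, all(candidate_radii_km > 0))
  structure(list(name = name, category = category,
                 smoothness_km = smoothness_km, range = range,
                 candidate_radii_km = sort(candidate_radii_km),
                 allow_quadratic = allow_quadratic,
                 expected_sign = expected_sign,
                 integer_valued = integer_valued, trend = trend),
            class = "covariate_spec")
}

#' Default covariate roster
#'
#' The seven-variable roster retained by the global wild pig density
#' analysis after correlation pruning: potential evapotranspiration and
#' agriculture (quadratic), large-carnivore richness and unvegetated area
#' (negative), precipitation in the wettest and driest seasons (positive)
#' and forest canopy cover (positive). Vegetation variables are summarised
#' at a 10 km radius, predation and climate variables at 40 km.
#'
#' @return Named list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  specs <- list(
    covariate_spec("pet", "abiotic-climate", smoothness_km = 120,
                   range = c(300, 1800), candidate_radii_km = 40,
                   allow_quadratic = TRUE, expected_sign = "quadratic"),
    covariate_spec("carnivore_richness", "biotic-predation",
                   smoothness_km = 100, range = c(0, 6),
                   candidate_radii_km = 40, expected_sign = "negative",
                   integer_valued = TRUE),
    covariate_spec("precip_wet", "abiotic-climate", smoothness_km = 90,
                   range = c(50, 900), candidate_radii_km = 40,
                   expected_sign = "positive", trend = -1.3),
    covariate_spec("unvegetated", "biotic-vegetation", smoothness_km = 60,
                   range = c(0, 1), candidate_radii_km = 10,
                   expected_sign = "negative", trend = 1.3),
    covariate_spec("agriculture", "biotic-vegetation", smoothness_km = 60,
                   range = c(0, 1), candidate_radii_km = 10,
                   allow_quadratic = TRUE, expected_sign = "quadratic",
                   trend = -1.2),
    covariate_spec("precip_dry", "abiotic-climate", smoothness_km = 90,
                   range = c(0, 400), candidate_radii_km = 40,
                   expected_sign = "positive", trend = -1),
    covariate_spec("forest", "biotic-vegetation", smoothness_km = 70,
                   range = c(0, 100), candidate_radii_km = 10,
                   expected_sign = "positive", trend = -0.8)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Synthetic landscape configuration
#'
#' @param seed integer seed; fixes every surface and the island mask.
#' @param extent_km length-2 (width, height) in km; must be divisible by
#'   `cell_km`.
#' @param cell_km cell size in km.
#' @param covariates named list of [covariate_spec()]; defaults to
#'   [default_covariate_specs()].
#' @param island_fraction proportion of cells belonging to islands, in
#'   `[0, 0.5)`.
#' @param native_polygon a [planar_polygon()] marking the native range;
#'   defaults to a rectangle over the western third of the extent.
#' @param island_radius_km radius of each island patch.
#' @param trend_ring_km `c(inner, outer)` distances (km) from the native
#'   range bounding the arid belt inside which covariate trends apply; the
#'   defaults make the belt coincide with the background buffer ring.
#' @param trend_softness_km width (km) of the smooth edges of the belt.
#' @return Object of class `landscape_config`.
#' @export
landscape_config <- function(seed = 1L,
                             extent_km = c(3000, 3000),
                             cell_km = 30,
                             covariates = default_covariate_specs(),
                             island_fraction = 0.02,
                             native_polygon = NULL,
                             island_radius_km = NULL,
                             trend_ring_km = c(100, 1000),
                             trend_softness_km = 75) {
  if (!is.numeric(cell_km) || cell_km <= 0 || any(extent_km <= 0)) {
    stop("config error: extent and cell size must be positive", call. = FALSE)
  }
  if (any(abs(extent_km / cell_km - round(extent_km / cell_km)) > 1e-9)) {
    stop("config error: extent must be divisible by cell size", call. = FALSE)
  }
  if (island_fraction < 0 || island_fraction >= 0.5) {
    stop("config error: island_fraction must be in [0, 0.5)", call. = FALSE)
  }
  nm <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("config error: covariate names must be unique", call. = FALSE)
  }
  names(covariates) <- nm
  if (is.null(native_polygon)) {
    native_polygon <- planar_polygon(rbind(
      c(0, 0), c(extent_km[1] / 3, 0),
      c(extent_km[1] / 3, extent_km[2]), c(0, extent_km[2])
    ))
  }
  if (is.null(island_radius_km)) island_radius_km <- 2 * cell_km
  structure(list(seed = as.integer(seed), extent_km = extent_km,
                 cell_km = cell_km, covariates = covariates,
                 island_fraction = island_fraction,
                 native_polygon = native_polygon,
                 island_radius_km = island_radius_km,
                 trend_ring_km = trend_ring_km,
                 trend_softness_km = trend_softness_km),
            class = "landscape_config")
}

# Smooth an i.i.d. N(0,1) field with a wrapped Gaussian kernel normalised to
# unit L2 norm, so the smoothed field keeps unit variance at every
# smoothness; smoothness -> Inf tends to a spatially constant field.
smooth_field <- function(nr, nc, sigma_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_cells <= 0) return(z)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(di^2, dj^2, `+`) / (2 * sigma_cells^2))
  k <- k / sqrt(sum(k^2))
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic landscape
#'
#' Draws one spatially autocorrelated surface per covariate (kernel-smoothed
#' white noise, mapped through the Gaussian CDF into the declared value
#' range) and an island mask of small disjoint circular patches outside the
#' native-range polygon. Deterministic for a fixed seed.
#'
#' @param config a [landscape_config()].
#' @return A list of class `landscape` with elements `grids` (named list of
#'   [raster_grid()]), `island` (0/1 [raster_grid()]) and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nc <- as.integer(round(config$extent_km[1] / config$cell_km))
  nr <- as.integer(round(config$extent_km[2] / config$cell_km))
  set.seed(config$seed)
  cc <- list(x = (seq_len(nc) - 0.5) * config$cell_km,
             y = (nr - seq_len(nr) + 0.5) * config$cell_km)
  need_trend <- any(vapply(config$covariates,
                           function(s) !identical(s$trend, 0), TRUE))
  dshift <- if (need_trend) {
    pts <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    d <- dist_to_polygon(config$native_polygon,
                         cc$x[pts$col], cc$y[pts$row])
    soft <- config$trend_softness_km
    belt <- stats::pnorm((d - config$trend_ring_km[1]) / soft) *
      (1 - stats::pnorm((d - config$trend_ring_km[2]) / soft))
    matrix(belt, nr, nc)
  } else matrix(0, nr, nc)
  grids <- list()
  for (sp in config$covariates) {
    f <- smooth_field(nr, nc, sp$smoothness_km / config$cell_km)
    f <- f + sp$trend * dshift
    v <- sp$range[1] + (sp$range[2] - sp$range[1]) * stats::pnorm(f)
    if (sp$integer_valued) v <- round(v)
    grids[[sp$name]] <- raster_grid(v, cellsize = config$cell_km)
  }
  island <- generate_island_mask(nr, nc, config)
  structure(list(grids = grids, island = island, config = config),
            class = "landscape")
}

# Disjoint disc patches placed outside the native polygon until the target
# cell fraction is reached (or proposals are exhausted).
generate_island_mask <- function(nr, nc, config) {
  cs <- config$cell_km
  mask <- matrix(0, nr, nc)
  target <- config$island_fraction * nr * nc
  if (target < 1) {
    return(raster_grid(mask, cellsize = cs))
  }
  cc <- list(x = (seq_len(nc) - 0.5) * cs, y = (nr - seq_len(nr) + 0.5) * cs)
  centers <- NULL
  r <- config$island_radius_km
  tries <- 0
  while (sum(mask) < target && tries < 2000) {
    tries <- tries + 1
    cx <- stats::runif(1, 0, nc * cs)
    cy <- stats::runif(1, 0, nr * cs)
    if (dist_to_polygon(config$native_polygon, cx, cy) < 2 * r) next
    if (!is.null(centers) &&
        any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) < 3 * r)) next
    centers <- rbind(centers, c(cx, cy))
    d2 <- outer((nr - seq_len(nr) + 0.5) * cs - cy,
                (seq_len(nc) - 0.5) * cs - cx,
                function(y, x) x^2 + y^2)
    mask[d2 <= r^2] <- 1
  }
  raster_grid(mask, cellsize = cs)
}

#' True log-linear density model
#'
#' The generating model of the synthetic data: on the natural-log scale,
#' density is a linear function of per-grid standardised covariates (with
#' optional quadratic terms), plus Gaussian noise; island cells are inflated
#' by a multiplicative factor on the density scale.
#'
#' @param intercept log-density intercept.
#' @param coefficients named list; each element is `c(m = ...)` or
#'   `c(m = ..., q = ...)` giving the main and quadratic coefficient of one
#'   covariate on the standardised scale.
#' @param noise_sd residual standard deviation on the log scale (> 0).
#' @param island_multiplier density multiplier for island cells (>= 1).
#' @return Object of class `true_model`.
#' @export
true_model <- function(intercept = 0.8,
                       coefficients = list(),
                       noise_sd = 0.44,
                       island_multiplier = 7) {
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("config error: noise_sd must be > 0", call. = FALSE)
  }
  if (island_multiplier < 1) {
    stop("config error: island_multiplier must be >= 1", call. = FALSE)
  }
  cf <- lapply(coefficients, function(b) {
    b <- unlist(b)
    if (!all(names(b) %in% c("m", "q")) || !"m" %in% names(b) ||
        !all(is.finite(b))) {
      stop("config error: each coefficient entry needs a finite 'm' and ",
           "optionally 'q'", call. = FALSE)
    }
    b
  })
  structure(list(intercept = intercept, coefficients = cf,
                 noise_sd = noise_sd,
                 island_multiplier = island_multiplier),
            class = "true_model")
}

#' Default true model
#'
#' Coefficient pattern of the published global wild pig analysis on the
#' standardised scale: quadratic responses to potential evapotranspiration
#' and agriculture, negative effects of carnivore richness and unvegetated
#' area, positive effects of wet- and dry-season precipitation, and a
#' negligible forest effect.
#'
#' @param noise_sd residual SD on the log scale. The default 0.44 is the
#'   residual ML standard deviation implied by the published top model's
#'   log-likelihood (logL = -108.33 at n = 183) and puts the fitted top
#'   model's adjusted R^2 near 0.55.
#' @return A [true_model()].
#' @export
default_true_model <- function(noise_sd = 0.44) {
  true_model(
    intercept = 0.8,
    coefficients = list(
      pet = c(m = 0.443, q = -0.226),
      carnivore_richness = c(m = -0.243),
      precip_wet = c(m = 0.233),
      unvegetated = c(m = -0.203),
      agriculture = c(m = 0.236, q = -0.118),
      precip_dry = c(m = 0.100),
      forest = c(m = -0.001)
    ),
    noise_sd = noise_sd,
    island_multiplier = 7
  )
}

# Standardise a vector to mean 0, sd 1 (population of supplied values).
std01 <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("degenerate-fit error: constant values cannot be standardised",
         call. = FALSE)
  }
  (v - mean(v)) / s
}

#' Generate the true density surface
#'
#' Applies the generating model to a set of covariate grids: each grid is
#' standardised over its cells, quadratic terms use the standardised square
#' of the standardised covariate (matching how quadratic design columns are
#' built downstream), cell-level Gaussian noise is added on the log scale,
#' the result is exponentiated, and island cells are multiplied by the
#' island factor.
#'
#' @param grids named list of [raster_grid()] with identical geometry.
#' @param model a [true_model()]; coefficient names must be a subset of the
#'   grid names.
#' @param seed integer seed for the noise field.
#' @param island optional 0/1 [raster_grid()] island mask.
#' @return A [raster_grid()] of density (animals/km^2, strictly positive).
#' @export
generate_true_density <- function(grids, model, seed = 1L, island = NULL) {
  stopifnot(inherits(model, "true_model"))
  stopifnot_same_geometry(grids)
  if (!all(names(model$coefficients) %in% names(grids))) {
    stop("config error: model coefficients refer to missing covariates",
         call. = FALSE)
  }
  ref <- grids[[1]]
  logd <- matrix(model$intercept, nrow(ref$values), ncol(ref$values))
  for (nm in names(model$coefficients)) {
    b <- model$coefficients[[nm]]
    z <- std01(as.vector(grids[[nm]]$values))
    term <- b[["m"]] * z
    if ("q" %in% names(b)) term <- term + b[["q"]] * std01(z^2)
    logd <- logd + matrix(term, nrow(ref$values), ncol(ref$values))
  }
  set.seed(seed)
  logd <- logd + matrix(stats::rnorm(length(logd), sd = model$noise_sd),
                        nrow(logd), ncol(logd))
  dens <- exp(logd)
  if (!is.null(island)) {
    if (!grid_same_geometry(ref, island)) {
      stop("geometry error: island mask does not match covariate grids",
           call. = FALSE)
    }
    dens[island$values > 0] <- dens[island$values > 0] * model$island_multiplier
  }
  raster_grid(dens, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize)
}

#' Sample study sites from a density surface
#'
#' Draws mainland and island cells without replacement, reads the density at
#' each sampled cell, and tags records as native or non-native by membership
#' in the native-range polygon. Defaults mirror the compiled global dataset:
#' 118 mainland and 11 island estimates.
#'
#' @param density_grid a [raster_grid()] of density.
#' @param island 0/1 [raster_grid()] island mask (same geometry).
#' @param n_mainland,n_island numbers of mainland and island records.
#' @param seed integer seed.
#' @param native_polygon optional [planar_polygon()]; records inside it get
#'   region `"native"`, others `"non-native"`.
#' @return A data frame of density records with columns `id`, `x`, `y`,
#'   `density`, `is_island`, `region`, `site_key`.
#' @export
sample_study_sites <- function(density_grid, island = NULL,
                               n_mainland = 118, n_island = 11, seed = 1L,
                               native_polygon = NULL) {
  nr <- nrow(density_grid$values); nc <- ncol(density_grid$values)
  isl <- if (is.null(island)) matrix(0, nr, nc) else island$values
  mainland_cells <- which(isl == 0)
  island_cells <- which(isl > 0)
  if (n_island > 0 && length(island_cells) == 0) {
    stop("sampling error: island records requested but no island cells exist",
         call. = FALSE)
  }
  if (n_mainland > length(mainland_cells) || n_island > length(island_cells) ||
      n_mainland + n_island > nr * nc) {
    stop("sampling error: more records requested than available cells",
         call. = FALSE)
  }
  set.seed(seed)
  cells <- c(sample(mainland_cells, n_mainland),
             if (n_island > 0) sample(island_cells, n_island))
  is_island <- c(rep(FALSE, n_mainland), rep(TRUE, n_island))
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  cs <- density_grid$cellsize
  x <- density_grid$xll + (col - 0.5) * cs
  y <- density_grid$yll + (nr - row + 0.5) * cs
  region <- rep("non-native", length(cells))
  if (!is.null(native_polygon)) {
    region[point_in_polygon(native_polygon, x, y)] <- "native"
  }
  data.frame(
    id = sprintf("site%03d", seq_along(cells)),
    x = x, y = y,
    density = density_grid$values[cbind(row, col)],
    is_island = is_island,
    region = region,
    site_key = sprintf("site%03d", seq_along(cells)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a density-record table
#'
#' Tab-delimited text with a header; columns `id`, `x`, `y`, `density`,
#' `is_island`, `region` and optionally `site_key`.
#'
#' @param records data frame of density records.
#' @param path file path.
#' @return `path` (write) or the records data frame (read).
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "density", "is_island", "region")
  if (!all(need %in% names(d))) {
    stop("data error: record table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d$is_island <- as.logical(d$is_island)
  if (!"site_key" %in% names(d)) d$site_key <- d$id
  d
}
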