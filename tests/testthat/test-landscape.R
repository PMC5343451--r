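small_config <- function(seed = 1, ...) {
  landscape_config(seed = seed, extent_km = c(500, 500), cell_km = 10, ...)
}

test_that("landscape generation is deterministic and respects declared ranges", {
  a <- generate_landscape(small_config(seed = 5))
  b <- generate_landscape(small_config(seed = 5))
  expect_identical(a$grids, b$grids)
  expect_identical(a$island$values, b$island$values)
  c2 <- generate_landscape(small_config(seed = 6))
  expect_false(identical(a$grids, c2$grids))

  specs <- default_covariate_specs()
  for (nm in names(specs)) {
    v <- a$grids[[nm]]$values
    expect_true(all(v >= specs[[nm]]$range[1] - 1e-9))
    expect_true(all(v <= specs[[nm]]$range[2] + 1e-9))
  }
  # species-count surface is integer-valued in 0..6
  cr <- a$grids[["carnivore_richness"]]$values
  expect_identical(cr, round(cr))
  expect_true(all(cr >= 0 & cr <= 6))
})

test_that("very large smoothness yields an (almost) constant surface", {
  cfg <- landscape_config(
    seed = 3, extent_km = c(300, 300), cell_km = 10,
    covariates = list(covariate_spec("v", "abiotic-climate",
                                     smoothness_km = 1e6,
                                     range = c(0, 10))),
    island_fraction = 0)
  g <- generate_landscape(cfg)$grids$v
  expect_lt(diff(range(g$values)), 1e-4 * diff(range(c(0, 10))))
})

test_that("variogram range grows with the smoothness scale", {
  semiv_profile <- function(smooth_km) {
    cfg <- landscape_config(
      seed = 9, extent_km = c(500, 500), cell_km = 10,
      covariates = list(covariate_spec("v", "abiotic-climate",
                                       smoothness_km = smooth_km,
                                       range = c(0, 1))),
      island_fraction = 0)
    m <- generate_landscape(cfg)$grids$v$values
    sill <- sample_semivariance(m, 20)
    sample_semivariance(m, 3) / sill
  }
  rough <- semiv_profile(10)
  smooth <- semiv_profile(80)
  # smoother fields keep more correlation at short lags
  expect_lt(smooth, rough)
  expect_lt(smooth, 0.6)
  expect_gt(rough, 0.6)
})

test_that("true density surface follows the generating model", {
  land <- generate_landscape(small_config(seed = 2))

  # zero coefficients, vanishing noise: density == exp(intercept)
  tm0 <- true_model(intercept = 1.1, noise_sd = 1e-9)
  d0 <- generate_true_density(land$grids, tm0, seed = 4)
  expect_equal(d0$values,
               matrix(exp(1.1), nrow(d0$values), ncol(d0$values)),
               tolerance = 1e-6)

  # strictly positive everywhere, islands inflated
  tm <- default_true_model()
  d1 <- generate_true_density(land$grids, tm, seed = 4)
  expect_true(all(d1$values > 0))
  d_isl <- generate_true_density(land$grids, tm, seed = 4,
                                 island = land$island)
  isl <- land$island$values > 0
  expect_equal(d_isl$values[isl], d1$values[isl] * tm$island_multiplier)
  expect_equal(d_isl$values[!isl], d1$values[!isl])

  # log SD matches noise_sd when all coefficients are zero (2500 cells)
  dn <- generate_true_density(land$grids, true_model(noise_sd = 0.5),
                              seed = 7)
  expect_lt(abs(stats::sd(log(dn$values)) - 0.5), 0.15 * 0.5)

  # mean log density ~ intercept (covariates centred, noise symmetric)
  tm2 <- default_true_model()
  d2 <- generate_true_density(land$grids, tm2, seed = 11)
  se <- tm2$noise_sd / sqrt(length(d2$values))
  # quadratic response of a z-scored covariate is centred too, so only
  # Monte-Carlo noise separates the cell mean from the intercept
  expect_lt(abs(mean(log(d2$values)) - tm2$intercept), 3 * se + 0.02)
})

test_that("a negative quadratic coefficient makes log density concave in the covariate", {
  cfg <- landscape_config(
    seed = 21, extent_km = c(400, 400), cell_km = 10,
    covariates = list(covariate_spec("v", "abiotic-climate",
                                     smoothness_km = 30, range = c(0, 100),
                                     allow_quadratic = TRUE,
                                     expected_sign = "quadratic")),
    island_fraction = 0)
  land <- generate_landscape(cfg)
  tm <- true_model(intercept = 0,
                   coefficients = list(v = c(m = 0.3, q = -0.4)),
                   noise_sd = 1e-9)
  d <- generate_true_density(land$grids, tm, seed = 1)
  ord <- order(land$grids$v$values)
  x <- as.vector(land$grids$v$values)[ord]
  y <- as.vector(log(d$values))[ord]
  keep <- c(TRUE, diff(x) > 1e-3)
  x <- x[keep]; y <- y[keep]
  # second difference of a concave function is non-positive (tolerance
  # covers the vanishing generator noise amplified by finite differencing)
  i <- seq(1, length(x) - 2)
  curv <- (y[i + 2] - y[i + 1]) / (x[i + 2] - x[i + 1]) -
          (y[i + 1] - y[i]) / (x[i + 1] - x[i])
  expect_true(all(curv < 1e-4))
})

test_that("study-site sampling honours counts, flags and determinism", {
  land <- generate_landscape(small_config(seed = 2))
  dens <- generate_true_density(land$grids, default_true_model(), seed = 3,
                                island = land$island)

  rec <- sample_study_sites(dens, land$island, n_mainland = 118,
                            n_island = 11, seed = 5,
                            native_polygon = small_config()$native_polygon)
  expect_equal(nrow(rec), 129)
  expect_equal(sum(rec$is_island), 11)
  expect_equal(sum(!rec$is_island), 118)
  expect_true(all(rec$region %in% c("native", "non-native")))
  # densities are read from the surface at the record cell
  expect_equal(rec$density, grid_value_at(dens, rec$x, rec$y))

  rec2 <- sample_study_sites(dens, land$island, 118, 11, seed = 5,
                             native_polygon = small_config()$native_polygon)
  expect_identical(rec, rec2)

  all_main <- sample_study_sites(dens, land$island, 30, 0, seed = 1)
  expect_false(any(all_main$is_island))

  no_isl <- raster_grid(matrix(0, 50, 50), cellsize = 10)
  expect_error(sample_study_sites(dens, no_isl, 10, 5, seed = 1),
               "sampling error")
})

test_that("invalid landscape configurations are rejected", {
  expect_error(landscape_config(cell_km = -1), "config error")
  expect_error(landscape_config(extent_km = c(95, 100), cell_km = 10),
               "divisible")
  expect_error(landscape_config(island_fraction = 0.7), "island_fraction")
  specs <- default_covariate_specs()
  specs[[2]]$name <- specs[[1]]$name
  expect_error(landscape_config(covariates = specs), "unique")
  expect_error(true_model(noise_sd = 0), "noise_sd")
})
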