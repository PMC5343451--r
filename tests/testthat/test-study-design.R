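make_rec <- function(id, density, site_key = id, is_island = FALSE,
                     region = "native", x = 1, y = 1) {
  data.frame(id = id, x = x, y = y, density = density,
             is_island = is_island, region = region, site_key = site_key,
             stringsAsFactors = FALSE)
}

test_that("aggregate_records averages repeated estimates per site and is idempotent", {
  single <- rbind(make_rec("a", 2), make_rec("b", 5, x = 3))
  expect_identical(aggregate_records(single), single)

  dup <- rbind(make_rec("a1", 2, site_key = "s1"),
               make_rec("a2", 4, site_key = "s1"),
               make_rec("b", 7, site_key = "s2", x = 2))
  out <- aggregate_records(dup)
  expect_equal(nrow(out), 2)
  expect_equal(out$density[out$site_key == "s1"], 3)
  expect_identical(aggregate_records(out), out)

  bad <- rbind(make_rec("a1", 2, site_key = "s1", is_island = FALSE),
               make_rec("a2", 4, site_key = "s1", is_island = TRUE))
  expect_error(aggregate_records(bad), "island flags")
})

test_that("147 estimates with 18 repeats collapse to 129 sites", {
  set.seed(8)
  base <- do.call(rbind, lapply(seq_len(129), function(i) {
    make_rec(sprintf("e%03d", i), runif(1, 0.1, 20),
             site_key = sprintf("s%03d", i), x = i, y = i)
  }))
  dup_sites <- sample(129, 18)
  extra <- base[dup_sites, ]
  extra$id <- paste0(extra$id, "_rep")
  extra$density <- extra$density * runif(18, 0.5, 2)
  all147 <- rbind(base, extra)
  expect_equal(nrow(all147), 147)
  out <- aggregate_records(all147)
  expect_equal(nrow(out), 129)
  # averaged density equals the group mean for a spot-checked duplicate
  k <- base$site_key[dup_sites[1]]
  expect_equal(out$density[out$site_key == k],
               mean(all147$density[all147$site_key == k]))
})

test_that("island/mainland Welch test matches the direct formula and drops background", {
  set.seed(3)
  rec <- rbind(
    make_rec(sprintf("m%d", 1:30), exp(rnorm(30, 1, 0.5)),
             is_island = FALSE),
    make_rec(sprintf("i%d", 1:8), exp(rnorm(8, 2.5, 0.6)),
             is_island = TRUE),
    make_rec(sprintf("b%d", 1:10), 0, region = "background")
  )
  w <- compare_island_mainland(rec, log_scale = FALSE)
  expect_equal(unname(w$n), c(8, 30))   # background excluded
  # same t as the summary formula on group means/SEs
  ref <- welch_from_summary(w$mean[1], w$se[1], w$mean[2], w$se[2],
                            n1 = 8, n2 = 30)
  expect_equal(w$t, ref$t, tolerance = 1e-12)
  expect_equal(w$df, ref$df, tolerance = 1e-12)
  expect_gt(w$t, 0)

  wl <- compare_island_mainland(rec, log_scale = TRUE)
  expect_gt(wl$t, 0)
  expect_true(wl$p < 1 && wl$p > 0)

  rec0 <- rec
  rec0$density[1] <- 0
  expect_error(compare_island_mainland(rec0, log_scale = TRUE), "domain")
  expect_error(compare_island_mainland(rec[1:31, ], log_scale = FALSE),
               "insufficient")
})

test_that("Welch summary statistic reproduces the published untransformed comparison", {
  # mainland 2.75 (se 0.38), islands 18.52 (se 4.15): |t| = 3.78 on the raw
  # scale; the published 4.72 was evidently computed on another scale
  w <- welch_from_summary(2.75, 0.38, 18.52, 4.15, n1 = 118, n2 = 11)
  expect_equal(abs(w$t), 3.784, tolerance = 1e-3)
  # dominant se2: df tends to n2 - 1
  w2 <- welch_from_summary(0, 0.001, 1, 5, n1 = 50, n2 = 12)
  expect_equal(w2$df, 11, tolerance = 1e-3)
  # antisymmetric in group order
  expect_equal(welch_from_summary(2.75, 0.38, 18.52, 4.15)$t,
               -welch_from_summary(18.52, 4.15, 2.75, 0.38)$t)
})

test_that("background sampling is proportional to the ring/native area ratio", {
  # convex square sized so that ring area == native area (Steiner:
  # 4*s*(outer-inner) + pi*(outer^2 - inner^2) = s^2), hence n_bg = n_native
  inner <- 100; outer <- 1000
  s <- (4 * (outer - inner) +
          sqrt(16 * (outer - inner)^2 + 4 * pi * (outer^2 - inner^2))) / 2
  poly <- planar_polygon(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
  bg <- sample_background(poly, inner, outer, n_native_estimates = 50,
                          seed = 2)
  expect_equal(nrow(bg), 50)
  expect_true(all(bg$density == 0))
  expect_true(all(bg$region == "background"))

  d <- dist_to_polygon(poly, bg$x, bg$y)
  expect_true(all(d >= inner - 1e-9 & d <= outer + 1e-9))
  expect_false(any(point_in_polygon(poly, bg$x, bg$y)))
})

test_that("a ring proportioned as 65/64 of the native area yields 65 background points", {
  # solve the Steiner quadratic for the square side with ring/native = 65/64
  inner <- 100; outer <- 1000
  ratio <- 65 / 64
  a <- ratio; b <- -4 * (outer - inner); cc <- -pi * (outer^2 - inner^2)
  s <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  poly <- planar_polygon(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
  expect_equal(ring_area(poly, inner, outer) / polygon_area(poly), ratio,
               tolerance = 1e-9)
  bg <- sample_background(poly, inner, outer, n_native_estimates = 64,
                          seed = 7)
  expect_equal(nrow(bg), 65)
})

test_that("background points are uniform over the ring", {
  poly <- planar_polygon(rbind(c(0, 0), c(2000, 0), c(2000, 1000),
                               c(0, 1000)))
  bg <- sample_background(poly, 100, 600, n_native_estimates = 400,
                          seed = 12)
  n <- nrow(bg)
  # split the ring by the polygon's vertical symmetry axis: equal areas
  left <- sum(bg$x < 1000)
  p <- left / n
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
})

test_that("degenerate background geometry is rejected", {
  poly <- planar_polygon(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  expect_error(sample_background(poly, 500, 100, n_native_estimates = 10),
               "inner")
  expect_error(planar_polygon(rbind(c(0, 0), c(1, 1))), "geometry error")
})

test_that("record tables and polygon rings round-trip through delimited text", {
  rec <- rbind(make_rec("a", 2.5), make_rec("b", 0.7, x = 3, y = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(back$density, rec$density)
  expect_equal(back$is_island, rec$is_island)
  expect_error(read_records(write_records(rec[, 1:3], path)), "data error")

  ppath <- withr::local_tempfile(fileext = ".tsv")
  writeLines("x\ty\n0\t0\n10\t0\n10\t5\n0\t5\n0\t0", ppath)
  poly <- read_polygon(ppath)
  expect_equal(polygon_area(poly), 50)
  expect_true(point_in_polygon(poly, 5, 2))
  expect_false(point_in_polygon(poly, 11, 2))
})
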