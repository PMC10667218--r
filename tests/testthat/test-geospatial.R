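st <- function(lon, lat, value) tibble::tibble(lon = lon, lat = lat,
                                               value = value)

test_that("degenerate station sets give constant surfaces", {
  one <- idw_interpolate(st(0, 0.5, 7), bbox = c(-0.5, 0.5, 0, 1),
                         cell = 0.1)
  expect_equal(max(abs(one$values - 7)), 0, tolerance = 1e-12)
  equal <- idw_interpolate(st(c(0, 0.3, -0.2), c(0.2, 0.8, 0.5), rep(2, 3)),
                           bbox = c(-0.5, 0.5, 0, 1), cell = 0.1)
  expect_equal(max(abs(equal$values - 2)), 0, tolerance = 1e-12)
})

test_that("a midpoint cell between two stations averages them symmetrically", {
  srf <- idw_interpolate(st(c(0, 0), c(0, 1), c(0, 1)),
                         bbox = c(-0.1, 0.1, 0, 1), cell = 0.2, power = 2)
  mid <- srf$values[which.min(abs(srf$lat - 0.5)), 1]
  expect_equal(mid, 0.5, tolerance = 1e-12)
})

test_that("IDW is bounded by the station range and exact at stations", {
  set.seed(31)
  for (i in 1:5) {
    s <- st(runif(8, -1, 1), runif(8, 40, 41), runif(8, 0, 10))
    srf <- idw_interpolate(s, cell = 0.05, power = 2)
    expect_gte(min(srf$values), min(s$value) - 1e-12)
    expect_lte(max(srf$values), max(s$value) + 1e-12)
  }
  # grid cell centered exactly on a station takes its value
  srf <- idw_interpolate(st(c(0.05, 0.85), c(0.05, 0.75), c(3, 9)),
                         bbox = c(0, 1, 0, 1), cell = 0.1)
  row <- which.min(abs(srf$lat - 0.05))
  col <- which.min(abs(srf$lon - 0.05))
  expect_identical(srf$values[row, col], 3)
})

test_that("duplicate stations are tolerated only when they agree", {
  agree <- idw_interpolate(st(c(0, 0, 1), c(0, 0, 1), c(5, 5, 2)),
                           bbox = c(-0.5, 1.5, -0.5, 1.5), cell = 0.5)
  expect_s3_class(agree, "surface_grid")
  expect_error(idw_interpolate(st(c(0, 0), c(0, 0), c(1, 2)),
                               bbox = c(-0.5, 0.5, -0.5, 0.5), cell = 0.5),
               "conflicting")
  expect_error(idw_interpolate(st(0, 0, 1), power = 0))
})

test_that("surface differences subtract cellwise with an antisymmetric sign", {
  a <- idw_interpolate(st(c(0, 1), c(0, 1), c(1, 3)),
                       bbox = c(0, 1, 0, 1), cell = 0.25)
  same <- surface_difference(a, a)
  expect_true(all(same$values == 0))
  expect_equal(attr(same, "mean_abs_diff"), 0)

  b <- a
  b$values <- a$values + 1
  plus <- surface_difference(a, b)
  expect_true(all(abs(plus$values - 1) < 1e-12))

  ab <- surface_difference(a, b)
  ba <- surface_difference(b, a)
  expect_equal(ab$values, -ba$values)

  other <- idw_interpolate(st(c(0, 1), c(0, 1), c(1, 3)),
                           bbox = c(0, 1, 0, 1), cell = 0.5)
  expect_error(surface_difference(a, other), "different grids")
})

test_that("banding maps cells to the classification and conserves counts", {
  base <- idw_interpolate(st(0, 0.5, 0.2), bbox = c(-0.5, 0.5, 0, 1),
                          cell = 0.1)
  banded <- band_surface(base)
  expect_true(all(banded$band_labels[banded$values] ==
                    "negligible/excellent"))
  base$values[] <- 2.5
  unfit <- band_surface(base)
  expect_true(all(unfit$band_labels[unfit$values] == "high/unfit"))
  expect_equal(sum(attr(unfit, "band_counts")), length(unfit$values))

  two <- base
  two$values[] <- rep(c(0.1, 0.9), length.out = length(two$values))
  counts <- attr(band_surface(two), "band_counts")
  expect_equal(sum(counts), length(two$values))
  expect_equal(sum(counts > 0), 2)

  overlap <- tibble::tibble(lower = c(0, 0.2), upper = c(0.3, 0.5),
                            label = c("a", "b"))
  expect_error(band_surface(base, overlap), "overlap")
})

test_that("surfaces round-trip through the ASCII grid format", {
  srf <- idw_interpolate(st(c(0, 0.7), c(0.1, 0.9), c(1, 4)),
                         bbox = c(0, 1, 0, 1), cell = 0.2,
                         variable = "hpi", season = "winter")
  asc <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(srf, asc)
  back <- read_ascii_grid(asc, variable = "hpi", season = "winter")
  expect_equal(back$values, srf$values, tolerance = 1e-12)
  expect_equal(back$bbox, srf$bbox)
  expect_equal(back$cell, srf$cell)
})

test_that("banded surfaces export as valid GeoJSON and plots build", {
  srf <- idw_interpolate(st(c(0, 0.7), c(0.1, 0.9), c(0.1, 2)),
                         bbox = c(0, 1, 0, 1), cell = 0.25)
  banded <- band_surface(srf)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_surface_geojson(banded, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, length(banded$values))
  expect_equal(parsed$features[[1]]$geometry$type, "Polygon")

  expect_s3_class(autoplot(srf), "ggplot")
  expect_s3_class(autoplot(banded), "ggplot")
  expect_s3_class(tidy(banded), "tbl_df")
  expect_true("band" %in% names(tidy(banded)))
})
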