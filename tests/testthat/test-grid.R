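test_that("planar hexagons have exactly the requested area", {
  g <- build_planar_hex_grid(c(0, 30, 0, 30), 10)
  expect_true(all(abs(g$area_km2 - 10) < 1e-6 * 10))
  # recompute from geometry with the shoelace formula
  shoelace <- vapply(g$polygons, function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  expect_true(all(abs(shoelace - 10) < 1e-6 * 10))
  expect_error(build_planar_hex_grid(c(0, -5, 0, 10), 10), "positive")
  expect_error(build_planar_hex_grid(c(0, 30, 0, 30), -1), "positive")
})

test_that("adjacent hexagon centroids are s*sqrt(3) apart", {
  g <- build_planar_hex_grid(c(0, 50, 0, 50), 25)
  s <- g$side
  d <- as.matrix(dist(g$centroids))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(abs(nn - s * sqrt(3)) < 1e-9))
})

test_that("random interior points fall in exactly one cell", {
  g <- build_planar_hex_grid(c(0, 40, 0, 40), 12)
  set.seed(11)
  pts <- cbind(runif(1000, 0, 40), runif(1000, 0, 40))
  hits <- vapply(seq_len(nrow(pts)), function(i) {
    sum(vapply(g$polygons, function(poly)
      oracle_point_in_polygon(pts[i, ], poly), logical(1)))
  }, numeric(1))
  expect_true(all(hits == 1))
  # nearest-centroid assignment agrees with point-in-polygon
  idx <- assign_cells(g, pts)
  ok <- vapply(seq_len(nrow(pts)), function(i)
    oracle_point_in_polygon(pts[i, ], g$polygons[[idx[i]]]), logical(1))
  expect_true(all(ok))
})

test_that("interior cell areas sum to count times target area", {
  g <- build_planar_hex_grid(c(0, 100, 0, 100), 20)
  inside <- vapply(g$polygons, function(p) {
    all(p[, 1] >= 0 & p[, 1] <= 100 & p[, 2] >= 0 & p[, 2] <= 100)
  }, logical(1))
  expect_gt(sum(inside), 100)
  expect_equal(sum(g$area_km2[inside]), sum(inside) * 20, tolerance = 1e-12)
})

test_that("sphere grid cells enclose the target spherical area", {
  g <- build_sphere_hex_grid(23323, 60)
  # independent oracle: geosphere's spherical polygon area on the authalic
  # sphere (f = 0), in km^2
  set.seed(3)
  sample_cells <- sample(length(g$cell_id), 60)
  orc <- vapply(sample_cells, function(i) {
    ring <- g$polygons[[i]]
    geosphere::areaPolygon(ring, a = EARTH_RADIUS_KM * 1000, f = 0) / 1e6
  }, numeric(1))
  expect_true(all(abs(orc - 23323) / 23323 < 0.005))
  expect_true(all(abs(g$area_km2 - 23323) / 23323 < 0.005))
})

test_that("sphere grid area sums to the closed-form band area", {
  g <- build_sphere_hex_grid(23323, 60)
  band <- 2 * pi * EARTH_RADIUS_KM^2 * (sin(pi / 3) - sin(-pi / 3))
  expect_lt(abs(sum(g$area_km2) - band) / band, 0.01)
})

test_that("degenerate or out-of-range latitude bands are rejected", {
  expect_error(build_sphere_hex_grid(23323, 0), "degenerate")
  expect_error(build_sphere_hex_grid(23323, 88), "unsupported domain")
})

test_that("DGGS cell counts and mean areas follow the closed forms", {
  expect_identical(dggs_cell_count(3, 0), 12)
  expect_identical(dggs_cell_count(3, 7), 21872)
  expect_identical(dggs_cell_count(4, 1), 42)
  expect_error(dggs_cell_count(5, 1), "aperture")
  expect_error(dggs_cell_count(3, -1), "resolution")
  R <- 1234.5
  expect_equal(dggs_mean_cell_area(3, 0, R), 4 * pi * R^2 / 12)
  expect_equal(dggs_mean_cell_area(3, 7, 2 * R) / dggs_mean_cell_area(3, 7, R), 4)
  counts <- vapply(0:9, function(r) dggs_cell_count(3, r), numeric(1))
  expect_true(all(diff(counts) > 0))
  areas <- vapply(0:9, function(r) dggs_mean_cell_area(3, r), numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("land clipping keeps exactly the intersecting cells", {
  g <- build_planar_hex_grid(c(0, 30, 0, 30), 40)
  land <- square_poly(2, 2, 8, 8)
  clipped <- clip_grid_to_land(g, land)
  # brute-force expectation: any of a dense point sample of the land square
  # falls inside the cell polygon
  set.seed(5)
  pts <- cbind(runif(4000, 2, 8), runif(4000, 2, 8))
  exp_keep <- vapply(g$polygons, function(poly) {
    any(vapply(seq_len(nrow(pts)), function(i)
      oracle_point_in_polygon(pts[i, ], poly), logical(1)))
  }, logical(1))
  expect_setequal(clipped$cell_id, g$cell_id[exp_keep])

  whole <- clip_grid_to_land(g, square_poly(-100, -100, 100, 100))
  expect_identical(whole$cell_id, g$cell_id)
  expect_length(suppressWarnings(clip_grid_to_land(g, square_poly(500, 500, 600, 600)))$cell_id, 0)
  expect_warning(clip_grid_to_land(g, list()), "empty land")
})

test_that("grid GeoJSON round-trip preserves ids, coordinates and areas", {
  g <- build_planar_hex_grid(c(0, 12, 0, 12), 9)
  path <- withr::local_tempfile(fileext = ".geojson")
  save_grid(g, path)
  g2 <- load_grid(path)
  expect_identical(g2$cell_id, g$cell_id)
  expect_equal(g2$area_km2, g$area_km2, tolerance = 1e-12)
  for (i in seq_along(g$polygons)) {
    expect_lt(max(abs(g2$polygons[[i]] - g$polygons[[i]])), 1e-9)
  }
})

test_that("grid files with broken properties are rejected", {
  path <- withr::local_tempfile(fileext = ".geojson")
  poly <- square_poly(0, 0, 1, 1)
  fc <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(cell_id = "a"),
         geometry = list(type = "Polygon", coordinates = list(ring_coords(poly)))),
    list(type = "Feature", properties = list(cell_id = "a"),
         geometry = list(type = "Polygon", coordinates = list(ring_coords(poly + 2))))))
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_grid(path), "duplicate cell_id")
  fc$features[[2]]$properties <- list(name = "b")
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  expect_error(load_grid(path), "feature 2")
})

test_that("third-party hexagon files load with areas recomputed", {
  path <- withr::local_tempfile(fileext = ".geojson")
  # unit squares posing as cells, no area property
  fc <- list(type = "FeatureCollection", features = lapply(1:3, function(i) {
    list(type = "Feature", properties = list(cell_id = paste0("c", i)),
         geometry = list(type = "Polygon",
                         coordinates = list(ring_coords(square_poly(i, 0, i + 1, 2)))))
  }))
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  g <- load_grid(path, crs_kind = "planar_km")
  expect_equal(g$area_km2, rep(2, 3))
})
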