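test_that("analysis grid follows the row-major top-left convention", {
  g <- analysis_grid(0, 0, 100, 60, cell_size_m = 20)
  expect_equal(c(g$nrow, g$ncol), c(3, 5))
  cc <- cell_centers(g, 1L)  # cell (0,0): min-x / max-y corner
  expect_equal(c(cc$x, cc$y), c(10, 50))
  cc2 <- cell_centers(g, g$ncol + 1L)  # first cell of second row
  expect_equal(c(cc2$x, cc2$y), c(10, 30))
  # padding: extent grows to a multiple of the cell size
  g2 <- analysis_grid(0, 0, 95, 41, cell_size_m = 20)
  expect_equal(c(g2$xmax, g2$ymax), c(100, 60))
})

test_that("polygon layers round-trip through GeoJSON", {
  p <- ses_polygons(c("A", "B"),
                    list(list(sq_ring(50, 50, 100)),
                         list(sq_ring(500.123456, 50, 100),
                              sq_ring(500.123456, 50, 20))),
                    extra = data.frame(score = c(1.25, -3.5)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_polygons(p, path)
  q <- read_polygons(path)
  expect_identical(q$id, p$id)
  expect_equal(q$score, p$score)
  expect_equal(q$area_ha, p$area_ha, tolerance = 1e-10)
  for (i in 1:2) for (r in seq_along(p$geometry[[i]]))
    expect_equal(q$geometry[[i]][[r]], p$geometry[[i]][[r]],
                 tolerance = 1e-8)
})

test_that("track layers round-trip through GeoJSON", {
  tr <- ses_tracks(c("t1", "t2"),
                   list(line_geom(c(0, 0), c(10.5, 20.25)),
                        list(rbind(c(0, 0), c(5, 5)),
                             rbind(c(7, 7), c(9, 9)))),
                   source = c("gps", "drawn"),
                   activity = c("running", NA))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_tracks(tr, path)
  s <- read_tracks(path)
  expect_identical(s$id, tr$id)
  expect_identical(s$source, tr$source)
  expect_equal(s$length_m, tr$length_m, tolerance = 1e-10)
  expect_equal(s$geometry[[2]][[2]], tr$geometry[[2]][[2]],
               tolerance = 1e-8)
})

test_that("a file without CRS is an error, never a guess", {
  p <- ses_polygons("A", list(list(sq_ring(0, 0, 10))))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_polygons(p, path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gj$crs <- NULL
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  expect_error(read_polygons(path), "CRS")
  expect_silent(read_polygons(path, crs = "local-metric"))
})

test_that("duplicate feature ids are reported by name", {
  p <- ses_polygons(c("A", "B"),
                    list(list(sq_ring(0, 0, 10)),
                         list(sq_ring(100, 0, 10))))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_polygons(p, path)
  txt <- readLines(path, warn = FALSE)
  writeLines(gsub('"id":"B"', '"id":"A"', txt), path)
  expect_error(read_polygons(path), "A")
})

test_that("geographic coordinates are projected to meters", {
  d <- 0.001  # ~111 m of latitude at the equator
  p <- ses_polygons("eq", list(list(rbind(c(0, 0), c(d, 0),
                                          c(d, d), c(0, d)))),
                    crs = "EPSG:4326")
  path <- withr::local_tempfile(fileext = ".geojson")
  write_polygons(p, path)
  q <- read_polygons(path)
  side_m <- 6371008.8 * d * pi / 180
  expect_equal(q$area_ha, side_m^2 / 1e4, tolerance = 0.01)
  expect_false(grepl("4326", attr(q, "crs")))
})

test_that("rasters round-trip through ESRI ASCII grids", {
  g <- analysis_grid(10, 20, 110, 80, cell_size_m = 20)
  v <- matrix(runif(g$nrow * g$ncol), g$nrow, g$ncol)
  v[2, 3] <- NA
  r <- sesmap:::new_raster(round(v, 6), g)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster_asc(r, path)
  r2 <- read_raster_asc(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$grid$xmin, 10)
  expect_equal(r2$grid$cell, 20)
})

test_that("rasterization assigns by cell center, last geometry wins", {
  g <- analysis_grid(0, 0, 200, 200, cell_size_m = 20)
  # one aligned 40x40 m square -> exactly 4 cells
  r <- rasterize_labels(list(list(rect_ring(40, 40, 80, 80))), 7, g)
  expect_equal(sum(r$values == 7, na.rm = TRUE), 4)
  expect_equal(sum(!is.na(r$values)), 4)
  # overlapping squares: the last-listed geometry takes the cell
  r2 <- rasterize_labels(list(list(rect_ring(0, 0, 80, 80)),
                              list(rect_ring(40, 40, 80, 80))),
                         c(1, 2), g)
  tv <- t(r2$values)
  expect_equal(unname(sesmap:::raster_cell_values(
    r2, cells_in_polygon(list(rect_ring(40, 40, 80, 80)), g))),
    rep(2, 4))
  # a sliver missing every cell center contributes nothing
  r3 <- rasterize_labels(list(list(rect_ring(21, 0, 29, 200))), 5, g)
  expect_equal(sum(!is.na(r3$values)), 0)
  # label set in the raster is a subset of the input labels
  expect_true(all(stats::na.omit(as.vector(r2$values)) %in% c(1, 2)))
  expect_warning(rasterize_labels(list(), numeric(0), g), "empty")
})

test_that("zonal means average valid in-polygon cells", {
  g <- analysis_grid(0, 0, 100, 100, cell_size_m = 20)
  p <- ses_polygons(c("A", "B"),
                    list(list(rect_ring(0, 0, 100, 100)),
                         list(rect_ring(0, 60, 40, 80))))
  const5 <- sesmap:::new_raster(matrix(5, g$nrow, g$ncol), g)
  expect_equal(unname(layer_values(zonal_mean(const5, p))), c(5, 5))

  v <- matrix(NA_real_, g$nrow, g$ncol)
  v[2, 1] <- 2; v[2, 2] <- 4  # the two cells of polygon B
  r <- sesmap:::new_raster(v, g)
  zl <- zonal_mean(r, p)
  expect_equal(unname(layer_values(zl)["B"]), 3)
  # no valid cells -> missing, not zero
  v2 <- matrix(NA_real_, g$nrow, g$ncol)
  expect_true(is.na(layer_values(
    zonal_mean(sesmap:::new_raster(v2, g), p))["A"]))
})

test_that("zonal means stay within the raster's value range", {
  set.seed(31)
  g <- analysis_grid(0, 0, 400, 400, cell_size_m = 20)
  for (k in 1:10) {
    v <- matrix(runif(g$nrow * g$ncol, -5, 7), g$nrow, g$ncol)
    r <- sesmap:::new_raster(v, g)
    p <- ses_polygons(letters[1:4],
                      lapply(1:4, function(i)
                        list(convex_ring(runif(1, 50, 350),
                                         runif(1, 50, 350), 80))))
    z <- layer_values(zonal_mean(r, p))
    z <- z[!is.na(z)]
    expect_true(all(z >= min(v) - 1e-12 & z <= max(v) + 1e-12))
  }
})
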