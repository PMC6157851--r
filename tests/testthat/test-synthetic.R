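test_that("polygon tessellation matches the configured study shape", {
  cfg <- simulation_config(seed = 1)
  p <- generate_polygons(cfg)
  expect_equal(nrow(p), 82)
  # cells tile the 2000 ha extent
  expect_equal(sum(p$area_ha), 2000, tolerance = 1e-9)
  # right-skewed: most polygons under 10 ha, a long upper tail
  expect_gte(mean(p$area_ha < 10), 0.6)
  expect_gt(max(p$area_ha), 40)
  expect_gt(stats::median(p$area_ha), 0)
  expect_lt(stats::median(p$area_ha), mean(p$area_ha))
})

test_that("small extents are tiled exactly and tiny ones rejected", {
  cfg <- simulation_config(seed = 2, n_polygons = 4,
                           park_extent_m = c(400, 400))
  p <- generate_polygons(cfg)
  expect_equal(nrow(p), 4)
  expect_equal(sum(p$area_ha), 16, tolerance = 1e-9)
  expect_error(generate_polygons(
    simulation_config(n_polygons = 100, park_extent_m = c(30, 30))),
    "too small")
})

test_that("every generator is deterministic under the seed", {
  cfg <- small_config(seed = 5)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$polygons$geometry, b$polygons$geometry)
  expect_identical(a$survey, b$survey)
  expect_identical(a$tracks$geometry, b$tracks$geometry)
  expect_identical(a$experts, b$experts)
  expect_identical(a$biotope_raster$values, b$biotope_raster$values)
  expect_identical(a$ground_truth$table, b$ground_truth$table)
  c_ <- simulate_landscape(small_config(seed = 6))
  expect_false(identical(a$survey, c_$survey))
})

test_that("survey assignment follows the planted propensity", {
  cfg <- simulation_config(seed = 3, n_polygons = 4,
                           park_extent_m = c(400, 400),
                           n_respondents = 10, p_assign = 1)
  p <- generate_polygons(cfg)
  gt0 <- list(table = data.frame(polygon_id = p$id, social = 0,
                                 use = 0, maturity = 0))
  expect_equal(nrow(generate_survey(cfg, p, gt0)), 0)
  # probability one everywhere: every respondent maps every category
  cfg1 <- simulation_config(seed = 3, n_polygons = 1,
                            park_extent_m = c(200, 200),
                            n_respondents = 10, p_assign = 1)
  p1 <- generate_polygons(cfg1)
  gt1 <- list(table = data.frame(polygon_id = p1$id, social = 1,
                                 use = 0, maturity = 0))
  sv <- generate_survey(cfg1, p1, gt1)
  # category weights spread around 1; force them equal via p_assign * w <= 1
  expect_equal(nrow(sv[sv$value_category ==
                         landscape_value_categories()[4], ]), 10)
  expect_equal(length(unique(sv$respondent_id)), 10)
})

test_that("tracks concentrate in the heavily used south", {
  south_heavier <- vapply(1:5, function(s) {
    cfg <- small_config(seed = s)
    p <- generate_polygons(cfg)
    gt <- generate_ground_truth(cfg, p)
    tr <- generate_tracks(cfg, p, gt)
    h <- cfg$park_extent_m[2]
    ylen <- vapply(seq_len(nrow(tr)), function(i) {
      pts <- tr$geometry[[i]][[1]]
      mid_y <- (pts[-1, 2] + pts[-nrow(pts), 2]) / 2
      seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
      c(sum(seg[mid_y < h / 2]), sum(seg[mid_y >= h / 2]))
    }, numeric(2))
    sum(ylen[1, ]) > sum(ylen[2, ])
  }, logical(1))
  expect_true(all(south_heavier))
})

test_that("zero tracks yield an empty layer", {
  cfg <- small_config(seed = 4)
  cfg$n_tracks <- 0L
  p <- generate_polygons(cfg)
  gt <- generate_ground_truth(cfg, p)
  expect_equal(nrow(generate_tracks(cfg, p, gt)), 0)
})

test_that("gps/drawn mix and activities mirror the configured shares", {
  sim <- small_sim()
  expect_setequal(unique(sim$tracks$source), c("gps", "drawn"))
  expect_equal(sum(sim$tracks$source == "gps"),
               round(nrow(sim$tracks) * 139 / 366))
})

test_that("stand attributes track the maturity field", {
  sim <- small_sim()
  st <- sim$stands
  expect_true(all(st$mean_diameter_cm >= 5))
  expect_true(all(st$volume_m3_per_ha >= 20))
  # stands subdivide the park: smaller than the big analysis polygons
  expect_lt(stats::median(st$area_ha), stats::median(sim$polygons$area_ha) * 5)
  # a degenerate all-zero maturity field floors every stand
  cfg <- small_config(seed = 8)
  p <- generate_polygons(cfg)
  gt <- generate_ground_truth(cfg, p)
  gt$rasters$maturity$values[] <- 0
  fb0 <- generate_forest_and_biotopes(cfg, p, gt)
  expect_true(all(fb0$stands$volume_m3_per_ha == 20))
  expect_true(all(fb0$stands$mean_diameter_cm == 5))
  expect_equal(nrow(fb0$stands), 60)  # nothing below a constant quantile
})

test_that("expert scores increase with biotope quality", {
  diffs <- vapply(1:3, function(s) {
    cfg <- small_config(seed = s)
    p <- generate_polygons(cfg)
    gt <- generate_ground_truth(cfg, p)
    fb <- generate_forest_and_biotopes(cfg, p, gt)
    top <- max(fb$legend$code); bottom <- min(fb$legend$code)
    mean(fb$experts$score[fb$experts$biotope == top]) -
      mean(fb$experts$score[fb$experts$biotope == bottom])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("biotope raster codes stay within the configured classes", {
  sim <- small_sim()
  codes <- stats::na.omit(as.vector(sim$biotope_raster$values))
  expect_true(all(codes %in% seq_len(sim$config$n_biotopes)))
  expect_gt(length(unique(codes)), 5)
})

test_that("ground truth is stored alongside but never consumed", {
  sim <- small_sim()
  gtt <- sim$ground_truth$table
  expect_setequal(gtt$polygon_id, sim$polygons$id)
  expect_true(all(c("label_social", "label_use", "label_maturity") %in%
                    names(gtt)))
  # analysis runs from the observable artifacts alone
  res <- suppressMessages(analyze_landscape(
    sim$polygons, sim$survey, sim$tracks, sim$stands, sim$biotope_raster,
    sim$experts, grid = sim$grid, boundary = sim$boundary))
  expect_s3_class(res$layers$landscape_values, "value_layer")
})
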