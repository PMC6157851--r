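make_responses <- function(score, confidence, n = 6, biotope = 1) {
  data.frame(expert_id = sprintf("E%d", seq_len(n)),
             taxon = rep(c("birds", "beetles"), length.out = n),
             biotope = biotope,
             attribute = rep(biodiversity_attributes()[1:3],
                             length.out = n),
             score = rep(score, length.out = n),
             confidence = rep(confidence, length.out = n))
}

test_that("habitat index is the logistic-diameter times volume", {
  expect_equal(habitat_quality_index(30, 0), 0)
  expect_equal(habitat_quality_index(25, 200), 100)  # f(midpoint) = 0.5
  v <- habitat_quality_index(60, 300)
  expect_gt(v, 299); expect_lt(v, 300)
  expect_equal(v, 300 / (1 + exp(-0.2 * 35)), tolerance = 1e-12)
  expect_error(habitat_quality_index(-1, 100), "nonnegative")
  expect_error(habitat_quality_index(10, -5), "nonnegative")
})

test_that("habitat index is bounded by volume and saturates", {
  d <- seq(0, 120, by = 3)
  v <- habitat_quality_index(d, 250)
  expect_true(all(v <= 250))
  expect_true(all(diff(v) > 0))
  expect_equal(habitat_quality_index(1e6, 250), 250)
})

test_that("confidence-weighted score spans 0 to 32 and averages products", {
  expect_equal(confidence_weighted_biotope_score(
    make_responses(4, 8), 1), 32)
  expect_equal(confidence_weighted_biotope_score(
    make_responses(c(4, 3, 2), 0), 1), 0)
  two <- make_responses(c(2, 4), c(4, 8), n = 2)
  expect_equal(confidence_weighted_biotope_score(two, 1), 20)
  expect_warning(
    na_score <- confidence_weighted_biotope_score(make_responses(4, 8), 99),
    "no expert responses")
  expect_true(is.na(na_score))
})

test_that("score matches a brute-force oracle and ignores row order", {
  set.seed(17)
  for (k in 1:25) {
    n <- sample(3:40, 1)
    r <- data.frame(expert_id = sample(sprintf("E%d", 1:5), n, TRUE),
                    taxon = sample(c("birds", "bats", "fungi"), n, TRUE),
                    biotope = sample(1:3, n, TRUE),
                    attribute = sample(biodiversity_attributes(), n, TRUE),
                    score = sample(0:4, n, TRUE),
                    confidence = sample(c(0, 1, 2, 4, 8), n, TRUE))
    b <- sample(unique(r$biotope), 1)
    got <- confidence_weighted_biotope_score(r, b)
    acc <- 0; cnt <- 0
    for (i in seq_len(n)) {
      if (r$biotope[i] == b) {
        acc <- acc + r$score[i] * r$confidence[i]
        cnt <- cnt + 1
      }
    }
    expect_equal(got, acc / cnt, tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 32)
    shuf <- r[sample(n), ]
    expect_identical(confidence_weighted_biotope_score(shuf, b), got)
  }
})

test_that("raising a score with positive confidence never lowers the mean", {
  set.seed(23)
  r <- make_responses(sample(0:3, 8, TRUE), sample(c(1, 2, 4, 8), 8, TRUE),
                      n = 8)
  base <- confidence_weighted_biotope_score(r, 1)
  r2 <- r
  r2$score[3] <- r2$score[3] + 1
  expect_gte(confidence_weighted_biotope_score(r2, 1), base)
})

test_that("alternative weighting schemes differ and stay in range", {
  r <- make_responses(c(4, 0), c(8, 1), n = 2)
  flat <- confidence_weighted_biotope_score(r, 1)                # 16
  wm <- confidence_weighted_biotope_score(r, 1, "weighted_mean") # 32/9
  expect_equal(flat, 16)
  expect_equal(wm, 32 / 9)
  expect_lte(wm, 4)
  # hierarchical: average within taxon first
  r$taxon <- c("birds", "birds")
  r2 <- rbind(r, make_responses(2, 2, n = 1))
  r2$taxon[3] <- "bats"
  h <- confidence_weighted_biotope_score(r2, 1, "hierarchical")
  expect_equal(h, mean(c(mean(c(32, 0)), 4)))
})

test_that("expert table validation names offending rows", {
  r <- make_responses(4, 8)
  r$score[4] <- 7
  expect_error(validate_expert_responses(r), "row\\(s\\): 4")
  r2 <- make_responses(4, 8)
  r2$confidence[2] <- 3
  expect_error(validate_expert_responses(r2), "row\\(s\\): 2")
})

test_that("habitat layer rasterizes stand indices and applies the
           non-forest rule", {
  g <- analysis_grid(0, 0, 200, 100, cell_size_m = 20)
  poly <- ses_polygons("A", list(list(rect_ring(0, 0, 200, 100))))
  # a single stand with f(d)*v = 10 covering the polygon
  d0 <- 25; vol <- 20
  stand <- ses_polygons("S1", list(list(rect_ring(0, 0, 200, 100))),
                        extra = data.frame(mean_diameter_cm = d0,
                                           volume_m3_per_ha = vol))
  lay <- habitat_quality_layer(stand, g, poly)
  expect_equal(unname(layer_values(lay)), 10)
  # half forest (index 10), half open: zero-fill rule halves the mean
  half <- ses_polygons("S1", list(list(rect_ring(0, 0, 100, 100))),
                       extra = data.frame(mean_diameter_cm = d0,
                                          volume_m3_per_ha = vol))
  expect_equal(unname(layer_values(habitat_quality_layer(half, g, poly))),
               5)
  expect_true(is.na(layer_values(
    habitat_quality_layer(half, g, poly, non_forest = "missing"))["A"]) ==
      FALSE)
  expect_equal(unname(layer_values(
    habitat_quality_layer(half, g, poly, non_forest = "missing"))), 10)
  # no stands at all: all polygons zero under the default rule
  none <- ses_polygons(character(0), list(),
                       extra = data.frame(mean_diameter_cm = numeric(0),
                                          volume_m3_per_ha = numeric(0)))
  expect_equal(unname(layer_values(habitat_quality_layer(none, g, poly))),
               0)
})

test_that("biodiversity layer averages biotope scores over cells", {
  g <- analysis_grid(0, 0, 200, 100, cell_size_m = 20)
  poly <- ses_polygons("A", list(list(rect_ring(0, 0, 200, 100))))
  # single biotope scoring 9: every polygon scores 9
  r9 <- rbind(make_responses(3, 4, n = 4),  # 12
              make_responses(3, 2, n = 4))  # 6 -> mean 9
  raster1 <- sesmap:::new_raster(matrix(1, g$nrow, g$ncol), g)
  expect_equal(unname(layer_values(
    biodiversity_layer(r9, raster1, poly))), 9)
  # cells split evenly between biotopes scoring 4 and 8 -> 6
  r48 <- rbind(make_responses(1, 4, n = 2, biotope = 1),
               make_responses(2, 4, n = 2, biotope = 2))
  v <- matrix(rep(c(1, 2), each = g$nrow * g$ncol / 2), g$nrow, g$ncol)
  expect_equal(unname(layer_values(
    biodiversity_layer(r48, sesmap:::new_raster(v, g), poly))), 6)
  # unscored biotope: cells left missing, mean over the rest, warning
  v2 <- v
  v2[, 6:10] <- 3
  expect_warning(
    lay <- biodiversity_layer(r48, sesmap:::new_raster(v2, g), poly),
    "without expert")
  expect_equal(unname(layer_values(lay)), 4)  # remaining cells all biotope 1
})
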