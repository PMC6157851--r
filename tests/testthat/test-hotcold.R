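vl <- function(v, name = "x", ids = sprintf("P%d", seq_along(v)))
  value_layer(ids, v, name)

test_that("quantile delineation labels the top and bottom thirds", {
  m9 <- delineate_hotcold(vl(1:9))
  expect_identical(m9$label[1:3], rep("cold", 3))
  expect_identical(m9$label[4:6], rep("neutral", 3))
  expect_identical(m9$label[7:9], rep("hot", 3))
  m3 <- delineate_hotcold(vl(c(2, 1, 3)))
  expect_identical(m3$label, c("neutral", "cold", "hot"))
  expect_warning(mall <- delineate_hotcold(vl(rep(5, 6))), "tied")
  expect_identical(unique(mall$label), "neutral")
  expect_error(delineate_hotcold(vl(c(1, 2, NA))), "3 non-missing")
})

test_that("class sizes stay within one of floor(n/3) and classes order", {
  set.seed(201)
  for (n in c(9, 30, 82)) {
    for (k in 1:20) {
      v <- runif(n)
      m <- delineate_hotcold(vl(v))
      nh <- sum(m$label == "hot"); nc <- sum(m$label == "cold")
      expect_lte(abs(nh - floor(n / 3)), 1)
      expect_lte(abs(nc - floor(n / 3)), 1)
      expect_gt(min(v[m$label == "hot"]), max(v[m$label == "cold"]))
    }
  }
})

test_that("threshold ties all take the threshold side's label", {
  v <- c(1, 2, 5, 5, 5, 6, 7, 8, 9)
  msg <- capture_messages(m <- delineate_hotcold(vl(v)))
  expect_match(paste(msg, collapse = ""), "ties")
  # hot threshold is the 3rd largest (7): hot = {7,8,9}
  expect_identical(m$label[v >= 7], rep("hot", 3))
  # cold threshold is the 3rd smallest (5): every tied 5 turns cold
  expect_identical(m$label[v == 5], rep("cold", 3))
  # value-range mode cuts the range instead
  mv <- delineate_hotcold(vl(c(0, 1, 2, 9, 10, 11)), mode = "value_range")
  expect_identical(mv$label, c("cold", "cold", "cold",
                               "hot", "hot", "hot"))
})

test_that("missing polygons are labeled missing and excluded", {
  m <- delineate_hotcold(vl(c(1, NA, 2, 3, 4)))
  expect_identical(m$label[2], "missing")
  expect_equal(sum(m$label == "missing"), 1)
})

test_that("hot/cold rasterization transfers labels by cell center", {
  g <- analysis_grid(0, 0, 120, 40, cell_size_m = 20)
  p <- ses_polygons(c("A", "B", "C"),
                    list(list(rect_ring(0, 0, 40, 40)),
                         list(rect_ring(40, 0, 80, 40)),
                         list(rect_ring(80, 0, 120, 40))))
  m <- delineate_hotcold(value_layer(p$id, c(3, 2, 1), "v"))
  r <- rasterize_hotcold(m, p, g)
  expect_equal(length(hotcold_cells(r, "hot")), 4)
  expect_equal(length(hotcold_cells(r, "cold")), 4)
  # every in-area cell carries exactly one label
  expect_equal(sum(!is.na(r$values)), 12)
  # an all-neutral map has no hot or cold cells
  suppressWarnings(flat <- delineate_hotcold(value_layer(p$id, c(1, 1, 1),
                                                         "v")))
  rf <- rasterize_hotcold(flat, p, g)
  expect_length(hotcold_cells(rf, "hot"), 0)
  expect_length(hotcold_cells(rf, "cold"), 0)
})

test_that("jaccard coefficient is shared over union, in percent", {
  expect_equal(jaccard_coefficient(1:5, 1:5), 100)
  expect_equal(jaccard_coefficient(1:3, 4:6), 0)
  expect_equal(jaccard_coefficient(1:3, 2:4), 50)
  expect_warning(j0 <- jaccard_coefficient(integer(0), integer(0)),
                 "empty")
  expect_equal(j0, 0)
})

test_that("jaccard is symmetric and monotone in the intersection", {
  set.seed(211)
  for (k in 1:50) {
    a <- sample(200, sample(0:60, 1))
    b <- sample(200, sample(1:60, 1))
    ja <- suppressWarnings(jaccard_coefficient(a, b))
    jb <- suppressWarnings(jaccard_coefficient(b, a))
    expect_identical(ja, jb)
    # removing a shared element with the union fixed never increases J
    shared <- intersect(a, b)
    if (length(shared) > 0) {
      a2 <- setdiff(a, shared[1])
      j2 <- suppressWarnings(jaccard_coefficient(c(a2, 999), b))
      expect_lte(j2, ja)
    }
  }
})

test_that("overlap bands follow the documented half-open bins", {
  expect_identical(band_overlap(8.6), "very low")
  expect_identical(band_overlap(50.4), "moderate")
  expect_identical(band_overlap(100), "very high")
  expect_identical(band_overlap(c(0, 20, 40, 60, 80)),
                   c("very low", "low", "moderate", "high", "very high"))
  expect_error(band_overlap(101))
})

test_that("overlay areas partition the total polygon area", {
  p <- ses_polygons(c("A", "B", "C"),
                    list(list(rect_ring(0, 0, 100, 100)),
                         list(rect_ring(100, 0, 200, 100)),
                         list(rect_ring(200, 0, 300, 100))))
  mk <- function(labels) {
    m <- data.frame(polygon_id = p$id, label = labels,
                    stringsAsFactors = FALSE)
    class(m) <- c("hotcold_map", "data.frame")
    attr(m, "variable_name") <- "v"
    m
  }
  a <- mk(c("hot", "neutral", "cold"))
  oa <- overlay_areas(a, a, p)
  expect_equal(sum(oa$area_ha), sum(p$area_ha))
  hh <- oa$area_ha[oa$state_a == "hot" & oa$state_b == "hot"]
  expect_equal(hh, 1)
  # identical maps put nothing in the off-diagonal hot/cold cells
  expect_equal(oa$area_ha[oa$state_a == "hot" & oa$state_b == "cold"], 0)
  b <- mk(c("cold", "hot", "neutral"))
  ob <- overlay_areas(a, b, p)
  expect_equal(sum(ob$area_ha), 3)
  expect_equal(ob$area_ha[ob$state_a == "hot" & ob$state_b == "cold"], 1)
})

test_that("jaccard table banding matches its percentages", {
  res <- small_results()
  jc <- res$jaccard
  expect_identical(jc$band_hot, band_overlap(jc$jaccard_hot))
  expect_identical(jc$band_cold, band_overlap(jc$jaccard_cold))
  expect_true(all(jc$jaccard_hot >= 0 & jc$jaccard_hot <= 100))
  # cell-based and polygon-based modes agree to coarse discretization
  sim <- small_sim()
  jp <- jaccard_table(res$hotcold, sim$polygons, sim$grid,
                      mode = "polygons")
  expect_equal(nrow(jp), nrow(jc))
})

test_that("mean pairwise overlap averages the selected pairs", {
  res <- data.frame(var_a = c("lv", "lv", "vu", "vu"),
                    var_b = c("fhq", "ub", "fhq", "ub"),
                    jaccard_hot = c(26.3, 20.4, 12.7, 25.3),
                    jaccard_cold = c(14.9, 12.2, 39.6, 46.2))
  m <- mean_pairwise_overlap(res)
  expect_equal(unname(m["mean_hot"]), 21.175)
  expect_equal(unname(m["mean_cold"]), 28.225)
  sub <- mean_pairwise_overlap(res, pairs = rbind(c("fhq", "lv")))
  expect_equal(unname(sub["mean_hot"]), 26.3)
  expect_error(mean_pairwise_overlap(res, pairs = rbind(c("a", "b"))),
               "empty")
})
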