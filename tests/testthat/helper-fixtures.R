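# Shared fixtures: all geometry is built in code, no stored data.

# axis-aligned square ring (side m, centered at cx, cy)
sq_ring <- function(cx, cy, side) {
  h <- side / 2
  rbind(c(cx - h, cy - h), c(cx + h, cy - h),
        c(cx + h, cy + h), c(cx - h, cy + h))
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
}

# random convex ring around (cx, cy)
convex_ring <- function(cx, cy, r_mean = 50, n = 8) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.5, 1.5) * r_mean
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# straight track geometry from coordinate pairs
line_geom <- function(...) {
  list(do.call(rbind, list(...)))
}

# small full synthetic study for pipeline-level tests
small_config <- function(seed = 7) {
  simulation_config(seed = seed, n_polygons = 30,
                    park_extent_m = c(1000, 3000), n_respondents = 60,
                    n_tracks = 40, n_stands = 60)
}

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function(seed = 7) {
  key <- paste0("sim", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_landscape(small_config(seed))
  .sim_cache[[key]]
}

small_results <- function(seed = 7) {
  key <- paste0("res", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- small_sim(seed)
    .sim_cache[[key]] <- suppressMessages(suppressWarnings(
      analyze_landscape(sim$polygons, sim$survey, sim$tracks, sim$stands,
                        sim$biotope_raster, sim$experts, grid = sim$grid,
                        boundary = sim$boundary, trails = sim$trails)))
  }
  .sim_cache[[key]]
}

# full-scale replication study used by the acceptance criteria: one run
# per seed at default study conditions, summarised per seed
replication_study <- function(n_seeds = 100) {
  key <- paste0("study", n_seeds)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  rows <- lapply(seq_len(n_seeds), function(s) {
    sim <- simulate_landscape(simulation_config(seed = s))
    r <- suppressMessages(suppressWarnings(analyze_landscape(
      sim$polygons, sim$survey, sim$tracks, sim$stands,
      sim$biotope_raster, sim$experts, grid = sim$grid,
      boundary = sim$boundary, trails = sim$trails)))
    gtt <- sim$ground_truth$table
    jac_rec <- function(lab_gt, map) {
      a <- which(lab_gt == "hot"); b <- which(map$label == "hot")
      100 * length(intersect(a, b)) / length(union(a, b))
    }
    co <- r$correlations
    rho <- function(a, b) co$rho[(co$var_a == a & co$var_b == b) |
                                   (co$var_a == b & co$var_b == a)]
    jc <- r$jaccard
    jh <- function(a, b) jc$jaccard_hot[(jc$var_a == a & jc$var_b == b) |
                                          (jc$var_a == b & jc$var_b == a)]
    soc_eco <- c(jh("landscape_values", "forest_habitat_quality"),
                 jh("landscape_values", "urban_biodiversity"),
                 jh("visitor_use", "forest_habitat_quality"),
                 jh("visitor_use", "urban_biodiversity"))
    c(rho_lv_vu = rho("landscape_values", "visitor_use"),
      rho_eco = rho("forest_habitat_quality", "urban_biodiversity"),
      rec_social = jac_rec(gtt$label_social, r$hotcold$landscape_values),
      rec_use = jac_rec(gtt$label_use, r$hotcold$visitor_use),
      rec_eco = jac_rec(gtt$label_maturity, r$hotcold$combined_ecological),
      j_lv_vu = jh("landscape_values", "visitor_use"),
      j_soc_eco_min = min(soc_eco), j_soc_eco_max = max(soc_eco),
      j_eco_eco = jh("forest_habitat_quality", "urban_biodiversity"))
  })
  .sim_cache[[key]] <- do.call(rbind, rows)
  .sim_cache[[key]]
}
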