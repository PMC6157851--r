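# End-to-end orchestration: the in-memory analysis core, the disk-based
# simulate/analyze stages, and the resolved-configuration bookkeeping.

#' Run the full analysis on in-memory inputs
#'
#' Executes the method end-to-end: social layers (landscape-value counts,
#' visitor-use density), ecological layers (forest habitat quality, urban
#' biodiversity), min-max normalization, Spearman correlation matrix
#' (including the trail-density covariate when a trail network is given),
#' equally weighted combined social and ecological layers, quantile
#' hot/coldspot maps, pairwise Jaccard overlap with interpretation bands,
#' overlay-area accounting for the three headline pairs, and the
#' management-strategy classification.
#'
#' @param polygons analysis [ses_polygons].
#' @param survey landscape-value assignment table (`respondent_id`,
#'   `polygon_id`, `value_category`).
#' @param tracks visitor-route [ses_tracks].
#' @param stands forest-stand [ses_polygons] with `mean_diameter_cm`,
#'   `volume_m3_per_ha`.
#' @param biotope_raster biotope-class `ses_raster` on the shared grid.
#' @param experts expert-response table.
#' @param grid the shared `ses_grid` (defaults to the biotope raster's).
#' @param boundary optional study-area boundary; tracks are clipped to it.
#' @param trails optional trail-network [ses_tracks] for the
#'   trail-density covariate.
#' @param hq_params [habitat_quality_params].
#' @param hot_fraction,cold_fraction hot/coldspot fractions.
#' @param delineation_mode `"quantile"` or `"value_range"`.
#' @param jaccard_mode `"cells"` or `"polygons"`.
#' @param non_forest non-forest rule for the habitat layer.
#' @param scoring_scheme expert-scoring scheme.
#' @return a results list (layers, normalized layers, correlations,
#'   hot/cold maps, Jaccard table, mean social-vs-ecological overlap,
#'   overlay areas, strategies).
#' @export
analyze_landscape <- function(polygons, survey, tracks, stands,
                              biotope_raster, experts,
                              grid = biotope_raster$grid,
                              boundary = NULL, trails = NULL,
                              hq_params = habitat_quality_params(),
                              hot_fraction = 1 / 3, cold_fraction = 1 / 3,
                              delineation_mode = "quantile",
                              jaccard_mode = "cells",
                              non_forest = "zero",
                              scoring_scheme = "product_mean") {
  experts <- validate_expert_responses(experts)
  cells <- polygon_cells(polygons, grid)
  if (!is.null(boundary)) tracks <- clip_to_boundary(tracks, boundary)

  lv_layers <- count_landscape_values(survey, polygons)
  lv <- lv_layers$landscape_values
  vu <- track_density(tracks, polygons, "visitor_use")
  fhq <- habitat_quality_layer(stands, grid, polygons, hq_params,
                               non_forest = non_forest, cells = cells)
  ub <- biodiversity_layer(experts, biotope_raster, polygons,
                           scheme = scoring_scheme, cells = cells)
  layers <- list(landscape_values = lv, visitor_use = vu,
                 forest_habitat_quality = fhq, urban_biodiversity = ub)
  if (!is.null(trails))
    layers$trail_density <- track_density(trails, polygons, "trail_density")

  normalized <- lapply(layers[c("landscape_values", "visitor_use",
                                "forest_habitat_quality",
                                "urban_biodiversity")], normalize_minmax)
  correlations <- spearman_matrix(layers)
  social <- combine_equal_weight(normalized[c("landscape_values",
                                              "visitor_use")],
                                 "combined_social")
  ecological <- combine_equal_weight(normalized[c("forest_habitat_quality",
                                                  "urban_biodiversity")],
                                     "combined_ecological")

  to_map <- c(layers[c("landscape_values", "visitor_use",
                       "forest_habitat_quality", "urban_biodiversity")],
              list(combined_social = social,
                   combined_ecological = ecological))
  hotcold <- lapply(to_map, delineate_hotcold, hot_fraction = hot_fraction,
                    cold_fraction = cold_fraction, mode = delineation_mode)

  jac <- jaccard_table(hotcold, polygons, grid, mode = jaccard_mode,
                       cells = cells)
  soc_eco_pairs <- rbind(
    c("landscape_values", "forest_habitat_quality"),
    c("landscape_values", "urban_biodiversity"),
    c("visitor_use", "forest_habitat_quality"),
    c("visitor_use", "urban_biodiversity"))
  mean_social_eco <- mean_pairwise_overlap(jac, soc_eco_pairs)

  ov_pairs <- list(
    c("landscape_values", "visitor_use"),
    c("combined_ecological", "visitor_use"),
    c("combined_social", "combined_ecological"))
  overlay <- do.call(rbind, lapply(ov_pairs, function(pr) {
    oa <- overlay_areas(hotcold[[pr[1]]], hotcold[[pr[2]]], polygons)
    cbind(data.frame(overlay = paste(pr[1], "vs", pr[2])), oa)
  }))

  strategies <- classify_strategies(hotcold$landscape_values,
                                    hotcold$visitor_use,
                                    hotcold$combined_ecological)

  list(polygons = polygons, layers = layers, normalized = normalized,
       correlations = correlations, hotcold = hotcold, jaccard = jac,
       mean_social_eco = mean_social_eco, overlay_areas = overlay,
       strategies = strategies, n_tracks = nrow(tracks))
}

# ---- disk-based stages -------------------------------------------------

sim_filenames <- function() {
  c(polygons = "polygons.geojson", boundary = "boundary.geojson",
    tracks = "tracks.geojson", trails = "trails.geojson",
    survey = "survey.csv", stands = "stands.geojson",
    biotope = "biotope.asc", legend = "biotope_legend.csv",
    experts = "experts.csv", ground_truth = "ground_truth.csv",
    config = "sim_config.yaml")
}

#' Simulate a synthetic study system to disk
#'
#' Runs [simulate_landscape] and writes every artifact in the package's
#' standard formats (GeoJSON vectors, ESRI ASCII grid raster, CSV
#' tables), the ground-truth sidecar, and the resolved configuration as
#' YAML for reproducibility. Deterministic under the configured seed.
#'
#' @param config a [simulation_config].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the simulated objects.
#' @export
run_simulate <- function(config = simulation_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_landscape(config)
  fn <- function(nm) file.path(out_dir, sim_filenames()[[nm]])
  write_polygons(sim$polygons, fn("polygons"))
  write_polygons(ses_polygons("boundary", list(sim$boundary)),
                 fn("boundary"))
  write_tracks(sim$tracks, fn("tracks"))
  write_tracks(sim$trails, fn("trails"))
  write.csv(sim$survey, fn("survey"), row.names = FALSE)
  write_polygons(sim$stands, fn("stands"))
  write_raster_asc(sim$biotope_raster, fn("biotope"))
  write.csv(sim$legend, fn("legend"), row.names = FALSE)
  write.csv(sim$experts, fn("experts"), row.names = FALSE)
  write.csv(sim$ground_truth$table, fn("ground_truth"), row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, fn("config"))
  message(sprintf("simulated %d polygons, %d tracks, %d survey rows, %d stands",
                  nrow(sim$polygons), nrow(sim$tracks), nrow(sim$survey),
                  nrow(sim$stands)))
  invisible(sim)
}

#' Pipeline configuration
#'
#' Resolved settings for a disk-based analysis run: where the inputs
#' live, where outputs go, and every methodological switch. Round-trips
#' through YAML unchanged via [write_pipeline_config] /
#' [read_pipeline_config].
#'
#' @param input_dir directory holding the inputs (as laid out by
#'   [run_simulate]).
#' @param output_dir directory for outputs.
#' @param crs CRS tag assumed for files carrying none.
#' @param midpoint_diameter_cm,steepness_per_cm habitat-sigmoid settings.
#' @param hot_fraction,cold_fraction delineation fractions.
#' @param delineation_mode `"quantile"` or `"value_range"`.
#' @param jaccard_mode `"cells"` or `"polygons"`.
#' @param non_forest `"zero"` or `"missing"`.
#' @param scoring_scheme expert-scoring scheme.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            crs = "local-metric",
                            midpoint_diameter_cm = 25,
                            steepness_per_cm = 0.2,
                            hot_fraction = 1 / 3, cold_fraction = 1 / 3,
                            delineation_mode = "quantile",
                            jaccard_mode = "cells",
                            non_forest = "zero",
                            scoring_scheme = "product_mean") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- config
  class(x) <- NULL
  yaml::write_yaml(x, path, precision = 17)  # bit-exact float round trip
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the disk-based analysis stage
#'
#' Reads the inputs named by the configuration, validates them, executes
#' [analyze_landscape], and writes the report bundle, the resolved
#' configuration and a run log (with input checksums) next to the
#' outputs. Any stage error aborts the run and removes partial outputs.
#'
#' @param config a [pipeline_config].
#' @return invisibly, the analysis results list.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fns <- sim_filenames()
  fn <- function(nm) file.path(config$input_dir, fns[[nm]])
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  res <- tryCatch({
    log <- c(sprintf("run started: deterministic analysis of %s",
                     config$input_dir))
    inputs <- vapply(c("polygons", "boundary", "tracks", "survey",
                       "stands", "biotope", "experts"), fn, character(1))
    missing_in <- inputs[!file.exists(inputs)]
    if (length(missing_in))
      stop("missing input file(s): ", paste(missing_in, collapse = ", "))
    sums <- tools::md5sum(inputs)
    log <- c(log, sprintf("input %s md5 %s", basename(names(sums)), sums))

    polygons <- read_polygons(fn("polygons"), crs = config$crs)
    boundary <- read_polygons(fn("boundary"), crs = config$crs)
    tracks <- read_tracks(fn("tracks"), crs = config$crs)
    trails <- if (file.exists(fn("trails")))
      read_tracks(fn("trails"), crs = config$crs) else NULL
    survey <- read.csv(fn("survey"), stringsAsFactors = FALSE,
                       colClasses = "character")
    stands <- read_polygons(fn("stands"), crs = config$crs)
    biotope_raster <- read_raster_asc(fn("biotope"))
    experts <- validate_expert_responses(
      read.csv(fn("experts"), stringsAsFactors = FALSE))
    log <- c(log, sprintf(
      "inputs: %d polygons, %d tracks, %d survey rows, %d stands, %d expert rows",
      nrow(polygons), nrow(tracks), nrow(survey), nrow(stands),
      nrow(experts)))

    results <- analyze_landscape(
      polygons, survey, tracks, stands, biotope_raster, experts,
      boundary = boundary, trails = trails,
      hq_params = habitat_quality_params(config$midpoint_diameter_cm,
                                         config$steepness_per_cm),
      hot_fraction = config$hot_fraction,
      cold_fraction = config$cold_fraction,
      delineation_mode = config$delineation_mode,
      jaccard_mode = config$jaccard_mode,
      non_forest = config$non_forest,
      scoring_scheme = config$scoring_scheme)

    written <- build_report(results, out_dir)
    cfg_path <- file.path(out_dir, "pipeline_config.yaml")
    write_pipeline_config(config, cfg_path)
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(log, "run completed"), log_path)
    written <- c(written, cfg_path, log_path)
    results
  }, error = function(e) {
    unlink(written)
    stop("analysis stage failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
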