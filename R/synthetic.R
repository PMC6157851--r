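# Synthetic study system: an elongated park tessellated into irregular
# analysis polygons, with planted spatial gradients that give the
# generated data the statistical structure the analysis assumes --
# citizen landscape values rising toward the quiet northern end, visitor
# use concentrated in the densely accessed south, and a shared latent
# "forest maturity" field driving both ecological layers. The ground
# truth is stored alongside the data and is never read by the analysis.

#' Configuration of the synthetic landscape
#'
#' Defaults emulate the study conditions the pipeline targets: 82
#' irregular polygons tiling a 2 x 10 km park, 599 survey respondents
#' over 7 landscape-value categories, 366 route tracks, stand-level
#' forest inventory, a 37-class biotope mosaic on a 20 m grid, and
#' 2-3 experts per each of 10 taxa scoring 7 biodiversity attributes
#' with 5-level confidence.
#'
#' Gradient strengths set the weight of the planted north-south trends
#' relative to the smooth random field (`gradient_social` pulls
#' landscape-value propensity north, `gradient_use` pulls route
#' intensity south, `gradient_maturity` raises forest maturity toward
#' both remote park ends, leaving the intensively managed mid-park
#' younger); `noise_*` set the smooth-field and observation noise
#' scales. The seed fully determines every generated artifact.
#'
#' @param seed integer RNG seed.
#' @param n_polygons number of analysis polygons.
#' @param park_extent_m `c(width, height)` of the park, meters.
#' @param n_respondents survey respondents.
#' @param n_tracks route tracks.
#' @param n_value_categories landscape-value categories (<= 7 uses the
#'   canonical names).
#' @param n_taxa taxonomic groups in the expert elicitation.
#' @param n_biotopes biotope classes in the raster mosaic.
#' @param experts_per_taxon candidate counts of experts per taxon.
#' @param cell_size_m analysis-grid cell size.
#' @param gradient_social,gradient_use,gradient_maturity trend weights.
#' @param noise_field smooth-field weight for the two social latents.
#' @param noise_maturity smooth-field weight for the maturity latent.
#' @param noise_stand lognormal sd of stand-level maturity noise.
#' @param noise_biotope lognormal sd of cell-level biotope noise.
#' @param noise_expert sd of expert score noise (score points).
#' @param p_assign maximum per-category assignment probability.
#' @param n_stands forest-stand count (default scales with park area,
#'   one stand per ~4.5 ha).
#' @param trail_spacing_m node spacing of the synthetic trail grid.
#' @param south_seed_fraction,south_band_fraction polygon-seed clustering
#'   controls producing the right-skewed area distribution.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_polygons = 82L,
                              park_extent_m = c(2000, 10000),
                              n_respondents = 599L,
                              n_tracks = 366L,
                              n_value_categories = 7L,
                              n_taxa = 10L,
                              n_biotopes = 37L,
                              experts_per_taxon = 2:3,
                              cell_size_m = 20,
                              gradient_social = 1,
                              gradient_use = 1,
                              gradient_maturity = 1,
                              noise_field = 0.25,
                              noise_maturity = 0.45,
                              noise_stand = 0.08,
                              noise_biotope = 0.12,
                              noise_expert = 0.8,
                              p_assign = 0.08,
                              n_stands = NULL,
                              trail_spacing_m = 100,
                              south_seed_fraction = 0.73,
                              south_band_fraction = 0.18) {
  cfg <- list(seed = as.integer(seed), n_polygons = as.integer(n_polygons),
              park_extent_m = park_extent_m,
              n_respondents = as.integer(n_respondents),
              n_tracks = as.integer(n_tracks),
              n_value_categories = as.integer(n_value_categories),
              n_taxa = as.integer(n_taxa),
              n_biotopes = as.integer(n_biotopes),
              experts_per_taxon = experts_per_taxon,
              cell_size_m = cell_size_m,
              gradient_social = gradient_social,
              gradient_use = gradient_use,
              gradient_maturity = gradient_maturity,
              noise_field = noise_field, noise_maturity = noise_maturity,
              noise_stand = noise_stand, noise_biotope = noise_biotope,
              noise_expert = noise_expert, p_assign = p_assign,
              n_stands = n_stands, trail_spacing_m = trail_spacing_m,
              south_seed_fraction = south_seed_fraction,
              south_band_fraction = south_band_fraction)
  counts <- c(cfg$n_polygons, cfg$n_respondents, cfg$n_value_categories,
              cfg$n_taxa, cfg$n_biotopes)
  if (any(counts <= 0) || cfg$n_tracks < 0)
    stop("all counts must be positive (n_tracks may be zero)")
  if (abs(cfg$seed) >= 2^30) stop("seed must be below 2^30 in magnitude")
  stopifnot(length(park_extent_m) == 2, all(park_extent_m > 0))
  class(cfg) <- "sim_config"
  cfg
}

sim_grid <- function(config) {
  analysis_grid(0, 0, config$park_extent_m[1], config$park_extent_m[2],
                cell_size_m = config$cell_size_m)
}

park_boundary <- function(config) {
  w <- config$park_extent_m[1]; h <- config$park_extent_m[2]
  list(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- analysis polygons -------------------------------------------------

#' Generate the analysis-polygon tessellation
#'
#' Voronoi cells of clustered seed points clipped to the park rectangle:
#' most seeds fall in a narrow southern band (mimicking the small,
#' intensively subdivided units near the city), the rest spread over the
#' remainder, yielding a right-skewed area distribution with the bulk of
#' polygons under 10 ha at defaults. The cells tile the extent exactly.
#'
#' @param config a [simulation_config].
#' @return a [ses_polygons] layer of `n_polygons` cells.
#' @export
generate_polygons <- function(config) {
  w <- config$park_extent_m[1]; h <- config$park_extent_m[2]
  n <- config$n_polygons
  if (w * h < n * 100)
    stop("extent too small for ", n, " polygons (need >= 100 m2 each)")
  with_seed(config$seed + 11L, {
    band <- config$south_band_fraction * h
    n_s <- round(config$south_seed_fraction * n)
    n_n <- n - n_s
    seeds <- rbind(
      cbind(runif(n_s, 0, w), runif(n_s, 0, band)),
      cbind(runif(n_n, 0, w), runif(n_n, band, h)))
    # enforce a minimal seed separation so no Voronoi cell degenerates
    repeat {
      d <- as.matrix(stats::dist(seeds))
      diag(d) <- Inf
      close_i <- which(apply(d, 1, min) < 1)
      if (length(close_i) == 0) break
      i <- close_i[1]
      in_south <- i <= n_s
      seeds[i, ] <- c(runif(1, 0, w),
                      if (in_south) runif(1, 0, band) else runif(1, band, h))
    }
    cells <- voronoi_rect(seeds, 0, 0, w, h)
    ses_polygons(sprintf("P%02d", seq_len(n)), cells)
  })
}

# ---- latent fields and ground truth ------------------------------------

# Smooth random field: a standardized sum of Gaussian bumps with ~1.2 km
# length scale, plus a monotone north-south trend. Exponential trend
# shapes keep rank spacing roughly even across the park.
make_field_raster <- function(config, seed_offset, direction, trend_weight,
                              noise_weight, grid, steep = 1.5) {
  with_seed(config$seed + seed_offset, {
    w <- config$park_extent_m[1]; h <- config$park_extent_m[2]
    n_bumps <- 25
    cx <- runif(n_bumps, 0, w); cy <- runif(n_bumps, 0, h)
    amp <- rnorm(n_bumps)
    ell <- 1200
    cc <- cell_centers(grid)
    bump <- rep(0, nrow(cc))
    for (k in seq_len(n_bumps))
      bump <- bump + amp[k] *
        exp(-((cc$x - cx[k])^2 + (cc$y - cy[k])^2) / (2 * ell^2))
    if (stats::sd(bump) > 0) bump <- (bump - mean(bump)) / stats::sd(bump)
    yn <- cc$y / h
    tn <- switch(direction,
                 north = 1 - yn,
                 south = yn,
                 # high within ~1.5 km of the south edge and ~4.5 km of
                 # the north edge, low across the managed mid-park
                 ends = pmin(yn / 0.15, (1 - yn) / 0.45, 1))
    trend <- (exp(-steep * tn) - exp(-steep)) / (1 - exp(-steep))
    trend <- (trend - mean(trend)) / stats::sd(trend)  # same scale as bump
    v <- trend_weight * trend + noise_weight * bump
    v <- (v - min(v)) / max(1e-12, diff(range(v)))
    tv <- rep(NA_real_, grid$nrow * grid$ncol)
    tv[cc$cell] <- v
    new_raster(matrix(tv, grid$nrow, grid$ncol, byrow = TRUE), grid)
  })
}

#' Generate the planted ground truth
#'
#' Builds the three latent surfaces (social-value propensity, use
#' intensity, forest maturity) on the analysis grid, the per-polygon
#' latents, and planted hot/cold labels for each latent (top/bottom
#' third at the default fractions). The social and maturity latents are
#' zonal means of their surfaces; the use latent is the track-generating
#' walk model's expected track-length density per polygon (edge weight
#' times in-polygon edge length, per hectare), i.e. the noiseless value
#' of the quantity the visitor-use layer later measures. The ground
#' truth is written alongside the generated data for parameter-recovery
#' checks and is never read by the analysis pipeline itself.
#'
#' @param config a [simulation_config].
#' @param polygons the generated analysis polygons.
#' @return a `ses_ground_truth` list with elements `rasters` (three
#'   `ses_raster`s scaled to `[0, 1]`), `table` (per-polygon latents and
#'   labels) and `grid`.
#' @export
generate_ground_truth <- function(config, polygons) {
  grid <- sim_grid(config)
  rasters <- list(
    social = make_field_raster(config, 21L, "north", config$gradient_social,
                               config$noise_field, grid),
    use = make_field_raster(config, 22L, "south", config$gradient_use,
                            config$noise_field, grid, steep = 3),
    maturity = make_field_raster(config, 23L, "ends",
                                 config$gradient_maturity,
                                 config$noise_maturity, grid))
  cells <- polygon_cells(polygons, grid)
  lat <- lapply(rasters[c("social", "maturity")], function(r)
    zonal_mean(r, polygons, cells = cells)$value)
  tg <- trail_graph(config, rasters$use)
  tab <- data.frame(polygon_id = polygons$id,
                    social = lat$social,
                    use = expected_walk_density(tg, polygons),
                    maturity = lat$maturity, stringsAsFactors = FALSE)
  for (nm in c("social", "use", "maturity")) {
    lay <- value_layer(polygons$id, tab[[nm]], nm)
    tab[[paste0("label_", nm)]] <-
      suppressMessages(delineate_hotcold(lay))$label
  }
  structure(list(rasters = rasters, table = tab, grid = grid),
            class = "ses_ground_truth")
}

# Trail-preference rule of the walk model: edge weights rise steeply
# with planted use intensity.
walk_edge_weights <- function(u_edge) (0.05 + u_edge)^4

# Expected track-length density (arbitrary units per ha) of the
# random-walk track model: stationary edge-visit rates are proportional
# to edge weight, so the expectation per polygon is the weighted sum of
# in-polygon edge lengths over the polygon area.
expected_walk_density <- function(tg, polygons) {
  w_edge <- walk_edge_weights(tg$u_edge)
  eb <- cbind(pmin(tg$x[tg$from], tg$x[tg$to]),
              pmin(tg$y[tg$from], tg$y[tg$to]),
              pmax(tg$x[tg$from], tg$x[tg$to]),
              pmax(tg$y[tg$from], tg$y[tg$to]))
  dens <- numeric(nrow(polygons))
  for (j in seq_len(nrow(polygons))) {
    rings <- polygons$geometry[[j]]
    bb <- rings_bbox(rings)
    hit <- which(eb[, 1] <= bb["xmax"] & eb[, 3] >= bb["xmin"] &
                 eb[, 2] <= bb["ymax"] & eb[, 4] >= bb["ymin"])
    tot <- 0
    for (e in hit) {
      seg <- rbind(c(tg$x[tg$from[e]], tg$y[tg$from[e]]),
                   c(tg$x[tg$to[e]], tg$y[tg$to[e]]))
      cl <- cpp_clip_polyline(seg, rings)
      if (length(cl)) tot <- tot + w_edge[e] * parts_length_m(cl)
    }
    dens[j] <- tot / polygons$area_ha[j]
  }
  dens
}

raster_lookup <- function(raster, x, y) {
  g <- raster$grid
  col <- pmin(g$ncol, pmax(1L, floor((x - g$xmin) / g$cell) + 1L))
  row <- pmin(g$nrow, pmax(1L, floor((g$ymax - y) / g$cell) + 1L))
  raster$values[cbind(row, col)]
}

# ---- survey ------------------------------------------------------------

#' Generate landscape-value survey assignments
#'
#' Every respondent assigns each value category to a random subset of
#' polygons, with probability `p_assign * w_c * s_i` where `s_i` is the
#' polygon's planted social-value propensity (in `[0, 1]`) and `w_c` a
#' per-category weight spread over 1.4 down to 0.6 (so some values are
#' mapped more often than others). Zero propensity yields no rows.
#'
#' @param config a [simulation_config].
#' @param polygons analysis polygons.
#' @param ground_truth the matching [generate_ground_truth] object.
#' @return data frame with `respondent_id`, `polygon_id`,
#'   `value_category` (one row per distinct assignment).
#' @export
generate_survey <- function(config, polygons, ground_truth) {
  s <- setNames(ground_truth$table$social,
                ground_truth$table$polygon_id)[polygons$id]
  ncat <- config$n_value_categories
  canon <- landscape_value_categories()
  cats <- if (ncat <= length(canon)) canon[seq_len(ncat)] else
    c(canon, sprintf("value_%02d", seq_len(ncat - length(canon)) +
                       length(canon)))
  w_c <- seq(1.4, 0.6, length.out = ncat)
  with_seed(config$seed + 31L, {
    nr <- config$n_respondents
    np <- nrow(polygons)
    p <- pmin(1, config$p_assign * outer(s, w_c))  # np x ncat
    u <- array(runif(nr * np * ncat), c(nr, np, ncat))
    p3 <- aperm(array(p, c(np, ncat, nr)), c(3, 1, 2))  # nr x np x ncat
    hit <- which(u < p3, arr.ind = TRUE)
    if (nrow(hit) == 0L)
      return(data.frame(respondent_id = character(0),
                        polygon_id = character(0),
                        value_category = character(0),
                        stringsAsFactors = FALSE))
    out <- data.frame(
      respondent_id = sprintf("R%03d", hit[, 1]),
      polygon_id = polygons$id[hit[, 2]],
      value_category = cats[hit[, 3]],
      stringsAsFactors = FALSE)
    out[order(out$respondent_id, out$polygon_id, out$value_category), ,
        drop = FALSE]
  })
}

# ---- tracks and trail network ------------------------------------------

# Noisy grid of paths: nodes on a jittered lattice, 4-neighbour edges.
trail_graph <- function(config, use_raster) {
  with_seed(config$seed + 41L, {
    w <- config$park_extent_m[1]; h <- config$park_extent_m[2]
    sp <- config$trail_spacing_m
    nx <- max(2L, round(w / sp)); ny <- max(2L, round(h / sp))
    gx <- rep(seq(sp / 2, w - sp / 2, length.out = nx), times = ny)
    gy <- rep(seq(sp / 2, h - sp / 2, length.out = ny), each = nx)
    gx <- pmin(w, pmax(0, gx + runif(nx * ny, -0.25 * sp, 0.25 * sp)))
    gy <- pmin(h, pmax(0, gy + runif(nx * ny, -0.25 * sp, 0.25 * sp)))
    idx <- function(i, j) (j - 1L) * nx + i
    e1 <- integer(0); e2 <- integer(0)
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      if (i < nx) { e1 <- c(e1, idx(i, j)); e2 <- c(e2, idx(i + 1L, j)) }
      if (j < ny) { e1 <- c(e1, idx(i, j)); e2 <- c(e2, idx(i, j + 1L)) }
    }
    len <- sqrt((gx[e1] - gx[e2])^2 + (gy[e1] - gy[e2])^2)
    umid <- raster_lookup(use_raster,
                          (gx[e1] + gx[e2]) / 2, (gy[e1] + gy[e2]) / 2)
    unode <- raster_lookup(use_raster, gx, gy)
    g <- igraph::graph_from_edgelist(cbind(e1, e2), directed = FALSE)
    list(graph = g, x = gx, y = gy, from = e1, to = e2, len = len,
         u_edge = umid, u_node = unode)
  })
}

#' Generate the managed trail-network layer
#'
#' The synthetic trail graph (a noisy lattice of paths) as one
#' multi-part polyline, with path density following the planted use
#' intensity only through which edges tracks later favor; the network
#' itself is spatially uniform. Used for the trail-density covariate.
#'
#' @inheritParams generate_survey
#' @return a one-feature [ses_tracks] layer named `"trail_network"`.
#' @export
generate_trail_network <- function(config, ground_truth) {
  tg <- trail_graph(config, ground_truth$rasters$use)
  parts <- lapply(seq_along(tg$from), function(k)
    rbind(c(tg$x[tg$from[k]], tg$y[tg$from[k]]),
          c(tg$x[tg$to[k]], tg$y[tg$to[k]])))
  ses_tracks("trail_network", list(parts), source = "drawn",
             activity = "trail")
}

#' Generate visitor route tracks
#'
#' Tracks are weighted random walks on the synthetic trail graph: edge
#' weights rise steeply with the planted use intensity, walk starts are
#' sampled from the stationary (strength-proportional) distribution,
#' and transitions pick incident edges proportionally to weight. For
#' such a reversible walk the stationary edge-visit rate is proportional
#' to the edge weight, so edge-visit rates -- and hence the summed track
#' length per polygon -- follow the planted use-intensity field, which
#' concentrates use in the heavily accessed south at defaults. Walk
#' lengths are lognormal (median ~5 km); a paper-like share of tracks is
#' labeled `gps` vs `drawn`, with activities drawn from recreational
#' categories.
#'
#' @inheritParams generate_survey
#' @return a [ses_tracks] layer of `n_tracks` tracks.
#' @export
generate_tracks <- function(config, polygons, ground_truth) {
  if (config$n_tracks == 0L)
    return(ses_tracks(character(0), list(), source = character(0),
                      activity = character(0)))
  tg <- trail_graph(config, ground_truth$rasters$use)
  with_seed(config$seed + 42L, {
    n <- config$n_tracks
    w_edge <- walk_edge_weights(tg$u_edge)
    nv <- length(tg$x)
    inc <- vector("list", nv)      # incident edge ids per node
    for (k in seq_along(tg$from)) {
      inc[[tg$from[k]]] <- c(inc[[tg$from[k]]], k)
      inc[[tg$to[k]]] <- c(inc[[tg$to[k]]], k)
    }
    strength <- vapply(inc, function(e) sum(w_edge[e]), numeric(1))
    mean_edge_len <- mean(tg$len)
    n_steps <- pmax(5L, round(rlnorm(n, log(5000 / mean_edge_len), 0.45)))
    geoms <- vector("list", n)
    for (t in seq_len(n)) {
      v <- sample.int(nv, 1, prob = strength)
      path <- integer(n_steps[t] + 1L)
      path[1] <- v
      for (s in seq_len(n_steps[t])) {
        es <- inc[[v]]
        e <- if (length(es) == 1L) es else
          es[sample.int(length(es), 1, prob = w_edge[es])]
        v <- if (tg$from[e] == v) tg$to[e] else tg$from[e]
        path[s + 1L] <- v
      }
      geoms[[t]] <- list(cbind(tg$x[path], tg$y[path]))
    }
    n_gps <- round(n * 139 / 366)
    src <- sample(c(rep("gps", n_gps), rep("drawn", n - n_gps)))
    act <- sample(c("running", "cycling", "walking", "dog walking",
                    "mountain biking"), n, replace = TRUE,
                  prob = c(0.333, 0.314, 0.139, 0.115, 0.099))
    ses_tracks(sprintf("T%03d", seq_len(n)), geoms, source = src,
               activity = act)
  })
}

# ---- forest stands, biotopes, expert table -----------------------------

#' Biodiversity attributes of the expert questionnaire
#' @export
biodiversity_attributes <- function() {
  c("species richness", "specialist species", "biomass", "abundance",
    "evenness", "uniqueness", "representativeness")
}

#' Generate forest stands, the biotope raster and the expert table
#'
#' Stands are a finer Voronoi subdivision of the park (one stand per
#' ~4.5 ha by default). Stand maturity is the planted maturity field at
#' the stand centroid under multiplicative lognormal noise; mean tree
#' diameter and wood volume rise linearly with it from configured floors
#' (5 cm, 20 m3/ha). Stands below a maturity threshold are non-forest
#' and are excluded from the inventory (their cells later fall under the
#' habitat layer's non-forest rule). Biotope classes are maturity
#' quantile bins with cell-level noise, so mature-forest classes
#' co-locate with high maturity; expert score means increase with the
#' class's quality parameter and confidences are sampled uniformly from
#' the five levels.
#'
#' @inheritParams generate_survey
#' @return list with `stands` (a [ses_polygons] layer with
#'   `mean_diameter_cm`, `volume_m3_per_ha`), `biotope_raster`
#'   (`ses_raster` of class codes), `legend` (code, name, quality) and
#'   `experts` (the expert-response table).
#' @export
generate_forest_and_biotopes <- function(config, polygons, ground_truth) {
  grid <- ground_truth$grid
  w <- config$park_extent_m[1]; h <- config$park_extent_m[2]
  n_st <- config$n_stands %||% max(4L, round(w * h / 1e4 / 4.5))
  mat <- ground_truth$rasters$maturity
  with_seed(config$seed + 51L, {
    seeds <- cbind(runif(n_st, 0, w), runif(n_st, 0, h))
    cells_geom <- voronoi_rect(seeds, 0, 0, w, h)
    cent <- t(vapply(cells_geom, function(g) rings_centroid(g), numeric(2)))
    m0 <- raster_lookup(mat, cent[, 1], cent[, 2])
    m_st <- pmin(1, m0 * exp(rnorm(n_st, 0, config$noise_stand)))
    # lowest-maturity stands (~12%) are open/non-forest habitats; with a
    # degenerate (constant) field nothing is strictly below the quantile
    # and every stand stays forest at the attribute floors
    forest <- !(m_st < stats::quantile(m_st, 0.12))
    stands <- ses_polygons(
      sprintf("S%03d", which(forest)), cells_geom[forest],
      extra = data.frame(mean_diameter_cm = 5 + 50 * m_st[forest],
                         volume_m3_per_ha = 20 + 380 * m_st[forest]))

    cc <- cell_centers(grid)
    m_cell <- raster_lookup(mat, cc$x, cc$y)
    q <- pmin(1, m_cell * exp(rnorm(length(m_cell), 0, config$noise_biotope)))
    nb <- config$n_biotopes
    code <- pmin(nb, 1L + floor(q * nb))
    tv <- rep(NA_real_, grid$nrow * grid$ncol)
    tv[cc$cell] <- code
    biotope_raster <- new_raster(matrix(tv, grid$nrow, grid$ncol,
                                        byrow = TRUE), grid)
    legend <- data.frame(code = seq_len(nb),
                         name = sprintf("biotope_%02d", seq_len(nb)),
                         quality = (seq_len(nb) - 0.5) / nb,
                         stringsAsFactors = FALSE)

    attrs <- biodiversity_attributes()
    taxa <- c("vascular plants", "polypores", "fungi", "birds", "bats",
              "mammals", "herpetofauna", "butterflies", "hymenoptera",
              "beetles")
    taxa <- if (config$n_taxa <= length(taxa)) taxa[seq_len(config$n_taxa)]
    else c(taxa, sprintf("taxon_%02d", seq_len(config$n_taxa - length(taxa))))
    n_exp <- sample(config$experts_per_taxon, length(taxa), replace = TRUE)
    rows <- list()
    eid <- 0L
    for (tx in seq_along(taxa)) {
      for (e in seq_len(n_exp[tx])) {
        eid <- eid + 1L
        mu <- 4 * legend$quality
        per_b <- lapply(seq_len(nb), function(b) {
          sc <- pmin(4, pmax(0, round(mu[b] +
                                        rnorm(length(attrs), 0,
                                              config$noise_expert))))
          data.frame(expert_id = sprintf("E%02d", eid), taxon = taxa[tx],
                     biotope = b, attribute = attrs, score = sc,
                     confidence = sample(c(0, 1, 2, 4, 8), length(attrs),
                                         replace = TRUE),
                     stringsAsFactors = FALSE)
        })
        rows <- c(rows, per_b)
      }
    }
    experts <- do.call(rbind, rows)
    rownames(experts) <- NULL
    list(stands = stands, biotope_raster = biotope_raster, legend = legend,
         experts = experts)
  })
}

#' Generate the complete synthetic study system
#'
#' Convenience wrapper running every generator under one configuration.
#'
#' @param config a [simulation_config].
#' @return list with `config`, `grid`, `boundary`, `polygons`,
#'   `ground_truth`, `survey`, `tracks`, `trails`, `stands`,
#'   `biotope_raster`, `legend`, `experts`.
#' @export
simulate_landscape <- function(config = simulation_config()) {
  polygons <- generate_polygons(config)
  gt <- generate_ground_truth(config, polygons)
  forest <- generate_forest_and_biotopes(config, polygons, gt)
  list(config = config, grid = gt$grid,
       boundary = park_boundary(config), polygons = polygons,
       ground_truth = gt,
       survey = generate_survey(config, polygons, gt),
       tracks = generate_tracks(config, polygons, gt),
       trails = generate_trail_network(config, gt),
       stands = forest$stands, biotope_raster = forest$biotope_raster,
       legend = forest$legend, experts = forest$experts)
}
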