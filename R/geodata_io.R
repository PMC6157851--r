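# Shared analysis grid, rasters, and file I/O (GeoJSON vectors, ESRI ASCII
# grid rasters, CSV tables). Every raster produced by the pipeline lives on
# one analysis grid so zonal statistics and cell-set overlap are exact.

#' Define the shared analysis grid
#'
#' A regular square grid (default 20 m cells) covering a rectangular
#' extent. The extent is padded outward so the cell size divides it
#' exactly. Cells are indexed row-major from the minimum-x / maximum-y
#' corner (row 1 is the top row); `cell_id = (row - 1) * ncol + col`.
#'
#' @param xmin,ymin,xmax,ymax extent in projected CRS units (meters).
#' @param cell_size_m cell edge length in meters (default 20).
#' @return a `ses_grid` object.
#' @export
analysis_grid <- function(xmin, ymin, xmax, ymax, cell_size_m = 20) {
  stopifnot(cell_size_m > 0, xmax > xmin, ymax > ymin)
  ncol <- ceiling((xmax - xmin) / cell_size_m - 1e-9)
  nrow <- ceiling((ymax - ymin) / cell_size_m - 1e-9)
  g <- list(xmin = xmin, ymin = ymin,
            xmax = xmin + ncol * cell_size_m,
            ymax = ymin + nrow * cell_size_m,
            cell = cell_size_m, nrow = nrow, ncol = ncol)
  class(g) <- "ses_grid"
  g
}

#' @export
print.ses_grid <- function(x, ...) {
  cat(sprintf("<ses_grid> %d x %d cells of %g m, extent [%g,%g]x[%g,%g]\n",
              x$nrow, x$ncol, x$cell, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

#' Cell-center coordinates
#'
#' @param grid a `ses_grid`.
#' @param cells optional integer cell ids (row-major, 1-based); default all.
#' @return data frame with `cell`, `x`, `y`.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$nrow * grid$ncol)
  row <- (cells - 1L) %/% grid$ncol + 1L
  col <- (cells - 1L) %% grid$ncol + 1L
  data.frame(cell = cells,
             x = grid$xmin + (col - 0.5) * grid$cell,
             y = grid$ymax - (row - 0.5) * grid$cell)
}

new_raster <- function(values, grid) {
  stopifnot(is.matrix(values), nrow(values) == grid$nrow,
            ncol(values) == grid$ncol)
  r <- list(values = values, grid = grid)
  class(r) <- "ses_raster"
  r
}

#' @export
print.ses_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<ses_raster> %d x %d cells of %g m; %d no-data; range %s\n",
              nrow(v), ncol(v), x$grid$cell, sum(is.na(v)),
              if (all(is.na(v))) "all NA" else
                sprintf("[%g, %g]", min(v, na.rm = TRUE), max(v, na.rm = TRUE))))
  invisible(x)
}

#' Cells whose centers fall inside a polygon
#'
#' @param rings polygon geometry (list of ring matrices).
#' @param grid a `ses_grid`.
#' @return integer vector of row-major cell ids.
#' @export
cells_in_polygon <- function(rings, grid) {
  rings <- normalize_rings(rings)
  bb <- rings_bbox(rings)
  col0 <- max(1L, floor((bb["xmin"] - grid$xmin) / grid$cell) + 1L)
  col1 <- min(grid$ncol, ceiling((bb["xmax"] - grid$xmin) / grid$cell))
  row0 <- max(1L, floor((grid$ymax - bb["ymax"]) / grid$cell) + 1L)
  row1 <- min(grid$nrow, ceiling((grid$ymax - bb["ymin"]) / grid$cell))
  if (col1 < col0 || row1 < row0) return(integer(0))
  rows <- row0:row1
  cols <- col0:col1
  cand <- as.integer(outer((rows - 1L) * grid$ncol, cols, "+"))
  cc <- cell_centers(grid, cand)
  cand[as.logical(points_in_rings_batch(cc$x, cc$y, rings))]
}

points_in_rings_batch <- function(px, py, rings) {
  cpp_points_in_rings(px, py, rings)
}

# Per-polygon cell-id lists; computed once and reused across layers.
polygon_cells <- function(polygons, grid) {
  lapply(polygons$geometry, cells_in_polygon, grid = grid)
}

#' Rasterize labeled geometries onto the analysis grid
#'
#' Assigns to each cell the label of the geometry containing its center;
#' when geometries overlap, the last-listed geometry wins (deterministic in
#' input order). Cells covered by no geometry are no-data.
#'
#' @param geoms list of polygon geometries, or a [ses_polygons] layer.
#' @param labels numeric label per geometry.
#' @param grid a `ses_grid`.
#' @return a `ses_raster` of labels (NA = no-data).
#' @export
rasterize_labels <- function(geoms, labels, grid) {
  if (inherits(geoms, "ses_polygons")) geoms <- geoms$geometry
  if (length(geoms) != length(labels))
    stop("labels must be one per geometry")
  vals <- matrix(NA_real_, grid$nrow, grid$ncol)
  if (length(geoms) == 0L) {
    warning("empty geometry collection: all-no-data raster")
    return(new_raster(vals, grid))
  }
  tv <- t(vals) # row-major indexing: tv[cell] with cell = (row-1)*ncol+col
  for (k in seq_along(geoms)) {
    cs <- cells_in_polygon(geoms[[k]], grid)
    if (length(cs)) tv[cs] <- labels[k]
  }
  new_raster(matrix(tv, grid$nrow, grid$ncol, byrow = TRUE), grid)
}

raster_cell_values <- function(raster, cells) {
  t(raster$values)[cells]
}

#' Zonal mean of a raster over analysis polygons
#'
#' Per polygon, the arithmetic mean of non-no-data cell values among the
#' cells whose centers fall inside it. Polygons containing zero valid
#' cells yield `NA` (missing, never silently zero).
#'
#' @param raster a `ses_raster`.
#' @param polygons a [ses_polygons] layer on the same grid/CRS.
#' @param variable_name name for the resulting layer.
#' @param cells optional precomputed [polygon_cells] list.
#' @param na_as_zero if `TRUE`, in-polygon no-data cells count as zeros in
#'   the mean instead of being dropped (used by the forest habitat layer's
#'   non-forest rule).
#' @return a [value_layer].
#' @export
zonal_mean <- function(raster, polygons, variable_name = "zonal_mean",
                       cells = NULL, na_as_zero = FALSE) {
  if (is.null(cells)) cells <- polygon_cells(polygons, raster$grid)
  vals <- vapply(cells, function(cs) {
    if (length(cs) == 0L) return(NA_real_)
    v <- raster_cell_values(raster, cs)
    if (na_as_zero) v[is.na(v)] <- 0
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  value_layer(polygons$id, vals, variable_name)
}

# ---- projection --------------------------------------------------------

is_geographic_crs <- function(crs) {
  grepl("4326|WGS *84|longlat|geographic|CRS84", crs, ignore.case = TRUE)
}

# Spherical transverse Mercator about a central meridian; used to bring
# geographic (degree) inputs into a local meter-based plane. R = 6371 km.
tmerc_project <- function(lon, lat, lon0) {
  R <- 6371008.8
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  B <- cos(phi) * sin(lam)
  x <- R / 2 * log((1 + B) / (1 - B))
  y <- R * atan2(tan(phi), cos(lam))
  cbind(x, y)
}

project_geometry <- function(rings_or_parts, lon0) {
  lapply(rings_or_parts, function(m) tmerc_project(m[, 1], m[, 2], lon0))
}

# ---- GeoJSON vector I/O ------------------------------------------------

geojson_read_features <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  crs <- gj$crs$properties$name
  list(features = gj$features, crs = crs)
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Read analysis polygons from a GeoJSON file
#'
#' Reads Polygon/MultiPolygon features, checks id uniqueness and geometry
#' validity (invalid geometries are rejected with an error), reprojects
#' geographic (degree) coordinates to a local meter-based transverse
#' Mercator plane, and computes areas in hectares.
#'
#' @param path GeoJSON file.
#' @param id_field property holding the polygon identifier.
#' @param crs CRS tag when the file carries none; a file without a CRS and
#'   no `crs` argument is an error (no silent assumption).
#' @return a [ses_polygons] layer.
#' @export
read_polygons <- function(path, id_field = "id", crs = NULL) {
  fc <- geojson_read_features(path)
  crs <- fc$crs %||% crs
  if (is.null(crs))
    stop("no CRS in ", path, " and none supplied; refusing to guess")
  ids <- character(0)
  geoms <- list()
  props <- list()
  for (f in fc$features) {
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, coords_to_matrix),
      MultiPolygon = unlist(lapply(g$coordinates, function(poly)
        lapply(poly, coords_to_matrix)), recursive = FALSE),
      stop("unsupported geometry type for polygons: ", g$type))
    ids <- c(ids, as.character(f$properties[[id_field]]))
    geoms <- c(geoms, list(rings))
    props <- c(props, list(f$properties))
  }
  if (anyDuplicated(ids))
    stop("duplicate polygon ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is_geographic_crs(crs)) {
    lon0 <- mean(vapply(geoms, function(g) mean(g[[1]][, 1]), numeric(1)))
    geoms <- lapply(geoms, project_geometry, lon0 = lon0)
    crs <- sprintf("local-tmerc lon0=%.6f", lon0)
  }
  # area_ha is always recomputed in the working CRS, never trusted from file
  extra_names <- setdiff(unique(unlist(lapply(props, names))),
                         c(id_field, "area_ha"))
  extra <- NULL
  if (length(extra_names)) {
    extra <- as.data.frame(lapply(extra_names, function(nm)
      vapply(props, function(p) {
        v <- p[[nm]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))), col.names = extra_names)
  }
  ses_polygons(ids, geoms, crs = crs, extra = extra)
}

#' Write analysis polygons to GeoJSON
#'
#' @param polygons a [ses_polygons] layer.
#' @param path output file.
#' @export
write_polygons <- function(polygons, path) {
  extra_cols <- setdiff(names(polygons), c("id", "geometry"))
  feats <- lapply(seq_len(nrow(polygons)), function(i) {
    rings <- polygons$geometry[[i]]
    coords <- lapply(rings, function(r)
      lapply(seq_len(nrow(r) + 1), function(k) {
        k <- if (k > nrow(r)) 1L else k
        c(r[k, 1], r[k, 2])
      }))
    props <- c(list(id = polygons$id[i]),
               lapply(polygons[i, extra_cols, drop = FALSE], identity))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = attr(polygons, "crs"))),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

#' Read route tracks from a GeoJSON file
#'
#' @inheritParams read_polygons
#' @return a [ses_tracks] layer.
#' @export
read_tracks <- function(path, id_field = "id", crs = NULL) {
  fc <- geojson_read_features(path)
  crs <- fc$crs %||% crs
  if (is.null(crs))
    stop("no CRS in ", path, " and none supplied; refusing to guess")
  ids <- character(0); geoms <- list(); src <- character(0); act <- character(0)
  for (f in fc$features) {
    g <- f$geometry
    parts <- switch(g$type,
      LineString = list(coords_to_matrix(g$coordinates)),
      MultiLineString = lapply(g$coordinates, coords_to_matrix),
      stop("unsupported geometry type for tracks: ", g$type))
    ids <- c(ids, as.character(f$properties[[id_field]]))
    src <- c(src, f$properties$source %||% "gps")
    act <- c(act, f$properties$activity %||% NA_character_)
    geoms <- c(geoms, list(parts))
  }
  if (is_geographic_crs(crs)) {
    lon0 <- mean(vapply(geoms, function(g) mean(g[[1]][, 1]), numeric(1)))
    geoms <- lapply(geoms, project_geometry, lon0 = lon0)
    crs <- sprintf("local-tmerc lon0=%.6f", lon0)
  }
  ses_tracks(ids, geoms, source = src, activity = act, crs = crs)
}

#' Write route tracks to GeoJSON
#'
#' @param tracks a [ses_tracks] layer.
#' @param path output file.
#' @export
write_tracks <- function(tracks, path) {
  feats <- lapply(seq_len(nrow(tracks)), function(i) {
    parts <- tracks$geometry[[i]]
    part_coords <- lapply(parts, function(p)
      lapply(seq_len(nrow(p)), function(k) c(p[k, 1], p[k, 2])))
    geom <- if (length(parts) == 1L)
      list(type = "LineString", coordinates = part_coords[[1]])
    else list(type = "MultiLineString", coordinates = part_coords)
    list(type = "Feature",
         properties = list(id = tracks$id[i], source = tracks$source[i],
                           activity = tracks$activity[i]),
         geometry = geom)
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = attr(tracks, "crs"))),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

# ---- ESRI ASCII grid raster I/O ---------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Single-band plain-text raster with an explicit no-data value; rows are
#' written top-down, matching the grid's row-major convention.
#'
#' @param raster a `ses_raster`.
#' @param path output `.asc` file.
#' @param nodata no-data sentinel written for `NA` cells.
#' @export
write_raster_asc <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  v <- raster$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cell),
    sprintf("NODATA_value %.10g", nodata)), con)
  writeLines(apply(v, 1, function(r) paste(format(r, scientific = FALSE,
                                                  trim = TRUE),
                                           collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path `.asc` file.
#' @return a `ses_raster`.
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- matrix(scan(text = lines[i:length(lines)], quiet = TRUE),
                 nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  vals[vals == nodata] <- NA_real_
  g <- analysis_grid(hdr$xllcorner, hdr$yllcorner,
                     hdr$xllcorner + hdr$ncols * hdr$cellsize,
                     hdr$yllcorner + hdr$nrows * hdr$cellsize,
                     cell_size_m = hdr$cellsize)
  new_raster(vals, g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
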