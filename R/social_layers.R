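# Social value layers: landscape-value counts from participatory mapping
# and visitor-use density from route tracks.

#' Canonical landscape-value categories
#'
#' The seven positive landscape values offered to survey respondents.
#' @export
landscape_value_categories <- function() {
  c("scenic view", "valuable nature site", "feeling of forest",
    "feeling of space and freedom", "history and culture",
    "peace and quiet", "opportunity for activities")
}

#' Count landscape-value assignments per polygon
#'
#' Each polygon receives, per value category, the number of distinct
#' respondents who assigned that category to it, plus a summed "multiple
#' landscape value" layer (sum of the per-category counts). A respondent
#' counts at most once per (polygon, category): duplicate rows are
#' collapsed with a warning. Polygons never mentioned get 0 -- absence of
#' mention is observed zero support, not missing data. Polygon size is
#' deliberately not used to adjust the counts.
#'
#' @param assignments data frame with columns `respondent_id`,
#'   `polygon_id`, `value_category`.
#' @param polygons a [ses_polygons] layer; every `polygon_id` in
#'   `assignments` must exist here (unknown ids are an error).
#' @param categories category levels; defaults to the categories present,
#'   ordered as in [landscape_value_categories()] where applicable.
#' @return named list of [value_layer]s, one per category, plus
#'   `landscape_values` (the summed layer).
#' @export
count_landscape_values <- function(assignments, polygons,
                                   categories = NULL) {
  need <- c("respondent_id", "polygon_id", "value_category")
  if (!all(need %in% names(assignments)))
    stop("assignments must have columns: ", paste(need, collapse = ", "))
  assignments$polygon_id <- as.character(assignments$polygon_id)
  unknown <- setdiff(assignments$polygon_id, polygons$id)
  if (length(unknown))
    stop("unknown polygon id(s) in assignments: ",
         paste(sort(unknown), collapse = ", "))
  key <- paste(assignments$respondent_id, assignments$polygon_id,
               assignments$value_category, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    warning(sprintf("collapsed %d duplicate (respondent, polygon, value) rows",
                    ndup))
    assignments <- assignments[!duplicated(key), ]
  }
  if (is.null(categories)) {
    present <- unique(as.character(assignments$value_category))
    canon <- landscape_value_categories()
    categories <- c(intersect(canon, present), setdiff(present, canon))
    if (length(categories) == 0L) categories <- canon
  }
  layers <- lapply(categories, function(cat) {
    sub <- assignments[assignments$value_category == cat, ]
    cnt <- table(factor(sub$polygon_id, levels = polygons$id))
    value_layer(polygons$id, as.numeric(cnt), variable_name = cat)
  })
  names(layers) <- categories
  total <- Reduce(`+`, lapply(layers, function(l) l$value))
  layers$landscape_values <- value_layer(polygons$id, total,
                                         variable_name = "landscape_values")
  layers
}

#' Clip route tracks to the study-area boundary
#'
#' Intersects each polyline with the boundary polygon; tracks falling
#' entirely outside are dropped, and a track that enters and leaves
#' repeatedly keeps all inside pieces as one multi-part geometry under its
#' original id.
#'
#' @param tracks a [ses_tracks] layer.
#' @param boundary polygon geometry (list of rings) or a one-row
#'   [ses_polygons] layer.
#' @return a [ses_tracks] layer of clipped tracks.
#' @export
clip_to_boundary <- function(tracks, boundary) {
  rings <- boundary_rings(boundary)
  keep_id <- character(0); keep_geom <- list()
  keep_src <- character(0); keep_act <- character(0)
  for (i in seq_len(nrow(tracks))) {
    cl <- clip_polyline(tracks$geometry[[i]], rings)
    if (length(cl) == 0L) next
    keep_id <- c(keep_id, tracks$id[i])
    keep_geom <- c(keep_geom, list(cl))
    keep_src <- c(keep_src, tracks$source[i])
    keep_act <- c(keep_act, tracks$activity[i])
  }
  ses_tracks(keep_id, keep_geom, source = keep_src, activity = keep_act,
             crs = attr(tracks, "crs"))
}

boundary_rings <- function(boundary) {
  if (inherits(boundary, "ses_polygons")) {
    stopifnot(nrow(boundary) == 1L)
    boundary <- boundary$geometry[[1]]
  }
  normalize_rings(boundary)
}

#' Visitor-use (track) density per polygon
#'
#' For every polygon, the summed length in meters of the track pieces
#' falling geometrically inside it, divided by the polygon area in
#' hectares (m/ha). Polygons crossed by no track get 0. The same operation
#' applied to a managed trail-network layer yields the trail-density
#' covariate.
#'
#' @param tracks a [ses_tracks] layer (clip with [clip_to_boundary] first
#'   so only intra-site pieces count).
#' @param polygons a [ses_polygons] layer in the same CRS.
#' @param variable_name layer name, default `"visitor_use"`.
#' @return a [value_layer] of densities (m/ha); its
#'   `attr(, "total_length_m")` carries the summed in-polygon length for
#'   conservation checks.
#' @export
track_density <- function(tracks, polygons, variable_name = "visitor_use") {
  crs_t <- attr(tracks, "crs"); crs_p <- attr(polygons, "crs")
  if (!is.null(crs_t) && !is.null(crs_p) && !identical(crs_t, crs_p))
    stop("CRS mismatch between tracks (", crs_t, ") and polygons (",
         crs_p, ")")
  lens <- numeric(nrow(polygons))
  if (nrow(tracks) > 0) {
    # flatten to parts so the bbox prefilter works for multi-part tracks
    parts <- unlist(tracks$geometry, recursive = FALSE)
    pb <- do.call(rbind, lapply(parts, function(p)
      c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))))
    for (j in seq_len(nrow(polygons))) {
      rings <- polygons$geometry[[j]]
      bb <- rings_bbox(rings)
      hit <- which(pb[, 1] <= bb["xmax"] & pb[, 3] >= bb["xmin"] &
                   pb[, 2] <= bb["ymax"] & pb[, 4] >= bb["ymin"])
      if (length(hit) == 0L) next
      tot <- 0
      for (i in hit) {
        cl <- cpp_clip_polyline(parts[[i]], rings)
        if (length(cl)) tot <- tot + parts_length_m(cl)
      }
      lens[j] <- tot
    }
  }
  out <- value_layer(polygons$id, lens / polygons$area_ha,
                     variable_name = variable_name)
  attr(out, "total_length_m") <- sum(lens)
  out
}
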