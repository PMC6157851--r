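# Planar geometry containers and primitives.
#
# A polygon geometry is a list of rings; each ring is an n x 2 numeric
# matrix of projected coordinates (meters) without a repeated closing
# vertex. Interior membership follows the even-odd rule over all rings, so
# holes and multi-part polygons need no special casing. A polyline geometry
# is a list of parts, each an m x 2 matrix.

#' Analysis-polygon layer
#'
#' Constructs the universal aggregation unit of the pipeline: a set of
#' uniquely identified polygons in a projected (meter) coordinate system
#' with their areas in hectares. All value layers, hot/coldspot maps and
#' overlay accounts are keyed by these polygon ids.
#'
#' @param id character vector of unique polygon identifiers.
#' @param geometry list of polygon geometries (each a list of `n x 2` ring
#'   matrices, meters).
#' @param crs character tag for the projected CRS the coordinates are in.
#' @param extra optional data frame of additional attribute columns
#'   (e.g. stand attributes), row-aligned with `id`.
#' @return a `ses_polygons` data frame with columns `id`, `geometry`
#'   (list column), `area_ha`, plus any extra attribute columns.
#' @examples
#' sq <- list(list(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))))
#' p <- ses_polygons("A", sq)
#' p$area_ha  # 1 ha
#' @export
ses_polygons <- function(id, geometry, crs = "local-metric", extra = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate polygon ids: ", paste(dup, collapse = ", "))
  }
  if (length(geometry) != length(id))
    stop("id and geometry lengths differ")
  geometry <- lapply(geometry, normalize_rings)
  bad <- !vapply(geometry, rings_valid, logical(1))
  if (any(bad))
    stop("invalid (self-intersecting or degenerate) geometry for id(s): ",
         paste(id[bad], collapse = ", "))
  area_ha <- vapply(geometry, rings_area_m2, numeric(1)) / 1e4
  df <- data.frame(id = id, area_ha = area_ha, stringsAsFactors = FALSE)
  df$geometry <- geometry
  df <- df[, c("id", "geometry", "area_ha")]
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == length(id))
    for (nm in setdiff(names(extra), c("id", "geometry", "area_ha")))
      df[[nm]] <- extra[[nm]]
  }
  attr(df, "crs") <- crs
  class(df) <- c("ses_polygons", "data.frame")
  df
}

#' @export
print.ses_polygons <- function(x, ...) {
  cat(sprintf("<ses_polygons> %d polygons, %.1f ha total [crs: %s]\n",
              nrow(x), sum(x$area_ha), attr(x, "crs")))
  cat(sprintf("  area range %.2f-%.2f ha\n",
              min(x$area_ha), max(x$area_ha)))
  invisible(x)
}

#' Route-track layer
#'
#' Polyline features (visitor routes or a managed trail network) in the
#' same projected CRS as the analysis polygons. Multi-part geometries are
#' supported; lengths are the summed euclidean part lengths in meters.
#'
#' @param id character vector of track identifiers.
#' @param geometry list of polyline geometries (lists of `m x 2` part
#'   matrices).
#' @param source per-track provenance, `"gps"` or `"drawn"`.
#' @param activity optional per-track activity label.
#' @param crs CRS tag.
#' @return a `ses_tracks` data frame with columns `id`, `geometry`,
#'   `source`, `activity`, `length_m`.
#' @export
ses_tracks <- function(id, geometry, source = "gps", activity = NA_character_,
                       crs = "local-metric") {
  id <- as.character(id)
  n <- length(id)
  if (length(geometry) != n) stop("id and geometry lengths differ")
  geometry <- lapply(geometry, normalize_parts)
  len <- vapply(geometry, parts_length_m, numeric(1))
  if (n > 0 && any(len <= 0))
    stop("zero-length track(s): ", paste(id[len <= 0], collapse = ", "))
  source <- rep_len(as.character(source), n)
  bad_src <- !source %in% c("gps", "drawn")
  if (n > 0 && any(bad_src)) stop("track source must be 'gps' or 'drawn'")
  df <- data.frame(id = id, source = source,
                   activity = rep_len(as.character(activity), n),
                   length_m = len, stringsAsFactors = FALSE)
  df$geometry <- geometry
  df <- df[, c("id", "geometry", "source", "activity", "length_m")]
  attr(df, "crs") <- crs
  class(df) <- c("ses_tracks", "data.frame")
  df
}

#' @export
print.ses_tracks <- function(x, ...) {
  cat(sprintf("<ses_tracks> %d tracks, %.1f km total [crs: %s]\n",
              nrow(x), sum(x$length_m) / 1000, attr(x, "crs")))
  invisible(x)
}

# ---- ring / part helpers ----------------------------------------------

normalize_rings <- function(geom) {
  if (is.matrix(geom)) geom <- list(geom)
  lapply(geom, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 2) stop("ring must have 2 columns")
    n <- nrow(r)
    if (n >= 2 && all(abs(r[1, ] - r[n, ]) < 1e-12)) r <- r[-n, , drop = FALSE]
    if (nrow(r) < 3) stop("ring needs at least 3 distinct vertices")
    dimnames(r) <- NULL
    r
  })
}

normalize_parts <- function(geom) {
  if (is.matrix(geom)) geom <- list(geom)
  lapply(geom, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 2) stop("polyline part must have 2 columns")
    if (nrow(p) < 2) stop("polyline part needs >= 2 vertices")
    dimnames(p) <- NULL
    p
  })
}

shoelace_area <- function(r) {
  n <- nrow(r)
  j <- c(n, seq_len(n - 1))
  abs(sum(r[j, 1] * r[, 2] - r[, 1] * r[j, 2])) / 2
}

# Even-odd area of a ring set: rings nested at odd depth subtract.
rings_area_m2 <- function(rings) {
  if (length(rings) == 1L) return(shoelace_area(rings[[1]]))
  signs <- vapply(seq_along(rings), function(k) {
    p <- rings[[k]][1, ]
    depth <- sum(vapply(seq_along(rings)[-k], function(j)
      cpp_points_in_rings(p[1], p[2], rings[j]), logical(1)))
    if (depth %% 2 == 0) 1 else -1
  }, numeric(1))
  sum(signs * vapply(rings, shoelace_area, numeric(1)))
}

# Non-adjacent self- or cross-intersections among ring edges.
rings_valid <- function(rings) {
  segs <- do.call(rbind, lapply(seq_along(rings), function(k) {
    r <- rings[[k]]
    n <- nrow(r)
    cbind(ring = k, i = seq_len(n), x1 = r[, 1], y1 = r[, 2],
          x2 = r[c(2:n, 1), 1], y2 = r[c(2:n, 1), 2])
  }))
  ns <- nrow(segs)
  if (ns > 400) return(TRUE)  # validity check is O(n^2); skip huge inputs
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      if (segs[a, "ring"] == segs[b, "ring"]) {
        n_in_ring <- nrow(rings[[segs[a, "ring"]]])
        d <- abs(segs[a, "i"] - segs[b, "i"])
        if (d <= 1 || d == n_in_ring - 1) next  # adjacent edges share a vertex
      }
      if (segments_cross(segs[a, 3:6], segs[b, 3:6])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(s, t) {
  d1 <- orient2d(t[1], t[2], t[3], t[4], s[1], s[2])
  d2 <- orient2d(t[1], t[2], t[3], t[4], s[3], s[4])
  d3 <- orient2d(s[1], s[2], s[3], s[4], t[1], t[2])
  d4 <- orient2d(s[1], s[2], s[3], s[4], t[3], t[4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

parts_length_m <- function(parts) {
  sum(vapply(parts, function(p) {
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  }, numeric(1)))
}

rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

rings_centroid <- function(rings) {
  # area-weighted centroid of the outer rings; adequate for label placement
  # and latent-field evaluation on convex-ish tessellation cells
  cs <- vapply(rings, function(r) {
    n <- nrow(r)
    j <- c(2:n, 1)
    cr <- r[, 1] * r[j, 2] - r[j, 1] * r[, 2]
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(c(mean(r[, 1]), mean(r[, 2]), 0))
    cx <- sum((r[, 1] + r[j, 1]) * cr) / (6 * a)
    cy <- sum((r[, 2] + r[j, 2]) * cr) / (6 * a)
    c(cx, cy, abs(a))
  }, numeric(3))
  w <- cs[3, ]
  if (sum(w) == 0) w <- rep(1, length(w))
  c(sum(cs[1, ] * w) / sum(w), sum(cs[2, ] * w) / sum(w))
}

points_in_geometry <- function(px, py, rings) {
  cpp_points_in_rings(px, py, rings)
}

#' Clip a polyline to a polygon
#'
#' Intersects each part of a polyline with the interior of a polygon
#' (ring set, even-odd rule) and returns the inside pieces as a multi-part
#' polyline, or an empty list when nothing falls inside.
#'
#' @param parts polyline geometry (list of `m x 2` matrices).
#' @param rings polygon geometry (list of ring matrices).
#' @return list of `m x 2` matrices (possibly empty).
#' @export
clip_polyline <- function(parts, rings) {
  parts <- normalize_parts(parts)
  rings <- normalize_rings(rings)
  out <- list()
  for (p in parts) out <- c(out, cpp_clip_polyline(p, rings))
  out
}

# Voronoi tessellation of seed points clipped to a rectangle, by iterative
# half-plane clipping against neighbours in order of increasing distance
# (with an early stop once no further neighbour can cut the cell).
voronoi_rect <- function(seeds, xmin, ymin, xmax, ymax) {
  n <- nrow(seeds)
  rect <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    si <- seeds[i, ]
    d2 <- (seeds[, 1] - si[1])^2 + (seeds[, 2] - si[2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    cell <- rect
    for (j in ord) {
      dj <- sqrt(d2[j])
      maxr <- sqrt(max((cell[, 1] - si[1])^2 + (cell[, 2] - si[2])^2))
      if (dj / 2 > maxr) break
      mid <- (si + seeds[j, ]) / 2
      nrm <- seeds[j, ] - si
      cell <- cpp_clip_halfplane(cell, mid[1], mid[2], nrm[1], nrm[2])
      if (nrow(cell) < 3) break
    }
    cells[[i]] <- list(cell)
  }
  cells
}
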