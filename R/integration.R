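# Layer integration: min-max normalization, Spearman rank-correlation
# matrix, equally weighted combination, and the population-density
# descriptive summary around the park border.

#' Min-max normalize a value layer
#'
#' Rescales to `v' = (v - min) / (max - min)` so every dataset carries
#' equal weight in combination: the minimum maps to 0 and the maximum to
#' 1. Missing values stay missing. A constant layer has no defined
#' normalization and errors by default; `constant = "zero"` maps it to all
#' zeros with a warning instead.
#'
#' @param layer a [value_layer].
#' @param constant `"error"` (default) or `"zero"`.
#' @return a normalized [value_layer].
#' @export
normalize_minmax <- function(layer, constant = c("error", "zero")) {
  constant <- match.arg(constant)
  v <- layer$value
  ok <- !is.na(v)
  if (sum(ok) == 0L) stop("layer '", variable_name(layer), "' is all missing")
  rng <- range(v[ok])
  if (diff(rng) == 0) {
    if (constant == "error")
      stop("layer '", variable_name(layer),
           "' is constant; min-max normalization undefined")
    warning("constant layer '", variable_name(layer), "' mapped to 0")
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - rng[1]) / (rng[2] - rng[1])
  }
  value_layer(layer$polygon_id, v, variable_name(layer), normalized = TRUE)
}

#' Pairwise Spearman correlations between layers
#'
#' Spearman rank correlation (average ranks for ties) with a two-sided
#' p-value for every unordered pair of layers, using pairwise-complete
#' polygons. Pairs with fewer than 3 complete polygons yield `NA` with a
#' warning. p-values are reported descriptively without multiple-testing
#' correction (set `p_adjust` to a [stats::p.adjust] method to switch it
#' on).
#'
#' @param layers named list of [value_layer]s over one polygon universe.
#' @param p_adjust `"none"` (default) or a `p.adjust` method.
#' @return data frame with `var_a`, `var_b`, `rho`, `p`, `n`.
#' @export
spearman_matrix <- function(layers, p_adjust = "none") {
  m <- layers_matrix(layers)
  nm <- colnames(m)
  pairs <- utils::combn(length(nm), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- m[, i]; b <- m[, j]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) {
      warning("fewer than 3 pairwise-complete polygons for ",
              nm[i], " vs ", nm[j])
      return(data.frame(var_a = nm[i], var_b = nm[j], rho = NA_real_,
                        p = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(
      cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
    data.frame(var_a = nm[i], var_b = nm[j],
               rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (p_adjust != "none") out$p <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Combine normalized layers with equal weight
#'
#' Per polygon, the sum of the (min-max normalized) input layers, so `k`
#' layers span `[0, k]`. A missing value in any input makes the combined
#' value missing -- imputing here would manufacture hot/coldspots.
#'
#' @param layers list of normalized [value_layer]s.
#' @param variable_name name of the combined layer.
#' @return a [value_layer] (not flagged normalized; range is `[0, k]`).
#' @export
combine_equal_weight <- function(layers, variable_name = "combined") {
  if (!all(vapply(layers, is_normalized, logical(1))))
    stop("all layers must be normalized before combination")
  m <- layers_matrix(layers)
  total <- rowSums(m)
  n_miss <- sum(is.na(total) & rowSums(!is.na(m)) > 0)
  if (n_miss > 0)
    message(n_miss, " polygon(s) missing in the combined layer ",
            "due to missing inputs")
  value_layer(rownames(m), unname(total), variable_name)
}

#' Population density in a buffer ring around the study area
#'
#' Buffers the study-area boundary outward by `buffer_m`, subtracts the
#' area itself, and reports inhabitants per square kilometer inside the
#' resulting ring, optionally split into a southern and a northern zone at
#' a dividing northing. The ring is evaluated numerically: membership is
#' "outside the boundary polygon and within `buffer_m` of its edge", and
#' the ring area is integrated on a fine point lattice (step
#' `buffer_m / 40` by default), which keeps the operation free of an
#' exact polygon-offsetting dependency.
#'
#' @param population_points data frame with `x`, `y` and a `weight`
#'   column of inhabitants per point.
#' @param boundary polygon geometry (ring list) or one-row [ses_polygons].
#' @param buffer_m buffer distance in meters (> 0).
#' @param split_y optional northing; zones `south` (`y < split_y`) and
#'   `north` are reported separately.
#' @param quad_step_m lattice step for the area quadrature.
#' @return data frame with `zone`, `inhabitants`, `area_km2`,
#'   `density_per_km2`.
#' @export
buffer_population_density <- function(population_points, boundary, buffer_m,
                                      split_y = NULL,
                                      quad_step_m = buffer_m / 40) {
  stopifnot(buffer_m > 0)
  rings <- boundary_rings(boundary)
  in_ring <- function(px, py) {
    inside <- as.logical(points_in_rings_batch(px, py, rings))
    d <- cpp_dist_to_rings(px, py, rings)
    !inside & d <= buffer_m
  }
  bb <- rings_bbox(rings)
  spanx <- bb["xmax"] - bb["xmin"] + 2 * buffer_m
  spany <- bb["ymax"] - bb["ymin"] + 2 * buffer_m
  if (spanx * spany / quad_step_m^2 > 1e6)  # cap the quadrature lattice
    quad_step_m <- sqrt(spanx * spany / 1e6)
  xs <- seq(bb["xmin"] - buffer_m + quad_step_m / 2,
            bb["xmax"] + buffer_m, by = quad_step_m)
  ys <- seq(bb["ymin"] - buffer_m + quad_step_m / 2,
            bb["ymax"] + buffer_m, by = quad_step_m)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  keep <- in_ring(gx, gy)
  if (!any(keep)) stop("empty buffer ring")
  cell_km2 <- (quad_step_m / 1000)^2
  w <- population_points$weight %||% rep(1, nrow(population_points))
  pin <- if (nrow(population_points)) {
    in_ring(population_points$x, population_points$y)
  } else logical(0)
  zone_of <- function(y) {
    if (is.null(split_y)) rep("all", length(y))
    else ifelse(y < split_y, "south", "north")
  }
  zones <- if (is.null(split_y)) "all" else c("south", "north")
  out <- lapply(zones, function(z) {
    zarea <- sum(keep & zone_of(gy) == z) * cell_km2
    zpop <- if (length(pin)) {
      sum(w[pin & zone_of(population_points$y) == z])
    } else 0
    data.frame(zone = z, inhabitants = zpop, area_km2 = zarea,
               density_per_km2 = if (zarea > 0) zpop / zarea else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
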