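# Quantile hot/coldspot delineation, Jaccard spatial overlap on the
# analysis grid, and overlay-area accounting.

#' Delineate hotspots and coldspots by rank quantile
#'
#' Ranks the polygons of a layer and labels the top `hot_fraction` as
#' `hot`, the bottom `cold_fraction` as `cold` and the remainder
#' `neutral` (defaults: thirds). Missing polygons are labeled `missing`.
#' Rank quantiles (equal polygon counts) are the default delineation;
#' `mode = "value_range"` instead cuts the value range itself into
#' thirds. Ties at a class threshold all take that class's label (the
#' side of the boundary the tied value falls on), which can make class
#' sizes unequal -- this is logged via a message. A polygon tied into
#' both classes at once, or an all-tied layer, is neutral (warned).
#'
#' @param layer a [value_layer] with at least 3 non-missing polygons.
#' @param hot_fraction,cold_fraction class fractions, default 1/3 each.
#' @param mode `"quantile"` (default) or `"value_range"`.
#' @return a `hotcold_map` data frame with `polygon_id`, `label`.
#' @export
delineate_hotcold <- function(layer, hot_fraction = 1 / 3,
                              cold_fraction = 1 / 3,
                              mode = c("quantile", "value_range")) {
  mode <- match.arg(mode)
  stopifnot(hot_fraction > 0, cold_fraction > 0,
            hot_fraction + cold_fraction <= 1)
  v <- layer$value
  ok <- !is.na(v)
  if (sum(ok) < 3) stop("need at least 3 non-missing polygons")
  lab <- rep("missing", length(v))
  vv <- v[ok]
  if (diff(range(vv)) == 0) {
    warning("all values tied; no hot/coldspots delineated")
    lab[ok] <- "neutral"
  } else if (mode == "quantile") {
    n <- length(vv)
    n_hot <- max(1L, round(hot_fraction * n))
    n_cold <- max(1L, round(cold_fraction * n))
    hot_thr <- sort(vv, decreasing = TRUE)[n_hot]
    cold_thr <- sort(vv)[n_cold]
    is_hot <- vv >= hot_thr
    is_cold <- vv <= cold_thr
    both <- is_hot & is_cold
    if (any(both)) {
      warning(sum(both), " polygon(s) tied into both classes; set neutral")
      is_hot[both] <- is_cold[both] <- FALSE
    }
    if (sum(is_hot) != n_hot || sum(is_cold) != n_cold)
      message(sprintf(
        "ties at threshold: %d hot / %d cold (target %d / %d)",
        sum(is_hot), sum(is_cold), n_hot, n_cold))
    lab[ok] <- ifelse(is_hot, "hot", ifelse(is_cold, "cold", "neutral"))
  } else {
    rng <- range(vv)
    hot_thr <- rng[2] - hot_fraction * diff(rng)
    cold_thr <- rng[1] + cold_fraction * diff(rng)
    lab[ok] <- ifelse(vv >= hot_thr, "hot",
                      ifelse(vv <= cold_thr, "cold", "neutral"))
  }
  out <- data.frame(polygon_id = layer$polygon_id, label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "variable_name") <- variable_name(layer)
  attr(out, "hot_fraction") <- hot_fraction
  attr(out, "cold_fraction") <- cold_fraction
  class(out) <- c("hotcold_map", "data.frame")
  out
}

#' @export
print.hotcold_map <- function(x, ...) {
  tb <- table(factor(x$label, c("hot", "neutral", "cold", "missing")))
  cat(sprintf("<hotcold_map> '%s': %d hot / %d neutral / %d cold / %d missing\n",
              attr(x, "variable_name"), tb["hot"], tb["neutral"], tb["cold"],
              tb["missing"]))
  invisible(x)
}

hotcold_codes <- c(cold = -1, neutral = 0, hot = 1)

#' Rasterize a hot/cold map onto the analysis grid
#'
#' Transfers polygon labels to grid cells by the cell-center rule
#' (hot = 1, neutral = 0, cold = -1; missing polygons and cells outside
#' every polygon are no-data).
#'
#' @param map a `hotcold_map`.
#' @param polygons the matching [ses_polygons] layer.
#' @param grid the shared `ses_grid`.
#' @param cells optional precomputed [polygon_cells] list.
#' @return a `ses_raster` of label codes.
#' @export
rasterize_hotcold <- function(map, polygons, grid, cells = NULL) {
  lab <- setNames(map$label, map$polygon_id)[polygons$id]
  code <- unname(hotcold_codes[lab])  # missing -> NA
  if (is.null(cells)) {
    rasterize_labels(polygons$geometry, code, grid)
  } else {
    tv <- rep(NA_real_, grid$nrow * grid$ncol)
    for (k in seq_along(cells)) if (!is.na(code[k])) tv[cells[[k]]] <- code[k]
    new_raster(matrix(tv, grid$nrow, grid$ncol, byrow = TRUE), grid)
  }
}

#' Cell set carrying a given label
#'
#' @param raster a label raster from [rasterize_hotcold].
#' @param which `"hot"` or `"cold"`.
#' @return integer vector of row-major cell ids.
#' @export
hotcold_cells <- function(raster, which = c("hot", "cold")) {
  which <- match.arg(which)
  code <- hotcold_codes[which]
  tv <- t(raster$values)
  which(!is.na(tv) & tv == code)
}

#' Jaccard spatial-overlap coefficient
#'
#' `J = |A intersect B| / |A union B| * 100` over grid-cell sets: the
#' share of hot (or cold) cells common to two layers among all cells that
#' are hot (cold) in either. Two empty sets are defined as 0% overlap
#' with a warning (rather than undefined) so batch runs stay total.
#'
#' @param cells_a,cells_b integer cell-id sets on the same grid.
#' @return overlap percentage in `[0, 100]`.
#' @export
jaccard_coefficient <- function(cells_a, cells_b) {
  a <- unique(cells_a)
  b <- unique(cells_b)
  uni <- length(a) + length(b) - sum(a %in% b)
  if (uni == 0L) {
    warning("both cell sets empty; Jaccard defined as 0")
    return(0)
  }
  100 * sum(a %in% b) / uni
}

#' Interpretation band of a Jaccard percentage
#'
#' Half-open bins: `[0,20)` very low, `[20,40)` low, `[40,60)` moderate,
#' `[60,80)` high, `[80,100]` very high (a value exactly at 20 is "low").
#'
#' @param j Jaccard percentage(s) in `[0, 100]`.
#' @return character band label(s).
#' @export
band_overlap <- function(j) {
  stopifnot(all(j >= 0 & j <= 100))
  bands <- c("very low", "low", "moderate", "high", "very high")
  bands[pmin(findInterval(j, c(0, 20, 40, 60, 80)), 5L)]
}

#' Pairwise Jaccard overlap table for hot/cold maps
#'
#' Computes, for every unordered pair of maps, the hot-hot and cold-cold
#' Jaccard percentages with their interpretation bands and shared/union
#' cell counts. Overlap is computed on 20 m grid cells by default
#' (`mode = "cells"`); `mode = "polygons"` uses polygon ids as the units
#' instead (agreeing with the cell mode up to discretization when labels
#' are polygon-constant).
#'
#' @param maps named list of `hotcold_map`s over one polygon universe.
#' @param polygons the matching [ses_polygons] layer.
#' @param grid the shared `ses_grid` (needed for `mode = "cells"`).
#' @param mode `"cells"` or `"polygons"`.
#' @param cells optional precomputed [polygon_cells] list.
#' @return data frame with `var_a`, `var_b`, `jaccard_hot`,
#'   `jaccard_cold`, `band_hot`, `band_cold`, and shared/union counts.
#' @export
jaccard_table <- function(maps, polygons, grid = NULL,
                          mode = c("cells", "polygons"), cells = NULL) {
  mode <- match.arg(mode)
  nm <- names(maps)
  if (is.null(nm))
    nm <- vapply(maps, function(m) attr(m, "variable_name"), character(1))
  sets <- lapply(maps, function(m) {
    if (mode == "cells") {
      if (is.null(grid)) stop("grid required for cell-based Jaccard")
      r <- rasterize_hotcold(m, polygons, grid, cells = cells)
      list(hot = hotcold_cells(r, "hot"), cold = hotcold_cells(r, "cold"))
    } else {
      list(hot = which(m$label == "hot"), cold = which(m$label == "cold"))
    }
  })
  pr <- utils::combn(length(maps), 2)
  out <- lapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1, k]; j <- pr[2, k]
    jh <- suppressWarnings(jaccard_coefficient(sets[[i]]$hot, sets[[j]]$hot))
    jc <- suppressWarnings(jaccard_coefficient(sets[[i]]$cold, sets[[j]]$cold))
    data.frame(
      var_a = nm[i], var_b = nm[j],
      jaccard_hot = jh, jaccard_cold = jc,
      band_hot = band_overlap(jh), band_cold = band_overlap(jc),
      shared_hot = sum(sets[[i]]$hot %in% sets[[j]]$hot),
      union_hot = length(unique(c(sets[[i]]$hot, sets[[j]]$hot))),
      shared_cold = sum(sets[[i]]$cold %in% sets[[j]]$cold),
      union_cold = length(unique(c(sets[[i]]$cold, sets[[j]]$cold))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overlay-area accounting for two hot/cold maps
#'
#' Hectare totals of every combination of the two maps' states
#' ({hot, neutral, cold} x {hot, neutral, cold}), computed from polygon
#' areas; the nine cells partition the total polygon area (missing
#' polygons are reported separately under `missing`).
#'
#' @param map_a,map_b `hotcold_map`s over the same polygon universe.
#' @param polygons the matching [ses_polygons] layer.
#' @return data frame with `state_a`, `state_b`, `area_ha`.
#' @export
overlay_areas <- function(map_a, map_b, polygons) {
  la <- setNames(map_a$label, map_a$polygon_id)[polygons$id]
  lb <- setNames(map_b$label, map_b$polygon_id)[polygons$id]
  if (anyNA(la) || anyNA(lb)) stop("maps do not cover the polygon universe")
  states <- c("hot", "neutral", "cold", "missing")
  fa <- factor(la, states)
  fb <- factor(lb, states)
  tab <- tapply(polygons$area_ha, list(fa, fb), sum, default = 0)
  out <- expand.grid(state_a = states, state_b = states,
                     stringsAsFactors = FALSE)
  out$area_ha <- unname(
    mapply(function(a, b) tab[a, b], out$state_a, out$state_b))
  # drop missing-state rows unless they actually carry area
  keep <- (out$state_a != "missing" & out$state_b != "missing") |
    out$area_ha > 0
  out[keep, ]
}

#' Mean social-vs-ecological overlap
#'
#' Arithmetic mean of the hot and cold Jaccard percentages over a subset
#' of pairwise overlap results (canonically the four social x ecological
#' pairs).
#'
#' @param results a [jaccard_table] data frame.
#' @param pairs optional two-column matrix/data frame of variable-name
#'   pairs selecting the subset (order-insensitive); default: all rows.
#' @return named numeric `c(mean_hot, mean_cold)`.
#' @export
mean_pairwise_overlap <- function(results, pairs = NULL) {
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    sel <- key(results$var_a, results$var_b) %in% key(pairs[, 1], pairs[, 2])
    results <- results[sel, ]
  }
  if (nrow(results) == 0L) stop("empty pair subset")
  c(mean_hot = mean(results$jaccard_hot),
    mean_cold = mean(results$jaccard_cold))
}
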