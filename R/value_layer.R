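# Value layers: the per-polygon quantities every stage of the pipeline
# exchanges. A layer maps polygon ids to a numeric value (possibly NA =
# missing) and records its variable name and whether it is normalized.

#' Construct a value layer
#'
#' @param polygon_id character vector of polygon ids (unique).
#' @param value numeric vector aligned with `polygon_id`; `NA` = missing.
#' @param variable_name name of the measured variable.
#' @param normalized logical; `TRUE` once min-max scaled to `[0, 1]`.
#' @return a `value_layer` data frame with columns `polygon_id`, `value`.
#' @export
value_layer <- function(polygon_id, value, variable_name = "value",
                        normalized = FALSE) {
  polygon_id <- as.character(polygon_id)
  if (anyDuplicated(polygon_id))
    stop("duplicate polygon ids in value layer")
  value <- as.numeric(value)
  if (length(value) != length(polygon_id))
    stop("polygon_id and value lengths differ")
  if (normalized) {
    ok <- value[!is.na(value)]
    if (length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
      stop("normalized layer has values outside [0, 1]")
  }
  df <- data.frame(polygon_id = polygon_id, value = value,
                   stringsAsFactors = FALSE)
  attr(df, "variable_name") <- variable_name
  attr(df, "normalized") <- normalized
  class(df) <- c("value_layer", "data.frame")
  df
}

#' @export
print.value_layer <- function(x, ...) {
  v <- x$value
  cat(sprintf("<value_layer> '%s'%s: %d polygons, %d missing, range %s\n",
              variable_name(x),
              if (attr(x, "normalized")) " (normalized)" else "",
              nrow(x), sum(is.na(v)),
              if (all(is.na(v))) "-" else
                sprintf("[%.4g, %.4g]", min(v, na.rm = TRUE),
                        max(v, na.rm = TRUE))))
  invisible(x)
}

#' Layer values as a named vector
#'
#' @param layer a [value_layer].
#' @return numeric vector named by polygon id.
#' @export
layer_values <- function(layer) {
  setNames(layer$value, layer$polygon_id)
}

#' Variable name of a layer
#'
#' @param layer a [value_layer].
#' @export
variable_name <- function(layer) {
  attr(layer, "variable_name")
}

#' Is a layer normalized?
#'
#' @param layer a [value_layer].
#' @export
is_normalized <- function(layer) {
  isTRUE(attr(layer, "normalized"))
}

# align a list of layers on a common polygon-id universe -> matrix
layers_matrix <- function(layers) {
  ids <- layers[[1]]$polygon_id
  for (l in layers[-1]) {
    if (!identical(sort(l$polygon_id), sort(ids)))
      stop("layers cover different polygon universes")
  }
  m <- vapply(layers, function(l) layer_values(l)[ids], numeric(length(ids)))
  rownames(m) <- ids
  nms <- vapply(layers, variable_name, character(1))
  colnames(m) <- make.unique(nms)
  m
}
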