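# Ecological value layers: forest habitat quality from stand inventories
# and urban biodiversity from confidence-weighted expert elicitation.

#' Parameters of the habitat-quality sigmoid
#'
#' The habitat quality index of a forest cell is `f(diameter) * volume`,
#' where `f` is a logistic ramp over mean tree diameter acting as a
#' maturity indicator: `f(d) = 1 / (1 + exp(-k (d - d0)))`. The midpoint
#' `d0` (cm) is where `f = 0.5`; the steepness `k` (per cm) controls how
#' quickly mature, large-diameter stands approach the saturation value
#' `f = 1`. Defaults (`d0 = 25` cm, `k = 0.2`/cm) put stands above ~40 cm
#' essentially at saturation, so mature forest scores close to its full
#' standing volume.
#'
#' @param midpoint_diameter_cm logistic midpoint, cm (> 0).
#' @param steepness_per_cm logistic steepness, 1/cm (> 0).
#' @return a `habitat_quality_params` list.
#' @export
habitat_quality_params <- function(midpoint_diameter_cm = 25,
                                   steepness_per_cm = 0.2) {
  stopifnot(midpoint_diameter_cm > 0, steepness_per_cm > 0)
  structure(list(midpoint_diameter_cm = midpoint_diameter_cm,
                 steepness_per_cm = steepness_per_cm),
            class = "habitat_quality_params")
}

#' Forest habitat quality index
#'
#' `index = f(mean_diameter) * volume` with `f` the configured logistic
#' (see [habitat_quality_params]): zero at zero volume, bounded above by
#' the volume, and strictly increasing in each argument when the other is
#' positive.
#'
#' @param mean_diameter_cm mean tree diameter, cm (>= 0); vectorized.
#' @param volume_m3_per_ha standing wood volume, m3/ha (>= 0); vectorized.
#' @param params a [habitat_quality_params].
#' @return numeric index values (same units as volume).
#' @examples
#' habitat_quality_index(25, 200)  # f(midpoint) = 0.5 -> 100
#' @export
habitat_quality_index <- function(mean_diameter_cm, volume_m3_per_ha,
                                  params = habitat_quality_params()) {
  if (any(mean_diameter_cm < 0, na.rm = TRUE))
    stop("mean_diameter_cm must be nonnegative")
  if (any(volume_m3_per_ha < 0, na.rm = TRUE))
    stop("volume_m3_per_ha must be nonnegative")
  f <- 1 / (1 + exp(-params$steepness_per_cm *
                      (mean_diameter_cm - params$midpoint_diameter_cm)))
  f * volume_m3_per_ha
}

#' Forest habitat quality per polygon
#'
#' Rasterizes the per-stand habitat quality index onto the shared 20 m
#' grid (cell-center rule, later stands win on overlap) and takes the
#' zonal mean per polygon. Cells outside every stand are non-forest; by
#' default they count as zeros within a polygon (`non_forest = "zero"`),
#' so polygons dominated by fields or other open habitats score low
#' rather than dropping out. With `non_forest = "missing"` such cells are
#' excluded from the mean and fully non-forested polygons become `NA`.
#'
#' @param stands a [ses_polygons] layer with attribute columns
#'   `mean_diameter_cm` and `volume_m3_per_ha`.
#' @param grid the shared `ses_grid`.
#' @param polygons analysis polygons.
#' @param params a [habitat_quality_params].
#' @param non_forest `"zero"` (default) or `"missing"`.
#' @param cells optional precomputed [polygon_cells] list.
#' @return a [value_layer] named `"forest_habitat_quality"`.
#' @export
habitat_quality_layer <- function(stands, grid, polygons,
                                  params = habitat_quality_params(),
                                  non_forest = c("zero", "missing"),
                                  cells = NULL) {
  non_forest <- match.arg(non_forest)
  if (nrow(stands) == 0L) {
    vals <- if (non_forest == "zero") 0 else NA_real_
    return(value_layer(polygons$id, rep(vals, nrow(polygons)),
                       "forest_habitat_quality"))
  }
  idx <- habitat_quality_index(stands$mean_diameter_cm,
                               stands$volume_m3_per_ha, params)
  rast <- rasterize_labels(stands$geometry, idx, grid)
  lay <- zonal_mean(rast, polygons, "forest_habitat_quality", cells = cells,
                    na_as_zero = (non_forest == "zero"))
  if (non_forest == "zero") lay$value[is.na(lay$value)] <- 0
  lay
}

# ---- expert biodiversity scoring --------------------------------------

#' Confidence levels of the expert questionnaire
#'
#' Map from the five self-rated confidence labels to the numeric weights
#' used in the analysis.
#' @export
confidence_levels <- function() {
  c("very unconfident" = 0, "unconfident" = 1, "somewhat unconfident" = 2,
    "somewhat confident" = 4, "very confident" = 8)
}

#' Validate an expert-response table
#'
#' Checks the required columns and the scoring domains (score 0-4,
#' confidence in {0, 1, 2, 4, 8}), reporting offending row numbers.
#'
#' @param responses expert-response data frame.
#' @return the validated table, invisibly unchanged.
#' @export
validate_expert_responses <- function(responses) {
  need <- c("expert_id", "taxon", "biotope", "attribute", "score",
            "confidence")
  if (!all(need %in% names(responses)))
    stop("expert responses must have columns: ", paste(need, collapse = ", "))
  bad <- which(!(responses$score %in% 0:4))
  if (length(bad))
    stop("expert score outside 0-4 at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  bad <- which(!(responses$confidence %in% c(0, 1, 2, 4, 8)))
  if (length(bad))
    stop("expert confidence outside {0,1,2,4,8} at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  responses
}

#' Confidence-weighted biodiversity score of one biotope
#'
#' Each response contributes its support score (0-4) multiplied by its
#' confidence weight (0/1/2/4/8); the biotope score is the arithmetic mean
#' of these weighted values over all (expert, taxon, attribute) responses
#' for the biotope, spanning the theoretical range 0 (no support and/or
#' all answers at the lowest confidence) to 32 (top support with top
#' confidence throughout). The product-then-mean scheme is the default
#' because only it attains that 0-32 range; `scheme = "weighted_mean"`
#' computes `sum(score * conf) / sum(conf)` (range 0-4) instead, and
#' `scheme = "hierarchical"` averages score*confidence within each taxon
#' before averaging across taxa.
#'
#' @param responses expert-response data frame (`expert_id`, `taxon`,
#'   `biotope`, `attribute`, `score`, `confidence`). Zero-confidence
#'   responses are included (they pull the mean toward 0).
#' @param biotope biotope class code to score.
#' @param scheme `"product_mean"` (default), `"weighted_mean"` or
#'   `"hierarchical"`.
#' @return the biotope score, or `NA` with a warning when the biotope has
#'   no responses.
#' @export
confidence_weighted_biotope_score <- function(responses, biotope,
                                              scheme = c("product_mean",
                                                         "weighted_mean",
                                                         "hierarchical")) {
  scheme <- match.arg(scheme)
  responses <- validate_expert_responses(responses)
  sub <- responses[responses$biotope == biotope, ]
  if (nrow(sub) == 0L) {
    warning("no expert responses for biotope '", biotope, "'")
    return(NA_real_)
  }
  switch(scheme,
    product_mean = mean(sub$score * sub$confidence),
    weighted_mean = if (sum(sub$confidence) == 0) 0 else
      sum(sub$score * sub$confidence) / sum(sub$confidence),
    hierarchical = mean(tapply(sub$score * sub$confidence, sub$taxon, mean)))
}

#' Score every biotope in an expert table
#'
#' @inheritParams confidence_weighted_biotope_score
#' @return data frame with `biotope`, `score`.
#' @export
biotope_score_table <- function(responses,
                                scheme = c("product_mean", "weighted_mean",
                                           "hierarchical")) {
  scheme <- match.arg(scheme)
  responses <- validate_expert_responses(responses)
  biotopes <- sort(unique(responses$biotope))
  data.frame(
    biotope = biotopes,
    score = vapply(biotopes, function(b)
      suppressWarnings(
        confidence_weighted_biotope_score(responses, b, scheme)),
      numeric(1)),
    stringsAsFactors = FALSE)
}

#' Urban biodiversity per polygon
#'
#' Assigns each raster cell the confidence-weighted score of its biotope
#' class and takes the zonal mean per polygon. Biotope codes present in
#' the raster but absent from the expert table leave their cells missing
#' (with a warning); polygon means are taken over the remaining cells.
#'
#' @param responses expert-response data frame.
#' @param biotope_raster `ses_raster` of integer biotope class codes.
#' @param polygons analysis polygons.
#' @param scheme scoring scheme, see [confidence_weighted_biotope_score].
#' @param cells optional precomputed [polygon_cells] list.
#' @return a [value_layer] named `"urban_biodiversity"`.
#' @export
biodiversity_layer <- function(responses, biotope_raster, polygons,
                               scheme = c("product_mean", "weighted_mean",
                                          "hierarchical"),
                               cells = NULL) {
  scheme <- match.arg(scheme)
  scores <- biotope_score_table(responses, scheme)
  codes <- biotope_raster$values
  in_raster <- sort(unique(as.vector(codes[!is.na(codes)])))
  unscored <- setdiff(in_raster, scores$biotope)
  if (length(unscored))
    warning("biotope class(es) in raster without expert responses: ",
            paste(unscored, collapse = ", "), "; their cells left missing")
  score_of <- setNames(scores$score, scores$biotope)
  vals <- matrix(score_of[as.character(codes)], nrow(codes), ncol(codes))
  score_raster <- new_raster(vals, biotope_raster$grid)
  zonal_mean(score_raster, polygons, "urban_biodiversity", cells = cells)
}
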