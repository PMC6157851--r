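# Management-strategy classification: cross the landscape-value,
# visitor-use and combined-ecological hot/cold states of each polygon and
# attach the matching strategy text from the packaged eight-cell matrix.

#' Load the management-strategy lookup table
#'
#' The packaged eight-cell matrix of management strategies for the
#' {high, low} landscape-value x visitor-use x ecological-value
#' combinations. Stored as an editable CSV resource rather than
#' hard-coded, since strategy wording is guidance, not an exhaustive
#' prescription.
#'
#' @param path optional path to a custom strategy CSV with columns
#'   `landscape_state`, `use_state`, `ecological_state`, `strategy`.
#' @return data frame of 8 strategy cells.
#' @export
strategy_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "strategy_table.csv", package = "sesmap")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("landscape_state", "use_state", "ecological_state", "strategy")
  if (!all(need %in% names(tab)))
    stop("strategy table must have columns: ", paste(need, collapse = ", "))
  combos <- with(tab, paste(landscape_state, use_state, ecological_state))
  want <- apply(expand.grid(c("high", "low"), c("high", "low"),
                            c("high", "low")), 1, paste, collapse = " ")
  if (!setequal(combos, want) || anyDuplicated(combos))
    stop("strategy table must define exactly the 8 {high,low}^3 cells")
  tab
}

state_of_label <- function(label) {
  ifelse(label == "hot", "high", ifelse(label == "cold", "low", "other"))
}

#' Classify polygons into management strategies
#'
#' Maps each polygon's hot/cold state in the landscape-value, visitor-use
#' and combined-ecological layers to {high, low, other} (hot = high,
#' cold = low, neutral or missing = other) and attaches the strategy text
#' for the eight {high, low}^3 combinations. Polygons with any `other`
#' state receive no strategy: the matrix applies to hot/coldspots only,
#' and the states form a continuum that a forced nearest-cell label would
#' overstate.
#'
#' @param lv_map,use_map,eco_map `hotcold_map`s over the same polygons
#'   (landscape values, visitor use, combined ecological value).
#' @param strategies strategy lookup from [strategy_table].
#' @return data frame with `polygon_id`, `landscape_state`, `use_state`,
#'   `ecological_state`, `strategy` (`NA` where any state is `other`).
#' @export
classify_strategies <- function(lv_map, use_map, eco_map,
                                strategies = strategy_table()) {
  ids <- lv_map$polygon_id
  if (!setequal(ids, use_map$polygon_id) ||
      !setequal(ids, eco_map$polygon_id))
    stop("hot/cold maps cover different polygon universes")
  lv <- setNames(lv_map$label, lv_map$polygon_id)[ids]
  us <- setNames(use_map$label, use_map$polygon_id)[ids]
  ec <- setNames(eco_map$label, eco_map$polygon_id)[ids]
  out <- data.frame(polygon_id = ids,
                    landscape_state = state_of_label(lv),
                    use_state = state_of_label(us),
                    ecological_state = state_of_label(ec),
                    stringsAsFactors = FALSE)
  key <- function(a, b, c) paste(a, b, c, sep = "|")
  lut <- setNames(strategies$strategy,
                  key(strategies$landscape_state, strategies$use_state,
                      strategies$ecological_state))
  out$strategy <- unname(lut[key(out$landscape_state, out$use_state,
                                 out$ecological_state)])
  rownames(out) <- NULL
  out
}

#' Write the pipeline report
#'
#' Emits a deterministic, human-readable Markdown report (layer
#' summaries, correlation table, Jaccard overlap table, overlay areas,
#' strategy counts) plus a machine-readable CSV bundle.
#'
#' @param results an analysis-results list from [analyze_landscape].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
build_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  layer_df <- do.call(rbind, lapply(results$layers, function(l)
    data.frame(variable = variable_name(l), n = nrow(l),
               missing = sum(is.na(l$value)),
               min = suppressWarnings(min(l$value, na.rm = TRUE)),
               mean = mean(l$value, na.rm = TRUE),
               max = suppressWarnings(max(l$value, na.rm = TRUE)))))
  rownames(layer_df) <- NULL
  wcsv(layer_df, "layer_summary.csv")
  wcsv(results$correlations, "correlations.csv")
  wcsv(results$jaccard, "jaccard.csv")
  wcsv(results$overlay_areas, "overlay_areas.csv")
  wcsv(results$strategies, "strategies.csv")
  hc <- do.call(rbind, lapply(names(results$hotcold), function(nm) {
    m <- results$hotcold[[nm]]
    data.frame(variable = nm, polygon_id = m$polygon_id, label = m$label,
               stringsAsFactors = FALSE)
  }))
  wcsv(hc, "hotcold_labels.csv")

  fmt_tab <- function(df) {
    df <- as.data.frame(lapply(df, function(c)
      if (is.numeric(c)) signif(c, 4) else c))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  strat_counts <- table(ifelse(is.na(results$strategies$strategy), "other",
                               paste(results$strategies$landscape_state,
                                     results$strategies$use_state,
                                     results$strategies$ecological_state,
                                     sep = "/")))
  md <- c(
    "# Social-ecological hot/coldspot report", "",
    sprintf("Polygons: %d (%.1f ha). Tracks: %d.",
            nrow(results$polygons), sum(results$polygons$area_ha),
            results$n_tracks), "",
    "## Layer summaries", "", fmt_tab(layer_df), "",
    "## Spearman correlations", "", fmt_tab(results$correlations), "",
    "## Jaccard overlap of hot/coldspots (%)", "",
    fmt_tab(results$jaccard[, c("var_a", "var_b", "jaccard_hot",
                                "band_hot", "jaccard_cold", "band_cold")]),
    "",
    sprintf("Mean social-vs-ecological overlap: %.1f%% (hot), %.1f%% (cold).",
            results$mean_social_eco["mean_hot"],
            results$mean_social_eco["mean_cold"]), "",
    "## Overlay areas (ha)", "", fmt_tab(results$overlay_areas), "",
    "## Strategy counts", "",
    fmt_tab(data.frame(cell = names(strat_counts),
                       n = as.integer(strat_counts))), "")
  rp <- file.path(out_dir, "report.md")
  writeLines(md, rp)
  invisible(c(paths, rp))
}
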