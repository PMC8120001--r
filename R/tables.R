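# Tabular export with documented, stable schemas and deterministic row
# order (fish, then track, then frame).

detections_table <- function(detections, fish = "fish_1") {
  if (!length(detections))
    return(data.frame(fish = character(0), frame = integer(0),
                      channel_role = character(0), object_id = integer(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      area_um2 = numeric(0)))
  do.call(rbind, lapply(detections, function(d)
    data.frame(fish = fish, frame = d$frame, channel_role = d$lineage,
               object_id = d$object_id,
               centroid_x_um = unname(d$centroid_um[1]),
               centroid_y_um = unname(d$centroid_um[2]),
               area_um2 = d$area_um2)))
}

tracks_table <- function(tracks, fish = "fish_1") {
  if (!length(tracks))
    return(data.frame(fish = character(0), track_id = integer(0),
                      lineage = character(0), frame = integer(0),
                      object_id = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0)))
  do.call(rbind, lapply(tracks, function(tr)
    data.frame(fish = fish, track_id = tr$track_id, lineage = tr$lineage,
               frame = tr$frames,
               object_id = vapply(tr$detections, `[[`, integer(1), "object_id"),
               centroid_x_um = vapply(tr$detections,
                                      function(d) unname(d$centroid_um[1]),
                                      numeric(1)),
               centroid_y_um = vapply(tr$detections,
                                      function(d) unname(d$centroid_um[2]),
                                      numeric(1)))))
}

#' Write all pipeline outputs as CSV files
#'
#' Writes `detections.csv`, `tracks.csv`, `distances.csv`, `events.csv`,
#' `metrics.csv` and `summary.csv` with fixed column schemas. Rows are
#' sorted by fish, then track, then frame; an empty component yields a
#' header-only file.
#'
#' @param results A list as returned by [analyse_movie()] (fields
#'   `detections`, `tracks`, `distances`, `events`, `metrics`, `summary`,
#'   `fish`), or a list of such lists for several fish.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  if (!is.null(results$fish)) results <- list(results)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  pull <- function(what, build) {
    parts <- lapply(results, build)
    df <- do.call(rbind, parts)
    df
  }
  sort_by <- function(df, cols) {
    cols <- intersect(cols, names(df))
    if (!nrow(df) || !length(cols)) return(df)
    df[do.call(order, df[cols]), , drop = FALSE]
  }
  add_fish <- function(df, fish) {
    if (nrow(df)) cbind(fish = fish, df)
    else cbind(data.frame(fish = character(0)), df)
  }
  tables <- list(
    detections = sort_by(pull("detections", function(r)
      detections_table(r$detections, r$fish)),
      c("fish", "frame", "channel_role", "object_id")),
    tracks = sort_by(pull("tracks", function(r)
      tracks_table(r$tracks, r$fish)), c("fish", "track_id", "frame")),
    distances = sort_by(pull("distances", function(r)
      add_fish(r$distances, r$fish)),
      c("fish", "track_id", "lesion_id", "frame")),
    events = sort_by(pull("events", function(r)
      add_fish(r$events, r$fish)),
      c("fish", "track_id", "lesion_id", "start_frame")),
    metrics = sort_by(pull("metrics", function(r)
      add_fish(r$metrics, r$fish)), c("fish", "track_id")),
    summary = sort_by(pull("summary", function(r)
      add_fish(r$summary$per_lineage, r$fish)), c("fish", "lineage")))
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], path, row.names = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}
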