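# Cell-lesion interaction analysis. The per-frame surface-to-surface
# distance is the minimum, over a detection's boundary pixels, of the
# lesion's signed distance field; the measured surface is the cytoplasmic
# margin for neutrophils and the nuclear margin for macrophages (whose
# cytoplasmic margin is too poorly defined to segment). An interaction
# event is a maximal run of consecutive frames-with-detections whose
# distance is strictly below the lineage threshold (default 20 um for
# neutrophils, 50 um for macrophage nuclei); it is a "contact" if the cell
# surface overlaps or touches the lesion at any frame of the run, otherwise
# "close".

#' Per-frame cell-to-lesion surface distances
#'
#' For each (track, lesion, frame-with-detection) the distance is
#' `max(0, min over boundary pixels of the signed field)` in um, with an
#' `overlap` flag set when the raw minimum is <= 0 (the object overlaps or
#' touches the lesion surface).
#'
#' @param tracks List of `ls_track`.
#' @param lesion_series One `ls_lesion_series` or a list of them.
#' @return Data frame with columns `track_id`, `lesion_id`, `lineage`,
#'   `frame`, `distance_um`, `overlap`.
#' @export
measure_distances <- function(tracks, lesion_series) {
  if (inherits(lesion_series, "ls_lesion_series"))
    lesion_series <- list(lesion_series)
  rows <- list()
  for (tr in tracks) {
    for (les in lesion_series) {
      if (any(tr$frames >= les$n_frames))
        stop(sprintf("track %s has frames beyond lesion series '%s' (%d frames)",
                     tr$track_id, les$lesion_id, les$n_frames))
      dist <- numeric(length(tr$frames))
      ovl <- logical(length(tr$frames))
      for (k in seq_along(tr$frames)) {
        sdf <- lesion_sdf_at(les, tr$frames[k])
        b <- tr$detections[[k]]$boundary
        raw_min <- min(sdf[cbind(b[, 2] + 1L, b[, 1] + 1L)])
        dist[k] <- max(0, raw_min)
        ovl[k] <- raw_min <= 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = tr$track_id, lesion_id = les$lesion_id,
        lineage = tr$lineage, frame = tr$frames,
        distance_um = dist, overlap = ovl)
    }
  }
  if (!length(rows))
    return(data.frame(track_id = integer(0), lesion_id = character(0),
                      lineage = character(0), frame = integer(0),
                      distance_um = numeric(0), overlap = logical(0)))
  do.call(rbind, rows)
}

#' Extract contact / close-proximity interaction events
#'
#' An event is a maximal run of consecutive frames (per track and lesion)
#' with `distance < threshold` for the track's lineage; runs are broken by
#' frames at or above the threshold and by track gaps. The event is classed
#' `contact` if any frame in the run carries the overlap/touch flag, else
#' `close`. Duration of an n-frame run is `n * frame_interval` (each
#' sampled frame represents one sampling interval).
#'
#' @param distance_series Data frame from [measure_distances()].
#' @param thresholds Named numeric vector of strict upper distance bounds in
#'   um per lineage; see [default_thresholds()].
#' @param frame_interval Minutes per frame.
#' @return Data frame with columns `track_id`, `lesion_id`, `lineage`,
#'   `start_frame`, `end_frame` (inclusive), `class`, `min_distance_um`,
#'   `duration_min`.
#' @export
classify_and_extract_events <- function(distance_series,
                                        thresholds = default_thresholds(),
                                        frame_interval = 2) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  empty <- data.frame(track_id = integer(0), lesion_id = character(0),
                      lineage = character(0), start_frame = integer(0),
                      end_frame = integer(0), class = character(0),
                      min_distance_um = numeric(0), duration_min = numeric(0))
  if (!nrow(distance_series)) return(empty)
  rows <- list()
  keys <- interaction(distance_series$track_id, distance_series$lesion_id,
                      drop = TRUE)
  for (grp in split(distance_series, keys)) {
    grp <- grp[order(grp$frame), ]
    lin <- grp$lineage[1]
    if (!lin %in% names(thresholds))
      stop("no threshold for lineage ", lin)
    thr <- thresholds[[lin]]
    below <- grp$distance_um < thr
    # run id increments when 'below' toggles or frames are not consecutive
    brk <- c(TRUE, diff(grp$frame) != 1L | below[-1] != below[-nrow(grp)])
    run <- cumsum(brk)
    for (r in split(seq_len(nrow(grp)), run)) {
      if (!below[r[1]]) next
      sub <- grp[r, ]
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = sub$track_id[1], lesion_id = sub$lesion_id[1],
        lineage = lin, start_frame = min(sub$frame),
        end_frame = max(sub$frame),
        class = if (any(sub$overlap)) "contact" else "close",
        min_distance_um = min(sub$distance_um),
        duration_min = nrow(sub) * frame_interval)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$lesion_id, out$start_frame), , drop = FALSE]
}

#' Summarise interaction events for one movie / fish
#'
#' Per lineage: number of events (contacts and close-proximity separately
#' and combined), the individual event durations, their summed/overall
#' duration, and the number of distinct interacting tracks. A per-lesion
#' breakdown is also returned.
#'
#' @param events Data frame from [classify_and_extract_events()].
#' @param tracks List of `ls_track` (for lineages with zero events).
#' @return List of class `ls_interaction_summary`: `per_lineage` data frame,
#'   `per_lesion` data frame, `durations` (named list of numeric vectors).
#' @export
summarise_interactions <- function(events, tracks = list()) {
  lineages <- sort(unique(c(events$lineage,
                            vapply(tracks, `[[`, character(1), "lineage"))))
  if (!length(lineages)) lineages <- LINEAGES
  per_lineage <- do.call(rbind, lapply(lineages, function(lin) {
    ev <- events[events$lineage == lin, , drop = FALSE]
    data.frame(lineage = lin, n_events = nrow(ev),
               n_contact = sum(ev$class == "contact"),
               n_close = sum(ev$class == "close"),
               total_duration_min = sum(ev$duration_min),
               n_tracks_interacting = length(unique(ev$track_id)))
  }))
  per_lesion <- if (nrow(events)) {
    agg <- aggregate(duration_min ~ lesion_id + lineage, events, sum)
    cnt <- aggregate(start_frame ~ lesion_id + lineage, events, length)
    names(cnt)[3] <- "n_events"
    names(agg)[3] <- "total_duration_min"
    merge(cnt, agg, by = c("lesion_id", "lineage"))
  } else {
    data.frame(lesion_id = character(0), lineage = character(0),
               n_events = integer(0), total_duration_min = numeric(0))
  }
  durations <- lapply(setNames(lineages, lineages), function(lin)
    events$duration_min[events$lineage == lin])
  structure(list(per_lineage = per_lineage, per_lesion = per_lesion,
                 durations = durations),
            class = "ls_interaction_summary")
}

#' @export
print.ls_interaction_summary <- function(x, ...) {
  cat("Interaction summary:\n")
  print(x$per_lineage, row.names = FALSE)
  invisible(x)
}

#' Count objects with centroids inside a physical field of view
#'
#' Counts detections whose centroid lies inside the half-open rectangle
#' `[x0, x1) x [y0, y1)` in um, e.g. the fixed 660 um x 310 um counting
#' region used for per-larva object counts.
#'
#' @param detections List of `ls_detection`.
#' @param fov_rect_um Numeric `c(x0, y0, x1, y1)` in um.
#' @return Integer count.
#' @export
count_in_fov <- function(detections, fov_rect_um) {
  stopifnot(length(fov_rect_um) == 4)
  x0 <- fov_rect_um[1]; y0 <- fov_rect_um[2]
  x1 <- fov_rect_um[3]; y1 <- fov_rect_um[4]
  if (x1 <= x0 || y1 <= y0) stop("degenerate field-of-view rectangle")
  if (!length(detections)) return(0L)
  cent <- t(vapply(detections, `[[`, numeric(2), "centroid_um"))
  sum(cent[, 1] >= x0 & cent[, 1] < x1 & cent[, 2] >= y0 & cent[, 2] < y1)
}
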