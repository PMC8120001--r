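# Track linking: per consecutive frame pair, a minimum-cost one-to-one
# assignment on centroid distance (links above max_link_distance forbidden),
# followed by cheapest-first gap closing across up to max_gap missing
# frames. This mirrors frame-to-frame LAP linking as popularised by
# TrackMate, without merge/split events: segmented immune cells are tracked
# as indivisible objects.

# Solve one frame-pair assignment. Returns an integer vector `link` of
# length n_prev: link[i] = j if prev i is linked to curr j, NA otherwise.
# The padded square LAP makes "no link" available at a cost P chosen so
# that the solver first maximises the number of feasible links and then
# minimises their total distance.
assign_frame_pair <- function(d, max_link_distance) {
  n <- nrow(d); m <- ncol(d)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  feasible <- d <= max_link_distance
  if (!any(feasible)) return(rep(NA_integer_, n))
  BIG <- 1e9
  P <- max_link_distance * (n + m + 1) + 1
  size <- n + m
  cost <- matrix(BIG, size, size)
  cost[seq_len(n), seq_len(m)] <- ifelse(feasible, d, BIG)
  for (i in seq_len(n)) cost[i, m + i] <- P          # prev i unlinked
  for (j in seq_len(m)) cost[n + j, j] <- P          # curr j unlinked
  cost[(n + 1):size, (m + 1):size] <- 0              # dummies pair freely
  sol <- clue::solve_LSAP(cost)
  link <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && feasible[i, j]) link[i] <- j
  }
  link
}

#' Link per-frame detections into tracks
#'
#' Detections are grouped by lineage; within a lineage, consecutive frames
#' are linked by an optimal one-to-one assignment on centroid Euclidean
#' distance (um), with links above `max_link_distance_um` forbidden. Track
#' ends are then closed across up to `max_gap_frames` missing frames using
#' the same distance rule, cheapest pair first. Every detection ends up in
#' exactly one track.
#'
#' @param detections List of `ls_detection` objects (any mix of frames and
#'   lineages).
#' @param max_link_distance_um Maximum centroid displacement per link (um).
#' @param max_gap_frames Maximum number of consecutive missing frames a
#'   track may bridge (0 disables gap closing).
#' @return List of `ls_track` objects: `track_id`, `lineage`, `frames`
#'   (0-based, strictly increasing), `detections`, `gaps` (frame pairs that
#'   were bridged).
#' @export
link_tracks <- function(detections, max_link_distance_um = 30,
                        max_gap_frames = 2) {
  if (max_link_distance_um < 0) stop("max_link_distance_um must be >= 0")
  stopifnot(max_gap_frames >= 0)
  lineages <- unique(vapply(detections, `[[`, character(1), "lineage"))
  tracks <- list()
  for (lin in sort(lineages)) {
    dets <- detections[vapply(detections, function(d) d$lineage == lin,
                              logical(1))]
    tracks <- c(tracks, link_one_lineage(dets, max_link_distance_um,
                                         max_gap_frames))
  }
  for (k in seq_along(tracks)) tracks[[k]]$track_id <- k
  tracks
}

link_one_lineage <- function(dets, max_link, max_gap) {
  if (!length(dets)) return(list())
  frames <- vapply(dets, `[[`, integer(1), "frame")
  by_frame <- split(seq_along(dets), frames)
  frame_keys <- as.integer(names(by_frame))
  # segments as lists of detection indices
  segments <- lapply(by_frame[[1]], function(i) i)
  open <- seq_along(segments)  # segments whose last frame is the previous one
  for (fi in seq_along(frame_keys)[-1]) {
    prev_f <- frame_keys[fi - 1L]; cur_f <- frame_keys[fi]
    cur_idx <- by_frame[[fi]]
    if (cur_f != prev_f + 1L) open <- integer(0)  # no detections in between
    if (length(open)) {
      prev_idx <- vapply(open, function(s) tail(segments[[s]], 1L), integer(1))
      d <- outer(seq_along(prev_idx), seq_along(cur_idx),
                 Vectorize(function(a, b)
                   sqrt(sum((dets[[prev_idx[a]]]$centroid_um -
                             dets[[cur_idx[b]]]$centroid_um)^2))))
      d <- matrix(d, length(prev_idx), length(cur_idx))
      link <- assign_frame_pair(d, max_link)
    } else {
      link <- integer(0)
    }
    new_open <- integer(0)
    linked_curr <- rep(FALSE, length(cur_idx))
    for (a in seq_along(link)) {
      if (!is.na(link[a])) {
        s <- open[a]
        segments[[s]] <- c(segments[[s]], cur_idx[link[a]])
        linked_curr[link[a]] <- TRUE
        new_open <- c(new_open, s)
      }
    }
    for (b in which(!linked_curr)) {
      segments[[length(segments) + 1L]] <- cur_idx[b]
      new_open <- c(new_open, length(segments))
    }
    open <- new_open
  }
  # gap closing, cheapest candidate first
  seg_first <- vapply(segments, function(s) frames[s[1]], integer(1))
  seg_last <- vapply(segments, function(s) frames[tail(s, 1)], integer(1))
  cands <- NULL
  if (max_gap > 0 && length(segments) > 1) {
    for (a in seq_along(segments)) {
      for (b in seq_along(segments)) {
        if (a == b) next
        gap <- seg_first[b] - seg_last[a] - 1L
        if (gap < 1L || gap > max_gap) next
        dist <- sqrt(sum((dets[[tail(segments[[a]], 1)]]$centroid_um -
                          dets[[segments[[b]][1]]]$centroid_um)^2))
        if (dist <= max_link)
          cands <- rbind(cands, c(a, b, dist))
      }
    }
  }
  next_seg <- rep(NA_integer_, length(segments))   # successor after a gap
  has_pred <- rep(FALSE, length(segments))
  if (!is.null(cands)) {
    cands <- cands[order(cands[, 3], cands[, 1], cands[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(cands))) {
      a <- cands[r, 1]; b <- cands[r, 2]
      if (is.na(next_seg[a]) && !has_pred[b]) {
        next_seg[a] <- b
        has_pred[b] <- TRUE
      }
    }
  }
  out <- list()
  for (s in which(!has_pred)) {
    chain <- integer(0); gaps <- NULL
    cur <- s
    repeat {
      chain <- c(chain, segments[[cur]])
      nxt <- next_seg[cur]
      if (is.na(nxt)) break
      gaps <- rbind(gaps, c(seg_last[cur], seg_first[nxt]))
      cur <- nxt
    }
    out[[length(out) + 1L]] <- structure(
      list(track_id = NA_integer_, lineage = dets[[chain[1]]]$lineage,
           frames = frames[chain], detections = dets[chain], gaps = gaps),
      class = "ls_track")
  }
  out
}

#' @export
print.ls_track <- function(x, ...) {
  cat(sprintf("Track %s (%s): frames %d-%d, %d detection(s), %d gap(s)\n",
              x$track_id, x$lineage, min(x$frames), max(x$frames),
              length(x$detections),
              if (is.null(x$gaps)) 0L else nrow(x$gaps)))
  invisible(x)
}

#' Per-track motility metrics
#'
#' `path_length` is the sum of consecutive centroid distances (gap segments
#' contribute their straight-line distance); `net_displacement` the distance
#' from first to last centroid; `duration = (last_frame - first_frame) *
#' frame_interval`; `mean_speed = path_length / duration`;
#' `directionality_ratio = net_displacement / path_length` (1 = perfectly
#' straight; `NA` when the path length is zero).
#'
#' @param track An `ls_track` with at least 2 detections.
#' @param calibration An [calibration()] object (frame interval, minutes).
#' @return A list of class `ls_track_metrics` with fields `mean_speed`
#'   (um/min), `directionality_ratio`, `path_length`, `net_displacement`
#'   (um), `duration` (min).
#' @export
compute_metrics <- function(track, calibration) {
  stopifnot(inherits(track, "ls_track"))
  n <- length(track$detections)
  if (n < 2) stop("metrics require a track with at least 2 detections")
  pos <- t(vapply(track$detections, `[[`, numeric(2), "centroid_um"))
  steps <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                         pos[-n, , drop = FALSE])^2))
  path_length <- sum(steps)
  net <- sqrt(sum((pos[n, ] - pos[1, ])^2))
  duration <- (max(track$frames) - min(track$frames)) *
    calibration$frame_interval
  structure(
    list(track_id = track$track_id, lineage = track$lineage,
         mean_speed = path_length / duration,
         directionality_ratio = if (path_length > 0) net / path_length
                                else NA_real_,
         path_length = path_length, net_displacement = net,
         duration = duration),
    class = "ls_track_metrics")
}

#' Metrics for a list of tracks as a data frame
#'
#' Tracks with fewer than 2 detections are skipped (metrics unavailable).
#'
#' @param tracks List of `ls_track`.
#' @param calibration An [calibration()] object.
#' @return Data frame, one row per track with computable metrics.
#' @export
metrics_table <- function(tracks, calibration) {
  rows <- lapply(tracks, function(tr) {
    if (length(tr$detections) < 2) return(NULL)
    m <- compute_metrics(tr, calibration)
    data.frame(track_id = m$track_id, lineage = m$lineage,
               mean_speed_um_min = m$mean_speed,
               directionality_ratio = m$directionality_ratio,
               path_length_um = m$path_length,
               net_displacement_um = m$net_displacement,
               duration_min = m$duration)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(track_id = integer(0), lineage = character(0),
                      mean_speed_um_min = numeric(0),
                      directionality_ratio = numeric(0),
                      path_length_um = numeric(0),
                      net_displacement_um = numeric(0),
                      duration_min = numeric(0)))
  do.call(rbind, rows)
}
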