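square_series <- function(x0, y0, side, shape = c(64L, 64L), n_frames = 10L,
                          pixel_size = 1) {
  ann <- annotation_file("lesion_1", list(list(
    frame = 0L,
    vertices = cbind(c(x0, x0 + side, x0 + side, x0),
                     c(y0, y0, y0 + side, y0 + side)))))
  rasterise_annotations(ann, shape, n_frames, pixel_size)
}

make_track <- function(frames, xs, ys, lineage = "neutrophil", id = 1L,
                       pixel_size = 1, r = 2) {
  dets <- lapply(seq_along(frames), function(k) {
    px <- raster_disc(xs[k], ys[k], r, 64L, 64L)
    lesionscope:::new_detection(frames[k], id, lineage, px, pixel_size)
  })
  structure(list(track_id = id, lineage = lineage, frames = as.integer(frames),
                 detections = dets, gaps = NULL), class = "ls_track")
}

test_that("surface distances: overlap, adjacency and brute-force agreement", {
  series <- square_series(10, 10, 20)  # pixels 10..29 filled

  # detection fully inside the lesion -> distance 0, overlap set
  inside <- make_track(0L, 20, 20)
  d <- measure_distances(list(inside), series)
  expect_equal(d$distance_um, 0)
  expect_true(d$overlap)

  # detection adjacent to the lesion boundary (8-adjacent boundary pixels)
  adj <- make_track(0L, 32, 20)  # disc reaches x = 30; lesion edge at x = 29
  da <- measure_distances(list(adj), series)
  expect_lte(da$distance_um, sqrt(2))
  expect_gt(da$distance_um, 0)
  expect_false(da$overlap)

  # brute force: min over (det boundary px, lesion boundary px) pairs
  far <- make_track(0L, 45, 45)
  df <- measure_distances(list(far), series)
  det <- far$detections[[1]]
  mask <- lesion_mask_at(series, 0)
  bl <- mask_to_pixels(boundary_mask(mask))
  bd <- det$boundary
  ref <- min(sqrt(outer(bd[, 1], bl[, 1], "-")^2 +
                  outer(bd[, 2], bl[, 2], "-")^2))
  expect_equal(df$distance_um, ref)

  # pixel_size scaling: 12 px at 0.5 um/px -> 6 um
  series_half <- square_series(10, 10, 20, pixel_size = 0.5)
  d2 <- measure_distances(list(make_track(0L, 41, 20, pixel_size = 0.5)),
                          series_half)
  det2 <- make_track(0L, 41, 20, pixel_size = 0.5)$detections[[1]]
  ref2 <- 0.5 * min(sqrt(outer(det2$boundary[, 1], bl[, 1], "-")^2 +
                         outer(det2$boundary[, 2], bl[, 2], "-")^2))
  expect_equal(d2$distance_um, ref2)
})

test_that("event extraction: worked examples at the default thresholds", {
  base <- data.frame(track_id = 1L, lesion_id = "lesion_1",
                     lineage = "neutrophil", frame = 0:4,
                     distance_um = c(25, 18, 15, 22, 10), overlap = FALSE)
  ev <- classify_and_extract_events(base, frame_interval = 2)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_frame, c(1L, 4L))
  expect_equal(ev$end_frame, c(2L, 4L))
  expect_equal(ev$duration_min, c(4, 2))
  expect_equal(ev$class, c("close", "close"))
  expect_equal(ev$min_distance_um, c(15, 10))

  # held exactly at the threshold -> no event (strict <)
  at_thr <- data.frame(track_id = 1L, lesion_id = "l", lineage = "neutrophil",
                       frame = 0:9, distance_um = 20, overlap = FALSE)
  expect_equal(nrow(classify_and_extract_events(at_thr)), 0)
  at_thr_mac <- within(at_thr, { lineage <- "macrophage"; distance_um <- 50 })
  expect_equal(nrow(classify_and_extract_events(at_thr_mac)), 0)

  # overlap frame inside a run makes the whole run a contact
  touch <- data.frame(track_id = 1L, lesion_id = "l", lineage = "neutrophil",
                      frame = 0:3, distance_um = c(30, 0, 5, 30),
                      overlap = c(FALSE, TRUE, FALSE, FALSE))
  evt <- classify_and_extract_events(touch, frame_interval = 2)
  expect_equal(nrow(evt), 1)
  expect_equal(evt$start_frame, 1L)
  expect_equal(evt$end_frame, 2L)
  expect_equal(evt$class, "contact")
  expect_equal(evt$min_distance_um, 0)

  # track gaps break runs even when both sides qualify
  gap <- data.frame(track_id = 1L, lesion_id = "l", lineage = "neutrophil",
                    frame = c(0:2, 5:6), distance_um = 5, overlap = FALSE)
  evg <- classify_and_extract_events(gap, frame_interval = 2)
  expect_equal(nrow(evg), 2)
  expect_equal(evg$duration_min, c(6, 4))

  expect_error(classify_and_extract_events(base, thresholds = c(neutrophil = 0)),
               "positive")
})

test_that("macrophages use the 50 um nuclear threshold", {
  mac <- data.frame(track_id = 1L, lesion_id = "l", lineage = "macrophage",
                    frame = 0:3, distance_um = c(60, 45, 30, 55),
                    overlap = FALSE)
  ev <- classify_and_extract_events(mac, frame_interval = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 1L)
  expect_equal(ev$end_frame, 2L)
  # the same distances under the neutrophil threshold yield nothing
  neu <- within(mac, lineage <- "neutrophil")
  expect_equal(nrow(classify_and_extract_events(neu)), 0)
})

test_that("extraction matches a direct run-scan oracle on random series", {
  set.seed(61)
  for (rep in 1:30) {
    nf <- sample(5:40, 1)
    frames <- sort(sample(0:59, nf))
    lin <- sample(c("neutrophil", "macrophage"), 1)
    dist <- round(runif(nf, 0, 60), 1)
    ds <- data.frame(track_id = 1L, lesion_id = "l", lineage = lin,
                     frame = frames, distance_um = dist,
                     overlap = dist == 0)
    thr <- default_thresholds()[[lin]]
    ev <- classify_and_extract_events(ds, frame_interval = 2)
    runs <- oracle_runs(frames, dist, thr)
    expect_equal(nrow(ev), length(runs))
    if (length(runs)) {
      expect_equal(ev$start_frame, vapply(runs, `[[`, integer(1), "start"))
      expect_equal(ev$end_frame, vapply(runs, `[[`, integer(1), "end"))
    }
    # partition property: no frame in two events; duration consistency
    covered <- unlist(lapply(seq_len(nrow(ev)), function(i)
      seq(ev$start_frame[i], ev$end_frame[i])))
    expect_equal(anyDuplicated(covered), 0)
    expect_lte(sum(ev$duration_min), length(frames) * 2)
    # threshold monotonicity of total duration and covered frames (event
    # counts are not monotone: events merge when a near-threshold
    # excursion drops below a raised threshold)
    d_prev <- -1; f_prev <- -1
    for (t in c(5, 15, 25, 40, 55)) {
      names(t) <- lin
      evt <- classify_and_extract_events(ds, thresholds = t,
                                         frame_interval = 2)
      n_frames_cov <- if (nrow(evt))
        sum(vapply(seq_len(nrow(evt)), function(i)
          sum(frames >= evt$start_frame[i] & frames <= evt$end_frame[i]),
          numeric(1))) else 0
      expect_gte(sum(evt$duration_min), d_prev)
      expect_gte(n_frames_cov, f_prev)
      d_prev <- sum(evt$duration_min); f_prev <- n_frames_cov
    }
  }
})

test_that("interaction summaries count events, durations and tracks", {
  none <- summarise_interactions(classify_and_extract_events(
    measure_distances(list(), list())))
  expect_true(all(none$per_lineage$n_events == 0))
  expect_true(all(none$per_lineage$total_duration_min == 0))

  ev <- data.frame(track_id = c(1L, 1L, 2L), lesion_id = "l",
                   lineage = "neutrophil",
                   start_frame = c(0L, 5L, 2L), end_frame = c(1L, 6L, 2L),
                   class = c("close", "contact", "close"),
                   min_distance_um = c(4, 0, 11),
                   duration_min = c(4, 4, 2))
  s <- summarise_interactions(ev)
  row <- s$per_lineage[s$per_lineage$lineage == "neutrophil", ]
  expect_equal(row$n_events, 3)
  expect_equal(row$n_tracks_interacting, 2)
  expect_equal(row$total_duration_min, 10)
  expect_equal(sort(s$durations$neutrophil), c(2, 4, 4))
  expect_equal(row$total_duration_min, sum(s$durations$neutrophil))
  expect_equal(s$per_lesion$n_events, 3)

  # durations 4 and 2 -> total 6, individual list preserved
  two <- summarise_interactions(ev[2:3, ])
  expect_equal(two$per_lineage$total_duration_min[
    two$per_lineage$lineage == "neutrophil"], 6)
  expect_equal(two$durations$neutrophil, c(4, 2))
})

test_that("field-of-view counting uses the half-open rectangle", {
  mk <- function(x, y) {
    px <- cbind(x = c(x, x + 1L), y = c(y, y))
    lesionscope:::new_detection(0L, 1L, "macrophage", px, 1)
  }
  # centroid of mk(x, y) is (x + 0.5, y)
  fov <- c(0, 0, 660, 310)
  inside <- lapply(1:7, function(i) mk(50L * i, 40L * (i %% 5) + 10L))
  outside <- list(mk(700L, 50L), mk(100L, 400L), mk(900L, 500L))
  expect_equal(count_in_fov(c(inside, outside), fov), 7)
  expect_equal(count_in_fov(list(), fov), 0)
  # centroid exactly on the x1 edge is not counted
  edge <- lesionscope:::new_detection(
    0L, 1L, "macrophage",
    cbind(x = c(659L, 660L), y = c(5L, 5L)), 1)  # centroid x = 659.5
  on_edge <- lesionscope:::new_detection(
    0L, 1L, "macrophage",
    cbind(x = c(660L, 660L), y = c(5L, 6L)), 1)  # centroid x = 660
  expect_equal(count_in_fov(list(edge), fov), 1)
  expect_equal(count_in_fov(list(on_edge), fov), 0)
  expect_error(count_in_fov(list(), c(10, 0, 10, 5)), "degenerate")
})
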