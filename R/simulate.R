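# Synthetic-movie simulator. Generates calibrated two-channel stacks
# (cytoplasmic neutrophil discs; small macrophage nuclear discs; the
# macrophage cytoplasm is deliberately not rendered, matching the rationale
# for segmenting nuclei), a lesion polygon that may deform over time, and
# analytic ground truth: every cell's centroid path, the per-frame lesion
# geometry, and the interaction events implied by them. Cells move as
# persistent random walks with optional chemotactic bias toward the lesion.
# Everything is deterministic given the seed.

#' Simulation configuration
#'
#' Defaults emulate the acquisitions the pipeline targets: 2 min/frame for
#' 2 h (60 frames), a 512 x 512 field at 1 um/px, 5 neutrophils (radius
#' 7-9 um) and 5 macrophage nuclei (radius 3-5 um) around one lesion.
#' Foreground/background intensities and noise SD give an SNR of ~10.
#' Motility defaults (speed 5 um/min, persistence 0.6, bias 0.3) are
#' testing placeholders, not biological claims.
#'
#' @param seed Integer RNG seed (mandatory; recorded in the output).
#' @param n_frames,frame_interval,pixel_size,image_size Movie geometry.
#' @param n_neutrophils,n_macrophages Cell counts per lineage.
#' @param neutrophil_radius_um,macrophage_radius_um Radius ranges (um);
#'   each cell draws a constant radius uniformly from its range.
#' @param intensity_fg,intensity_bg,noise_sd Rendering intensities and
#'   additive Gaussian noise SD.
#' @param motility Named list per lineage with `speed` (um/min),
#'   `persistence` in `[0, 1]`, `bias` in `[0, 1]`.
#' @param lesion_polygon `n x 2` matrix of pixel vertices; default a 24-gon
#'   of radius 40 um centred at (160, 256) px.
#' @param deformation_amplitude_um Radial deformation amplitude of the
#'   lesion outline over time (0 = static).
#' @param annotation_interval Keyframe spacing (frames) for the emitted
#'   annotations; a static lesion gets a single keyframe at frame 0.
#' @param min_separation_um Minimum surface gap enforced between same-lineage
#'   cells (steps that would violate it are resampled, then refused). The
#'   default (12 um) keeps cells resolvable as distinct objects (surfaces
#'   beyond the segmentation feature support) and keeps centre spacing above
#'   the per-frame displacement, the regime in which identity-preserving
#'   automated tracking is well defined; cells closer than this are the
#'   touching/overlaying cases handled by manual correction, not tracking.
#' @return List of class `ls_sim_config`.
#' @export
sim_config <- function(seed,
                       n_frames = 60L, frame_interval = 2, pixel_size = 1,
                       image_size = c(512L, 512L),
                       n_neutrophils = 5L, n_macrophages = 5L,
                       neutrophil_radius_um = c(7, 9),
                       macrophage_radius_um = c(3, 5),
                       intensity_fg = 200, intensity_bg = 20, noise_sd = 18,
                       motility = list(
                         neutrophil = list(speed = 5, persistence = 0.6,
                                           bias = 0.3),
                         macrophage = list(speed = 5, persistence = 0.6,
                                           bias = 0.3)),
                       lesion_polygon = NULL,
                       deformation_amplitude_um = 0,
                       annotation_interval = 10L,
                       min_separation_um = 12) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_frames >= 1, frame_interval > 0, pixel_size > 0,
            n_neutrophils >= 0, n_macrophages >= 0, noise_sd >= 0,
            min_separation_um >= 0)
  for (lin in LINEAGES) {
    m <- motility[[lin]]
    stopifnot(!is.null(m), m$speed >= 0,
              m$persistence >= 0, m$persistence <= 1,
              m$bias >= 0, m$bias <= 1)
  }
  if (is.null(lesion_polygon)) {
    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    r_px <- 40 / pixel_size
    lesion_polygon <- cbind(x = 160 + r_px * cos(ang),
                            y = 256 + r_px * sin(ang))
  }
  structure(
    list(seed = as.integer(seed), n_frames = as.integer(n_frames),
         frame_interval = frame_interval, pixel_size = pixel_size,
         image_size = as.integer(image_size),
         n_cells = c(neutrophil = as.integer(n_neutrophils),
                     macrophage = as.integer(n_macrophages)),
         radius_um = list(neutrophil = neutrophil_radius_um,
                          macrophage = macrophage_radius_um),
         intensity_fg = intensity_fg, intensity_bg = intensity_bg,
         noise_sd = noise_sd, motility = motility,
         lesion_polygon = lesion_polygon,
         deformation_amplitude_um = deformation_amplitude_um,
         annotation_interval = as.integer(annotation_interval),
         min_separation_um = min_separation_um),
    class = "ls_sim_config")
}

lesion_polygon_at <- function(config, frame) {
  poly <- config$lesion_polygon
  amp <- config$deformation_amplitude_um / config$pixel_size
  if (amp == 0 || frame == 0) return(poly)
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  ang <- atan2(poly[, 2] - cy, poly[, 1] - cx)
  # slow radial breathing plus a travelling 3-lobed ripple
  scale <- 1 + (amp * sin(2 * pi * frame / config$n_frames +
                          3 * ang)) /
                sqrt((poly[, 1] - cx)^2 + (poly[, 2] - cy)^2)
  cbind(x = cx + (poly[, 1] - cx) * scale,
        y = cy + (poly[, 2] - cy) * scale)
}

#' Simulate a calibrated movie with ground truth
#'
#' Cells take fixed-length steps of `speed * frame_interval`; each step
#' direction is the normalised mixture `persistence * previous_direction +
#' bias * unit_vector_to_lesion_centroid + (1 - persistence) * (1 - bias) *
#' random_unit_vector`. Positions reflect off the image border (keeping the
#' whole disc inside) and steps that would bring two same-lineage discs
#' closer than `min_separation_um` are resampled, then refused. Discs are
#' rendered with the pixel-centre-inside rule at constant foreground
#' intensity, so the noiseless rendered pixel set of a cell equals its
#' ground-truth raster disc exactly; Gaussian noise (rounded to integer
#' intensities) is then added.
#'
#' @param config An [sim_config()].
#' @param render Set to `FALSE` to skip rasterising the image stack (the
#'   returned `movie` is then `NULL`); useful for motility studies at sizes
#'   where the pixel array would be wastefully large.
#' @return List with `movie` ([movie_stack()]: channel 1 neutrophil,
#'   channel 2 macrophage), `truth` (class `ls_ground_truth`: `tracks` data
#'   frame with `cell_id`, `lineage`, `frame`, `x_um`, `y_um`, `radius_um`;
#'   plus the per-frame lesion polygons, config and seed) and `annotations`
#'   (list of [annotation_file()] sampled every `annotation_interval`
#'   frames).
#' @export
simulate_movie <- function(config, render = TRUE) {
  stopifnot(inherits(config, "ls_sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  h <- config$image_size[1]; w <- config$image_size[2]
  px <- config$pixel_size
  nT <- config$n_frames
  lesion_centroid_px <- c(mean(config$lesion_polygon[, 1]),
                          mean(config$lesion_polygon[, 2]))

  # --- draw radii and initial non-overlapping positions (pixel coords) ----
  cells <- list()
  for (lin in LINEAGES) {
    for (i in seq_len(config$n_cells[[lin]])) {
      rng <- config$radius_um[[lin]]
      r_um <- runif(1, rng[1], rng[2])
      r_px <- r_um / px
      placed <- FALSE
      for (try in 1:2000) {
        pos <- c(runif(1, r_px + 1, w - r_px - 2),
                 runif(1, r_px + 1, h - r_px - 2))
        ok <- TRUE
        for (other in cells) {
          if (other$lineage != lin) next
          gap <- sqrt(sum((pos - other$pos)^2)) * px -
            (r_um + other$r_um + config$min_separation_um)
          if (gap < 0) { ok <- FALSE; break }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place all cells without overlap; reduce counts or enlarge the image")
      theta <- runif(1, 0, 2 * pi)
      cells[[length(cells) + 1L]] <- list(
        cell_id = sprintf("%s_%d", substr(lin, 1, 1), i), lineage = lin,
        r_um = r_um, r_px = r_px, pos = pos,
        dir = c(cos(theta), sin(theta)))
    }
  }

  # --- propagate persistent biased random walks --------------------------
  n_cells <- length(cells)
  pos_arr <- array(NA_real_, dim = c(nT, n_cells, 2))
  for (ci in seq_len(n_cells)) pos_arr[1, ci, ] <- cells[[ci]]$pos
  if (nT > 1) {
    for (t in 2:nT) {
      for (ci in seq_len(n_cells)) {
        cell <- cells[[ci]]
        mot <- config$motility[[cell$lineage]]
        step_px <- mot$speed * config$frame_interval / px
        lo <- cell$r_px + 1; hi_x <- w - cell$r_px - 2; hi_y <- h - cell$r_px - 2
        to_lesion <- lesion_centroid_px - cell$pos
        nl <- sqrt(sum(to_lesion^2))
        u_lesion <- if (nl > 0) to_lesion / nl else c(0, 0)
        w_noise <- (1 - mot$persistence) * (1 - mot$bias)
        accepted <- FALSE
        for (attempt in 1:20) {
          phi <- runif(1, 0, 2 * pi)
          v <- mot$persistence * cell$dir + mot$bias * u_lesion +
            w_noise * c(cos(phi), sin(phi))
          nv <- sqrt(sum(v^2))
          if (nv == 0) v <- c(cos(phi), sin(phi)) else v <- v / nv
          cand <- cell$pos + step_px * v
          # reflective boundaries, keeping the disc fully inside
          if (cand[1] < lo) cand[1] <- 2 * lo - cand[1]
          if (cand[1] > hi_x) cand[1] <- 2 * hi_x - cand[1]
          if (cand[2] < lo) cand[2] <- 2 * lo - cand[2]
          if (cand[2] > hi_y) cand[2] <- 2 * hi_y - cand[2]
          ok <- TRUE
          for (cj in seq_len(n_cells)) {
            if (cj == ci) next
            other <- cells[[cj]]
            if (other$lineage != cell$lineage) next
            if (sqrt(sum((cand - other$pos)^2)) * px <
                cell$r_um + other$r_um + config$min_separation_um) {
              ok <- FALSE; break
            }
          }
          if (ok) { accepted <- TRUE; break }
          if (step_px == 0) break
        }
        if (accepted && step_px > 0) {
          disp <- cand - cell$pos
          nd <- sqrt(sum(disp^2))
          if (nd > 0) cell$dir <- disp / nd
          cell$pos <- cand
        }
        cells[[ci]] <- cell
        pos_arr[t, ci, ] <- cell$pos
      }
    }
  }

  # --- render -------------------------------------------------------------
  movie <- NULL
  if (render) {
    pixels <- array(0, dim = c(h, w, 2L, nT))
    chan_of <- c(neutrophil = 1L, macrophage = 2L)
    for (t in seq_len(nT)) {
      for (ch in 1:2) {
        img <- matrix(config$intensity_bg, h, w)
        for (ci in seq_len(n_cells)) {
          cell <- cells[[ci]]
          if (chan_of[[cell$lineage]] != ch) next
          disc <- raster_disc(pos_arr[t, ci, 1], pos_arr[t, ci, 2],
                              cell$r_px, h, w)
          if (nrow(disc))
            img[cbind(disc[, 2] + 1L, disc[, 1] + 1L)] <- config$intensity_fg
        }
        if (config$noise_sd > 0)
          img <- img + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
        pixels[, , ch, t] <- pmin(pmax(round(img), 0), 65535)
      }
    }
    cal <- calibration(px, config$frame_interval,
                       c("neutrophil", "macrophage"))
    movie <- movie_stack(pixels, cal)
  }

  # --- ground truth and annotations --------------------------------------
  tracks <- do.call(rbind, lapply(seq_len(n_cells), function(ci) {
    cell <- cells[[ci]]
    data.frame(cell_id = cell$cell_id, lineage = cell$lineage,
               frame = 0:(nT - 1L),
               x_um = pos_arr[, ci, 1] * px, y_um = pos_arr[, ci, 2] * px,
               radius_um = cell$r_um)
  }))
  lesion_polys <- lapply(0:(nT - 1L), lesion_polygon_at, config = config)
  kf_frames <- if (config$deformation_amplitude_um > 0)
    seq(0L, nT - 1L, by = config$annotation_interval) else 0L
  annotations <- list(annotation_file("lesion_1", lapply(kf_frames,
    function(f) list(frame = f, vertices = lesion_polys[[f + 1L]]))))
  truth <- structure(
    list(tracks = tracks, lesion_polygons = lesion_polys,
         annotations = annotations, config = config, seed = config$seed),
    class = "ls_ground_truth")
  list(movie = movie, truth = truth, annotations = annotations)
}

#' @export
print.ls_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d cell(s) x %d frame(s), seed %d\n",
              length(unique(x$tracks$cell_id)), x$config$n_frames, x$seed))
  invisible(x)
}

#' True interaction events from simulator ground truth
#'
#' Computes each cell's surface distance series directly from the analytic
#' geometry - the cell's raster disc (no rendering, noise, segmentation or
#' linking involved) against the annotated lesion's signed distance field -
#' and extracts events with the same run/threshold rules as
#' [classify_and_extract_events()]. This is the oracle the image pipeline
#' is validated against.
#'
#' @param truth An `ls_ground_truth`.
#' @param thresholds Strict per-lineage distance bounds (um).
#' @return List with `events` and `distances` data frames (keyed by true
#'   `cell_id` in the `track_id` column).
#' @export
true_events <- function(truth, thresholds = default_thresholds()) {
  stopifnot(inherits(truth, "ls_ground_truth"))
  config <- truth$config
  h <- config$image_size[1]; w <- config$image_size[2]
  px <- config$pixel_size
  series <- rasterise_annotations(truth$annotations[[1]], c(h, w),
                                  config$n_frames, px)
  tr <- truth$tracks
  rows <- list()
  for (id in unique(tr$cell_id)) {
    sub <- tr[tr$cell_id == id, ]
    dist <- numeric(nrow(sub)); ovl <- logical(nrow(sub))
    for (k in seq_len(nrow(sub))) {
      sdf <- lesion_sdf_at(series, sub$frame[k])
      disc <- raster_disc(sub$x_um[k] / px, sub$y_um[k] / px,
                          sub$radius_um[k] / px, h, w)
      bnd <- mask_to_pixels(boundary_mask(pixels_to_mask(disc, h, w)))
      raw_min <- min(sdf[cbind(bnd[, 2] + 1L, bnd[, 1] + 1L)])
      dist[k] <- max(0, raw_min)
      ovl[k] <- raw_min <= 0
    }
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = id, lesion_id = series$lesion_id,
      lineage = sub$lineage[1], frame = sub$frame,
      distance_um = dist, overlap = ovl)
  }
  distances <- do.call(rbind, rows)
  events <- classify_and_extract_events(distances, thresholds,
                                        config$frame_interval)
  list(events = events, distances = distances)
}
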