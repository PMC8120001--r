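# Independent brute-force oracles. These deliberately share no code with the
# package internals: labelling is a scan-and-grow loop, distances are
# all-pairs minima, assignment is exhaustive enumeration.

# --- connected components: iterative flood fill, 8-connectivity -------------
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (x in seq_len(w)) {       # scan order irrelevant: compared as partition
    for (y in seq_len(h)) {
      if (!mask[y, x] || lab[y, x] != 0L) next
      cur <- cur + 1L
      stack <- list(c(y, x))
      lab[y, x] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dy in -1:1) for (dx in -1:1) {
          ny <- p[1] + dy; nx <- p[2] + dx
          if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
              mask[ny, nx] && lab[ny, nx] == 0L) {
            lab[ny, nx] <- cur
            stack[[length(stack) + 1L]] <- c(ny, nx)
          }
        }
      }
    }
  }
  lab
}

# canonical representation of a labelling: set of components, each a sorted
# vector of linear pixel indices
label_partition <- function(lab) {
  comps <- unname(split(which(lab > 0), lab[lab > 0]))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, numeric(1), 1))]
}

# --- signed distance to boundary pixels: all-pairs minimum ------------------
oracle_signed_distance <- function(mask, pixel_size) {
  h <- nrow(mask); w <- ncol(mask)
  is_boundary <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!mask[y, x]) next
    nb <- c(if (y > 1) mask[y - 1, x] else FALSE,
            if (y < h) mask[y + 1, x] else FALSE,
            if (x > 1) mask[y, x - 1] else FALSE,
            if (x < w) mask[y, x + 1] else FALSE)
    if (!all(nb)) is_boundary[y, x] <- TRUE
  }
  b <- which(is_boundary, arr.ind = TRUE)
  out <- matrix(NA_real_, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    d <- sqrt(min((b[, 1] - y)^2 + (b[, 2] - x)^2))
    out[y, x] <- if (mask[y, x] && !is_boundary[y, x]) -d else d
  }
  out * pixel_size
}

random_mask <- function(h = 32L, w = 32L, p = 0.35) {
  matrix(runif(h * w) < p, h, w)
}

# --- assignment: exhaustive enumeration -------------------------------------
# All one-to-one partial assignments between rows and columns of d, links
# above maxd forbidden. Objective: maximise number of links, then minimise
# total cost. Returns list(n_links, cost).
oracle_assignment <- function(d, maxd) {
  n <- nrow(d); m <- ncol(d)
  best <- list(n_links = -1L, cost = Inf)
  recurse <- function(i, used, links, cost) {
    if (i > n) {
      if (links > best$n_links ||
          (links == best$n_links && cost < best$cost - 1e-12))
        best <<- list(n_links = links, cost = cost)
      return(invisible(NULL))
    }
    recurse(i + 1L, used, links, cost)       # row i unlinked
    for (j in seq_len(m)) {
      if (used[j] || d[i, j] > maxd) next
      used[j] <- TRUE
      recurse(i + 1L, used, links + 1L, cost + d[i, j])
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best
}

# --- event runs: direct loop over a distance vector -------------------------
oracle_runs <- function(frames, dist, thr) {
  runs <- list()
  cur <- NULL
  for (k in seq_along(frames)) {
    below <- dist[k] < thr
    contiguous <- !is.null(cur) && frames[k] == cur$end + 1L
    if (below && contiguous) {
      cur$end <- frames[k]
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- if (below) list(start = frames[k], end = frames[k]) else NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

# --- independent ImageJ .roi byte writer ------------------------------------
# Written directly from the format description (big-endian; 'Iout' magic,
# type byte at offset 6, bounds at 8..15, n at 16, header2 offset at 60,
# coords at 64, T position at header2 + 12).
oracle_roi_bytes <- function(xs, ys, t_position_1based) {
  int16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "big")
  int32 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "big")
  n <- length(xs)
  left <- min(xs); top <- min(ys)
  h2_off <- 64L + 4L * n
  c(charToRaw("Iout"),
    int16(227),                          # version
    as.raw(c(0, 0)),                     # type polygon, pad
    int16(top), int16(left), int16(max(ys) + 1L), int16(max(xs) + 1L),
    int16(n),
    raw(38),                             # unused floats etc. (18..55)
    int32(0),                            # stack position unset
    int32(h2_off),
    unlist(lapply(xs - left, int16)), unlist(lapply(ys - top, int16)),
    raw(12),                             # header2[0..11]
    int32(t_position_1based),
    raw(48))
}

# --- shared fixtures --------------------------------------------------------
# Small simulated movie + trained classifier + params, reused across tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    poly <- {
      a <- seq(0, 2 * pi, length.out = 21)[-21]
      cbind(x = 70 + 30 * cos(a), y = 128 + 30 * sin(a))
    }
    cfg <- sim_config(seed = 404, n_frames = 15, image_size = c(256L, 256L),
                      n_neutrophils = 3, n_macrophages = 3,
                      lesion_polygon = poly)
    sim <- simulate_movie(cfg)
    mask <- truth_macrophage_mask(sim$truth, 0)
    labels <- sample_training_labels(mask, 1500, seed = 11)
    clf <- train_pixel_classifier(get_frame(sim$movie, 0, "macrophage"),
                                  labels, seed = 11)
    cache <<- list(sim = sim, clf = clf,
                   params = analysis_params(neutrophil_threshold = 110,
                                            classifier = clf))
    cache
  }
})

# rasterise the true macrophage discs of one frame (for label sampling)
truth_macrophage_mask <- function(truth, frame) {
  tt <- truth$tracks
  sub <- tt[tt$lineage == "macrophage" & tt$frame == frame, ]
  h <- truth$config$image_size[1]; w <- truth$config$image_size[2]
  px <- truth$config$pixel_size
  m <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(sub))) {
    d <- raster_disc(sub$x_um[i] / px, sub$y_um[i] / px,
                     sub$radius_um[i] / px, h, w)
    m[cbind(d[, 2] + 1L, d[, 1] + 1L)] <- TRUE
  }
  m
}

event_key <- function(e)
  sort(paste(e$lineage, e$lesion_id, e$start_frame, e$end_frame, e$class))

# hand-built ground-truth object for constructed scenarios
make_truth <- function(tracks, lesion_vertices, n_frames, pixel_size = 1,
                       frame_interval = 2, image_size = c(128L, 128L)) {
  cfg <- sim_config(seed = 1, n_frames = n_frames,
                    frame_interval = frame_interval, pixel_size = pixel_size,
                    image_size = image_size, n_neutrophils = 0,
                    n_macrophages = 0, lesion_polygon = lesion_vertices)
  ann <- annotation_file("lesion_1",
                         list(list(frame = 0L, vertices = lesion_vertices)))
  structure(list(tracks = tracks,
                 lesion_polygons = rep(list(lesion_vertices), n_frames),
                 annotations = list(ann), config = cfg, seed = 1L),
            class = "ls_ground_truth")
}

python_available <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- nzchar(Sys.which("python")) &&
        system2("python", c("-c", shQuote("import tifffile")),
                stdout = FALSE, stderr = FALSE) == 0
    cache
  }
})
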