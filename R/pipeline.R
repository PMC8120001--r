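# End-to-end driver: movie + annotations -> detections -> tracks ->
# distances -> events -> metrics -> summary.

#' Analysis parameters
#'
#' @param neutrophil_threshold Intensity threshold or `"otsu"` for the
#'   cytoplasmic channel (empirically derived fixed values are typical).
#' @param neutrophil_area_um2,macrophage_area_um2 Inclusive size filters.
#' @param classifier A trained [train_pixel_classifier()] for macrophage
#'   nuclei (required if a macrophage channel is analysed).
#' @param prob_threshold Probability cut for nucleus binarisation.
#' @param max_link_distance_um,max_gap_frames Tracking parameters.
#' @param thresholds Interaction distance thresholds (um, strict).
#' @return List of class `ls_params`.
#' @export
analysis_params <- function(neutrophil_threshold = "otsu",
                            neutrophil_area_um2 = c(30, 800),
                            macrophage_area_um2 = c(10, 300),
                            classifier = NULL,
                            prob_threshold = 0.5,
                            max_link_distance_um = 30,
                            max_gap_frames = 2,
                            thresholds = default_thresholds()) {
  structure(list(neutrophil_threshold = neutrophil_threshold,
                 neutrophil_area_um2 = neutrophil_area_um2,
                 macrophage_area_um2 = macrophage_area_um2,
                 classifier = classifier, prob_threshold = prob_threshold,
                 max_link_distance_um = max_link_distance_um,
                 max_gap_frames = max_gap_frames, thresholds = thresholds),
            class = "ls_params")
}

#' Run the full interaction-analysis pipeline on one movie
#'
#' Segments every frame of the neutrophil (cytoplasmic) and macrophage
#' (nuclear) channels present in the movie's calibration, applies optional
#' manual corrections, links tracks, rasterises the lesion annotations,
#' measures surface distances, extracts contact/close interaction events
#' and computes per-track motility metrics.
#'
#' @param movie An [movie_stack()].
#' @param annotations List of [annotation_file()] (or one).
#' @param params An [analysis_params()].
#' @param corrections Optional list of manual correction directives per
#'   lineage, e.g. `list(macrophage = list(...))`; see
#'   [apply_corrections()].
#' @param fish Label for this movie/larva in the output tables.
#' @return List with `detections`, `tracks`, `distances`, `events`,
#'   `metrics`, `summary`, `lesions`, `fish`.
#' @export
analyse_movie <- function(movie, annotations, params = analysis_params(),
                          corrections = NULL, fish = "fish_1") {
  stopifnot(inherits(movie, "ls_movie"))
  if (inherits(annotations, "ls_annotation")) annotations <- list(annotations)
  cal <- movie$calibration
  px <- cal$pixel_size
  detections <- list()
  for (lin in intersect(LINEAGES, cal$channel_roles)) {
    lin_dets <- list()
    for (f in 0:(movie$n_frames - 1L)) {
      img <- get_frame(movie, f, lin)
      dets <- if (lin == "neutrophil") {
        segment_cytoplasmic(img, params$neutrophil_threshold,
                            params$neutrophil_area_um2[1],
                            params$neutrophil_area_um2[2],
                            pixel_size = px, frame = f)
      } else {
        if (is.null(params$classifier))
          stop("macrophage channel present but no pixel classifier in params")
        segment_nuclei(img, params$classifier, params$prob_threshold,
                       params$macrophage_area_um2[1],
                       params$macrophage_area_um2[2],
                       pixel_size = px, frame = f)
      }
      lin_dets <- c(lin_dets, dets)
    }
    if (!is.null(corrections[[lin]]))
      lin_dets <- apply_corrections(lin_dets, corrections[[lin]], px,
                                    c(movie$height, movie$width))
    detections <- c(detections, lin_dets)
  }
  tracks <- link_tracks(detections, params$max_link_distance_um,
                        params$max_gap_frames)
  lesions <- lapply(annotations, function(a) {
    validate_annotation_bounds(a, movie$height, movie$width)
    rasterise_annotations(a, c(movie$height, movie$width), movie$n_frames, px)
  })
  distances <- measure_distances(tracks, lesions)
  events <- classify_and_extract_events(distances, params$thresholds,
                                        cal$frame_interval)
  metrics <- metrics_table(tracks, cal)
  summary <- summarise_interactions(events, tracks)
  list(detections = detections, tracks = tracks, distances = distances,
       events = events, metrics = metrics, summary = summary,
       lesions = lesions, fish = fish)
}

#' Sample sparse training labels from a reference mask
#'
#' Draws `n_per_class` labelled pixels from a known foreground mask (e.g. a
#' hand-labelled frame, or simulator ground truth in tests) and from the
#' background, for [train_pixel_classifier()]. Background labels are
#' stratified: a fraction is drawn from the thin ring just outside the
#' foreground (where smoothed features look object-like) and the rest
#' uniformly — mirroring the standard practice of explicitly labelling
#' object borders when training a pixel classifier, without which the
#' classifier dilates every object by its feature-smoothing radius.
#'
#' @param mask Logical matrix (foreground = nucleus).
#' @param n_per_class Number of labelled pixels per class.
#' @param seed RNG seed.
#' @param image 1-based image index stored in the label table.
#' @param boundary_fraction Fraction of background labels drawn from within
#'   `ring_width` pixels of the foreground.
#' @param ring_width Width (px) of the border ring, matching the feature
#'   smoothing scales.
#' @return Data frame with columns `image`, `x`, `y`, `class`.
#' @export
sample_training_labels <- function(mask, n_per_class = 2000L, seed = 1L,
                                   image = 1L, boundary_fraction = 0.5,
                                   ring_width = 3L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  fg <- which(mask); bg <- which(!mask)
  if (!length(fg) || !length(bg))
    stop("mask must contain both foreground and background pixels")
  near <- cpp_edt_seeded(mask) <= ring_width & !mask
  ring <- which(near); far <- which(!mask & !near)
  pick <- function(idx, n) {
    n <- min(n, length(idx))
    if (n == 0) integer(0) else idx[sample.int(length(idx), n)]
  }
  n_ring <- round(n_per_class * boundary_fraction)
  sel_fg <- pick(fg, n_per_class)
  sel_bg <- c(pick(ring, n_ring), pick(far, n_per_class - n_ring))
  sel <- c(sel_fg, sel_bg)
  cls <- rep(c("nucleus", "background"), c(length(sel_fg), length(sel_bg)))
  h <- nrow(mask)
  data.frame(image = image,
             x = (sel - 1L) %/% h,
             y = (sel - 1L) %% h,
             class = cls)
}
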