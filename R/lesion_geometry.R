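# Lesion geometry: time-keyed polygon annotations become per-frame masks
# (hold-last interpolation) and signed Euclidean distance fields in um.

#' Signed Euclidean distance field of a mask
#'
#' Distance (um) from each pixel centre to the nearest boundary pixel centre
#' of the mask: positive outside, negative strictly inside, zero on the
#' boundary itself. Boundary pixels are foreground pixels with at least one
#' 4-neighbour outside the mask (or outside the image).
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @param pixel_size um per pixel.
#' @return Numeric matrix of signed distances in um.
#' @export
distance_field <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  mask <- mask & TRUE
  if (!any(mask)) stop("mask is empty")
  boundary <- boundary_mask(mask)
  d <- cpp_edt_seeded(boundary) * pixel_size
  d[mask & !boundary] <- -d[mask & !boundary]
  d
}

#' Rasterise time-keyed annotations into a per-frame lesion series
#'
#' Frame `f` uses the polygon of the latest keyframe at or before `f`
#' (piecewise-constant hold: outlines are redrawn, not morphed). Polygons
#' are rasterised with the pixel-centre-inside rule. Masks and signed
#' distance fields are stored once per keyframe and shared by all frames in
#' that keyframe's span.
#'
#' @param annotation An [annotation_file()].
#' @param movie_shape `c(height, width)` in pixels.
#' @param n_frames Number of analysed frames; the first keyframe must be at
#'   or before frame 0.
#' @param pixel_size um per pixel, for the distance fields.
#' @return An object of class `ls_lesion_series` with fields `lesion_id`,
#'   `masks` (one per keyframe), `sdf` (signed distance fields, um),
#'   `frame_index` (length `n_frames`, mapping frame to keyframe).
#' @export
rasterise_annotations <- function(annotation, movie_shape, n_frames,
                                  pixel_size) {
  stopifnot(inherits(annotation, "ls_annotation"), n_frames >= 1)
  kf_frames <- vapply(annotation$keyframes, `[[`, integer(1), "frame")
  if (kf_frames[1] > 0)
    stop(sprintf("lesion %s: first keyframe at frame %d but analysis starts at frame 0",
                 annotation$lesion_id, kf_frames[1]))
  masks <- lapply(annotation$keyframes, function(kf)
    cpp_rasterise_polygon(kf$vertices[, 1], kf$vertices[, 2],
                          movie_shape[1], movie_shape[2]))
  for (i in seq_along(masks))
    if (!any(masks[[i]]))
      stop(sprintf("lesion %s keyframe %d rasterises to an empty mask",
                   annotation$lesion_id, kf_frames[i]))
  sdf <- lapply(masks, distance_field, pixel_size = pixel_size)
  frame_index <- findInterval(0:(n_frames - 1), kf_frames)
  structure(
    list(lesion_id = annotation$lesion_id, masks = masks, sdf = sdf,
         keyframe_frames = kf_frames, frame_index = frame_index,
         n_frames = as.integer(n_frames), pixel_size = pixel_size),
    class = "ls_lesion_series")
}

#' @export
print.ls_lesion_series <- function(x, ...) {
  cat(sprintf("LesionSeries '%s': %d frame(s), keyframes at %s\n",
              x$lesion_id, x$n_frames,
              paste(x$keyframe_frames, collapse = ", ")))
  invisible(x)
}

#' Lesion mask / distance field governing one frame
#'
#' @param series An `ls_lesion_series`.
#' @param frame 0-based frame index.
#' @return Logical mask or numeric signed-distance matrix (um).
#' @export
lesion_mask_at <- function(series, frame) {
  stopifnot(inherits(series, "ls_lesion_series"))
  if (frame < 0 || frame >= series$n_frames) stop("frame out of range")
  series$masks[[series$frame_index[frame + 1L]]]
}

#' @rdname lesion_mask_at
#' @export
lesion_sdf_at <- function(series, frame) {
  stopifnot(inherits(series, "ls_lesion_series"))
  if (frame < 0 || frame >= series$n_frames) stop("frame out of range")
  series$sdf[[series$frame_index[frame + 1L]]]
}
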