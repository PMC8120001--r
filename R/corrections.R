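# Manual correction directives, mirroring the hand-editing used when object
# sizes/intensities are too similar for automated detection or when cells
# overlay one another: delete, merge, split (along a dividing polyline) and
# add (a hand-drawn polygon). Directives are applied in listed order; object
# ids are then reassigned deterministically per frame (raster-scan order of
# each object's topmost-leftmost pixel).

#' Apply manual correction directives to detections
#'
#' @param detections List of `ls_detection` objects (one lineage).
#' @param corrections List of directives, each a list with an `action` field:
#'   * `list(action = "delete", frame, object_id)`
#'   * `list(action = "merge", frame, object_ids)` - union of the pixel sets,
#'     which must be 8-connected;
#'   * `list(action = "split", frame, object_id, polyline)` - `polyline` is an
#'     `n x 2` matrix of pixel vertices; pixels under the rasterised polyline
#'     are cut, the remainder must fall apart into >= 2 components, and cut
#'     pixels are reassigned to the nearest resulting component;
#'   * `list(action = "add", frame, polygon)` - rasterised with the
#'     pixel-centre rule; must not overlap an existing object.
#' @param pixel_size um per pixel (areas are recomputed).
#' @param image_shape `c(height, width)` for rasterising added polygons.
#' @return Corrected list of `ls_detection` objects with fresh ids.
#' @export
apply_corrections <- function(detections, corrections, pixel_size,
                              image_shape) {
  find_det <- function(frame, object_id) {
    for (i in seq_along(detections)) {
      d <- detections[[i]]
      if (d$frame == frame && d$object_id == object_id) return(i)
    }
    stop(sprintf("no detection with object_id %d in frame %d",
                 object_id, frame))
  }
  lineage_of <- function(frame) {
    for (d in detections) if (d$frame == frame) return(d$lineage)
    if (length(detections)) detections[[1]]$lineage else "neutrophil"
  }
  for (corr in corrections) {
    action <- corr$action
    if (action == "delete") {
      i <- find_det(corr$frame, corr$object_id)
      detections[[i]] <- NULL
    } else if (action == "merge") {
      ids <- corr$object_ids
      if (length(ids) < 2) stop("merge needs at least two object ids")
      idxs <- vapply(ids, function(id) find_det(corr$frame, id), integer(1))
      pix <- do.call(rbind, lapply(detections[idxs], `[[`, "pixels"))
      pix <- unique(pix)
      if (!pixel_set_connected(pix))
        stop("merge would create a disconnected object")
      lin <- detections[[idxs[1]]]$lineage
      detections <- detections[-idxs]
      detections[[length(detections) + 1L]] <-
        new_detection(corr$frame, 0L, lin, pix, pixel_size)
    } else if (action == "split") {
      i <- find_det(corr$frame, corr$object_id)
      d <- detections[[i]]
      parts <- split_pixels(d$pixels, corr$polyline)
      detections[[i]] <- NULL
      for (p in parts)
        detections[[length(detections) + 1L]] <-
          new_detection(corr$frame, 0L, d$lineage, p, pixel_size)
    } else if (action == "add") {
      poly <- corr$polygon
      mask <- cpp_rasterise_polygon(poly[, 1], poly[, 2],
                                    image_shape[1], image_shape[2])
      pix <- mask_to_pixels(mask)
      if (!nrow(pix)) stop("added polygon rasterises to an empty pixel set")
      for (d in detections)
        if (d$frame == corr$frame &&
            nrow(merge_overlap(d$pixels, pix)) > 0)
          stop("added polygon overlaps an existing object")
      detections[[length(detections) + 1L]] <-
        new_detection(corr$frame, 0L, lineage_of(corr$frame), pix, pixel_size)
    } else {
      stop("unknown correction action: ", action)
    }
  }
  renumber_detections(detections)
}

merge_overlap <- function(a, b) {
  keys_a <- paste(a[, 1], a[, 2])
  b[paste(b[, 1], b[, 2]) %in% keys_a, , drop = FALSE]
}

pixel_set_connected <- function(pixels) {
  x0 <- min(pixels[, 1]); y0 <- min(pixels[, 2])
  local <- cbind(pixels[, 1] - x0, pixels[, 2] - y0)
  m <- pixels_to_mask(local, max(local[, 2]) + 1L, max(local[, 1]) + 1L)
  max(cpp_label_components(m, 8L)) == 1L
}

# Cut an object's pixel set along a polyline: pixels under the Bresenham
# rasterisation of the polyline are removed, the remainder must form >= 2
# components, and the cut pixels are assigned to the nearest component
# (ties to the lower component label).
split_pixels <- function(pixels, polyline) {
  polyline <- round(polyline)
  cut <- NULL
  for (i in seq_len(nrow(polyline) - 1L))
    cut <- rbind(cut, bresenham(polyline[i, 1], polyline[i, 2],
                                polyline[i + 1L, 1], polyline[i + 1L, 2]))
  keys_cut <- unique(paste(cut[, 1], cut[, 2]))
  keys_px <- paste(pixels[, 1], pixels[, 2])
  on_cut <- keys_px %in% keys_cut
  rest <- pixels[!on_cut, , drop = FALSE]
  if (nrow(rest) == 0) stop("split polyline removes the whole object")
  x0 <- min(pixels[, 1]); y0 <- min(pixels[, 2])
  w <- max(pixels[, 1]) - x0 + 1L; h <- max(pixels[, 2]) - y0 + 1L
  m <- pixels_to_mask(cbind(rest[, 1] - x0, rest[, 2] - y0), h, w)
  labels <- cpp_label_components(m, 8L)
  k <- max(labels)
  if (k < 2) stop("split polyline does not partition the object")
  parts <- lapply(seq_len(k), function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    cbind(x = as.integer(idx[, 2] - 1L + x0), y = as.integer(idx[, 1] - 1L + y0))
  })
  cut_px <- pixels[on_cut, , drop = FALSE]
  for (j in seq_len(nrow(cut_px))) {
    dmin <- vapply(parts, function(p)
      min((p[, 1] - cut_px[j, 1])^2 + (p[, 2] - cut_px[j, 2])^2), numeric(1))
    best <- which.min(dmin)
    parts[[best]] <- rbind(parts[[best]], cut_px[j, , drop = FALSE])
  }
  parts
}

# Reassign object ids: per frame, in raster-scan order of the topmost-
# leftmost pixel of each object.
renumber_detections <- function(detections) {
  if (!length(detections)) return(detections)
  frames <- vapply(detections, `[[`, integer(1), "frame")
  anchor <- t(vapply(detections, function(d) {
    ys <- d$pixels[, 2]; xs <- d$pixels[, 1]
    top <- min(ys)
    c(top, min(xs[ys == top]))
  }, numeric(2)))
  ord <- order(frames, anchor[, 1], anchor[, 2])
  detections <- detections[ord]
  frames <- frames[ord]
  for (f in unique(frames)) {
    ids <- which(frames == f)
    for (k in seq_along(ids))
      detections[[ids[k]]]$object_id <- k
  }
  detections
}
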