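# Lesion annotations: time-keyed polygons in 0-based pixel coordinates,
# origin top-left. Sources: the package's JSON dialect, or ImageJ .roi /
# .zip files as produced by outlining lesions with the Freehand tool frame
# by frame. ImageJ stores 1-based frame positions; these are converted to
# 0-based on read.

#' Construct a time-keyed lesion annotation
#'
#' @param lesion_id Identifier string.
#' @param keyframes List of `list(frame = <0-based int>, vertices = <n x 2
#'   matrix of (x, y) pixel coordinates>)`; sorted by frame on construction.
#' @return An object of class `ls_annotation`.
#' @export
annotation_file <- function(lesion_id, keyframes) {
  stopifnot(is.character(lesion_id), length(lesion_id) == 1,
            is.list(keyframes), length(keyframes) >= 1)
  keyframes <- lapply(keyframes, function(kf) {
    v <- kf$vertices
    if (is.list(v) && !is.matrix(v))
      v <- do.call(rbind, lapply(v, function(p) as.numeric(unlist(p))))
    v <- matrix(as.numeric(v), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
    if (nrow(v) < 3)
      stop("polygon for lesion ", lesion_id, " has fewer than 3 vertices")
    if (!polygon_is_simple(v))
      stop("polygon for lesion ", lesion_id, " is self-intersecting")
    list(frame = as.integer(kf$frame), vertices = v)
  })
  frames <- vapply(keyframes, `[[`, integer(1), "frame")
  if (anyDuplicated(frames))
    stop("duplicate keyframe for lesion ", lesion_id, " at frame ",
         frames[duplicated(frames)][1])
  keyframes <- keyframes[order(frames)]
  structure(list(lesion_id = lesion_id, keyframes = keyframes),
            class = "ls_annotation")
}

#' @export
print.ls_annotation <- function(x, ...) {
  cat(sprintf("Lesion annotation '%s': %d keyframe(s) at frame(s) %s\n",
              x$lesion_id, length(x$keyframes),
              paste(vapply(x$keyframes, `[[`, integer(1), "frame"),
                    collapse = ", ")))
  invisible(x)
}

validate_annotation_bounds <- function(annotation, height, width) {
  for (kf in annotation$keyframes) {
    v <- kf$vertices
    if (any(v[, 1] < 0) || any(v[, 1] > width - 1) ||
        any(v[, 2] < 0) || any(v[, 2] > height - 1))
      stop(sprintf("lesion %s frame %d: vertex outside the %d x %d image",
                   annotation$lesion_id, kf$frame, width, height))
  }
  invisible(annotation)
}

#' Read lesion annotations
#'
#' @param path A `.json` file in the package dialect
#'   (`{"lesion_id", "keyframes": [{"frame", "vertices": [[x, y], ...]}]}`,
#'   a single object or an array of them), a single ImageJ `.roi`, or an
#'   ImageJ `.zip` of polygon ROIs. All ROIs in one zip are read as the
#'   keyframes of one lesion (named after the file).
#' @param dialect `"json"` or `"imagej"`; inferred from the extension by
#'   default.
#' @param image_size Optional `c(height, width)`; when given, vertices are
#'   checked against the image bounds.
#' @return A list of [annotation_file()] objects.
#' @export
read_annotations <- function(path, dialect = NULL, image_size = NULL) {
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, json = "json", roi = "imagej", zip = "imagej",
                      stop("cannot infer annotation dialect from .", ext))
  }
  anns <- switch(dialect,
    json = read_annotations_json(path),
    imagej = read_annotations_imagej(path),
    stop("unknown dialect: ", dialect))
  if (!is.null(image_size))
    for (a in anns) validate_annotation_bounds(a, image_size[1], image_size[2])
  anns
}

read_annotations_json <- function(path) {
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(parsed$lesion_id)) parsed <- list(parsed)
  lapply(parsed, function(obj) {
    annotation_file(obj$lesion_id, lapply(obj$keyframes, function(kf) {
      verts <- do.call(rbind, lapply(kf$vertices, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      list(frame = kf$frame, vertices = verts)
    }))
  })
}

#' Write annotations in the JSON dialect
#'
#' Vertices round-trip exactly (written at full precision).
#'
#' @param annotations A list of [annotation_file()] objects (or one).
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "ls_annotation")) annotations <- list(annotations)
  payload <- lapply(annotations, function(a) {
    list(lesion_id = a$lesion_id,
         keyframes = lapply(a$keyframes, function(kf) {
           list(frame = kf$frame,
                vertices = lapply(seq_len(nrow(kf$vertices)), function(i)
                  c(kf$vertices[i, 1], kf$vertices[i, 2])))
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- ImageJ ROI binary format ------------------------------------------------

# Parse one ImageJ .roi blob (big-endian). Supports polygon (0), freehand
# (7) and traced (8) outline types. Returns list(vertices, frame) with a
# 0-based frame index taken from the T position in header2 when set, else
# the overall stack position, else frame 0.
parse_imagej_roi <- function(raw) {
  rb <- function(from, n, size, signed = TRUE)
    readBin(raw[(from + 1):(from + n * size)], "integer", n, size,
            signed = signed, endian = "big")
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI (missing 'Iout' magic)")
  roi_type <- as.integer(raw[7])
  if (!roi_type %in% c(0L, 7L, 8L))
    stop("unsupported ImageJ ROI type ", roi_type,
         " (only polygon/freehand/traced outlines)")
  top <- rb(8, 1, 2); left <- rb(10, 1, 2)
  n <- rb(16, 1, 2, signed = FALSE)
  if (n < 3) stop("ImageJ ROI has fewer than 3 vertices")
  position <- rb(56, 1, 4)
  h2 <- rb(60, 1, 4)
  xs <- rb(64, n, 2) + left
  ys <- rb(64 + 2 * n, n, 2) + top
  t_pos <- 0L
  if (h2 > 0 && h2 + 16 <= length(raw)) t_pos <- rb(h2 + 12, 1, 4)
  frame1 <- if (t_pos > 0) t_pos else if (position > 0) position else 1L
  list(vertices = cbind(x = as.numeric(xs), y = as.numeric(ys)),
       frame = as.integer(frame1 - 1L))
}

read_annotations_imagej <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lesion_id <- sub("\\.[^.]*$", "", basename(path))
  if (ext == "roi") {
    roi <- parse_imagej_roi(readBin(path, "raw", file.info(path)$size))
    return(list(annotation_file(lesion_id, list(roi))))
  }
  exdir <- tempfile("rois")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
  if (!length(files)) stop("zip contains no .roi entries: ", path)
  kfs <- lapply(files, function(f)
    parse_imagej_roi(readBin(f, "raw", file.info(f)$size)))
  list(annotation_file(lesion_id, kfs))
}

#' Write a minimal ImageJ polygon .roi file
#'
#' Emits an outline ROI with integer vertices and a 1-based T position, as
#' ImageJ's RoiEncoder would. Mainly useful for exchanging package
#' annotations with Fiji.
#'
#' @param vertices `n x 2` matrix of (x, y) pixel coordinates (rounded to
#'   integers, as the format requires).
#' @param frame 0-based frame index; stored as the 1-based T position.
#' @param path Output path.
#' @export
write_imagej_roi <- function(vertices, frame, path) {
  xs <- as.integer(round(vertices[, 1])); ys <- as.integer(round(vertices[, 2]))
  n <- length(xs)
  left <- min(xs); top <- min(ys)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(as.integer(x), con, size, endian = "big")
  writeBin(charToRaw("Iout"), con)
  wb(228, 2)                     # version
  writeBin(as.raw(c(0, 0)), con) # type = 0 (polygon), pad
  wb(top, 2); wb(left, 2); wb(max(ys) + 1, 2); wb(max(xs) + 1, 2)
  wb(n, 2)
  writeBin(raw(38), con)         # x1..position (offsets 18..55) zeroed
  wb(0, 4)                       # position (unused; header2 carries T)
  h2 <- 64 + 4 * n
  wb(h2, 4)                      # header2 offset
  wb(xs - left, 2); wb(ys - top, 2)
  writeBin(raw(12), con)         # header2 bytes 0..11 (incl. C, Z positions)
  wb(frame + 1, 4)               # T position, 1-based
  writeBin(raw(48), con)         # rest of header2
  invisible(path)
}
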