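#' Physical calibration of a movie
#'
#' Records the isotropic pixel size, the frame interval, and the biological
#' role of each channel. Calibration always comes from user configuration:
#' embedded file metadata is considered unreliable and is never used to set
#' these values (a mismatch only triggers a warning on read).
#'
#' @param pixel_size Pixel edge length in micrometres (isotropic in x and y).
#' @param frame_interval Time between consecutive frames, in minutes. The
#'   acquisitions this models were recorded at 2 min per frame for 1.5-2 h.
#' @param channel_roles Character vector giving the role of each channel, in
#'   channel order; values from `neutrophil`, `macrophage`, `lesion`,
#'   `brightfield`, `other`.
#' @return An object of class `ls_calibration`.
#' @examples
#' calibration(1.0, 2, c("neutrophil", "macrophage"))
#' @export
calibration <- function(pixel_size, frame_interval,
                        channel_roles = c("neutrophil", "macrophage")) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0,
            is.numeric(frame_interval), length(frame_interval) == 1,
            frame_interval > 0)
  channel_roles <- as.character(channel_roles)
  if (!all(channel_roles %in% CHANNEL_ROLES))
    stop("unknown channel role(s): ",
         paste(setdiff(channel_roles, CHANNEL_ROLES), collapse = ", "))
  structure(
    list(pixel_size = pixel_size, frame_interval = frame_interval,
         channel_roles = channel_roles),
    class = "ls_calibration")
}

#' @export
print.ls_calibration <- function(x, ...) {
  cat(sprintf("Calibration: %.4g um/px, %.4g min/frame, channels: %s\n",
              x$pixel_size, x$frame_interval,
              paste(x$channel_roles, collapse = ", ")))
  invisible(x)
}

#' Calibrated multi-channel time-lapse stack
#'
#' Pixel data are stored as a 4-d numeric array indexed `[y, x, channel,
#' frame]` with 0-based pixel coordinates in the analysis layer: pixel `(x,
#' y)` lives at array position `[y + 1, x + 1]`, origin top-left, y
#' increasing downward. Physical coordinates are `index * pixel_size`.
#'
#' @param pixels 4-d array `[y, x, channel, frame]` (a 2-d matrix or 3-d
#'   array is promoted to a single-channel / single-frame stack).
#' @param calibration An [calibration()] object; its number of channel roles
#'   must match the stack.
#' @return An object of class `ls_movie`.
#' @export
movie_stack <- function(pixels, calibration) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 4L)
    stop("pixels must be a [y, x, channel, frame] array")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and non-negative")
  if (!inherits(calibration, "ls_calibration"))
    stop("calibration must be an ls_calibration object")
  d <- dim(pixels)
  if (length(calibration$channel_roles) != d[3])
    stop(sprintf("calibration lists %d channel roles but stack has %d channels",
                 length(calibration$channel_roles), d[3]))
  structure(
    list(pixels = pixels, calibration = calibration,
         height = d[1], width = d[2], n_channels = d[3], n_frames = d[4]),
    class = "ls_movie")
}

#' @export
print.ls_movie <- function(x, ...) {
  cat(sprintf("MovieStack: %d frame(s), %d channel(s), %d x %d px\n",
              x$n_frames, x$n_channels, x$width, x$height))
  print(x$calibration)
  invisible(x)
}

#' Extract one frame of one channel as a matrix
#'
#' @param movie An `ls_movie`.
#' @param frame 0-based frame index.
#' @param channel 1-based channel index, or a channel role name which is
#'   looked up in the calibration.
#' @return A `height x width` numeric matrix.
#' @export
get_frame <- function(movie, frame, channel) {
  stopifnot(inherits(movie, "ls_movie"))
  if (is.character(channel)) {
    idx <- which(movie$calibration$channel_roles == channel)
    if (length(idx) == 0) stop("no channel with role ", channel)
    channel <- idx[1]
  }
  if (frame < 0 || frame >= movie$n_frames) stop("frame out of range")
  movie$pixels[, , channel, frame + 1L]
}
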