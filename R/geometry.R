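# Shared raster-geometry helpers. Pixel coordinates are 0-based (x = column,
# y = row, origin top-left); a pixel set is an integer matrix with columns
# (x, y). All matrices are indexed [y + 1, x + 1].

#' Boundary pixels of a binary mask
#'
#' A pixel belongs to the boundary if it is foreground and at least one of
#' its 4-neighbours is background or lies outside the image.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same shape marking boundary pixels.
#' @export
boundary_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE  # coerce to logical
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L), drop = FALSE]
  up    <- pad[1:h,        2:(w + 1L), drop = FALSE]
  down  <- pad[3:(h + 2L), 2:(w + 1L), drop = FALSE]
  left  <- pad[2:(h + 1L), 1:w,        drop = FALSE]
  right <- pad[2:(h + 1L), 3:(w + 2L), drop = FALSE]
  inner & !(up & down & left & right)
}

# logical mask -> n x 2 integer matrix of 0-based (x, y), raster order
mask_to_pixels <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = as.integer(idx[, 2] - 1L), y = as.integer(idx[, 1] - 1L))
}

# n x 2 pixel matrix -> logical mask of given shape
pixels_to_mask <- function(pixels, height, width) {
  m <- matrix(FALSE, height, width)
  if (nrow(pixels)) m[cbind(pixels[, 2] + 1L, pixels[, 1] + 1L)] <- TRUE
  m
}

#' Rasterise a disc with the pixel-centre-inside rule
#'
#' Returns the 0-based pixel coordinates whose centres lie within `radius`
#' of `(cx, cy)` (all in pixel units), clipped to the image.
#'
#' @param cx,cy Disc centre in pixel coordinates (may be fractional).
#' @param radius Disc radius in pixels.
#' @param height,width Image dimensions.
#' @return Integer matrix with columns (x, y).
#' @export
raster_disc <- function(cx, cy, radius, height, width) {
  x0 <- max(0L, floor(cx - radius)); x1 <- min(width - 1L, ceiling(cx + radius))
  y0 <- max(0L, floor(cy - radius)); y1 <- min(height - 1L, ceiling(cy + radius))
  if (x1 < x0 || y1 < y0)
    return(cbind(x = integer(0), y = integer(0)))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
  dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
  keep <- which(dx2 + dy2 <= radius^2, arr.ind = TRUE)
  cbind(x = as.integer(xs[keep[, 2]]), y = as.integer(ys[keep[, 1]]))
}

# Simple-polygon check: no two non-adjacent edges intersect.
polygon_is_simple <- function(vertices) {
  n <- nrow(vertices)
  if (n < 3) return(FALSE)
  seg <- function(i) {
    j <- if (i == n) 1L else i + 1L
    c(vertices[i, 1], vertices[i, 2], vertices[j, 1], vertices[j, 2])
  }
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  intersects <- function(s1, s2) {
    o1 <- orient(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
    o2 <- orient(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
    o3 <- orient(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
    o4 <- orient(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
    (o1 != o2 && o3 != o4)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

# Bresenham line between two 0-based integer pixels, inclusive.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  xs <- integer(0); ys <- integer(0)
  repeat {
    xs <- c(xs, x0); ys <- c(ys, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(x = xs, y = ys)
}
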