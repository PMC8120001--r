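# Per-frame segmentation. Neutrophils: cytoplasmic fluorescence is
# binarised (fixed empirical threshold or Otsu) and labelled with
# 8-connected components; macrophage nuclei: a trainable pixel classifier
# produces a probability map that is binarised at a fixed probability.
# Detected objects then pass size-based filters to remove noise.

new_detection <- function(frame, object_id, lineage, pixels, pixel_size) {
  # boundary relative to the object itself, computed on its bounding box
  x0 <- min(pixels[, 1]); y0 <- min(pixels[, 2])
  local <- cbind(pixels[, 1] - x0, pixels[, 2] - y0)
  bnd <- mask_to_pixels(boundary_mask(
    pixels_to_mask(local, max(local[, 2]) + 1L, max(local[, 1]) + 1L)))
  boundary <- cbind(x = bnd[, 1] + x0, y = bnd[, 2] + y0)
  structure(
    list(frame = as.integer(frame), object_id = as.integer(object_id),
         lineage = lineage, pixels = pixels, boundary = boundary,
         centroid_px = c(x = mean(pixels[, 1]), y = mean(pixels[, 2])),
         centroid_um = c(x = mean(pixels[, 1]), y = mean(pixels[, 2])) * pixel_size,
         area_um2 = nrow(pixels) * pixel_size^2),
    class = "ls_detection")
}

# Label a binary mask and build size-filtered detections. Components are
# numbered in raster-scan order of their topmost-leftmost pixel.
detections_from_mask <- function(mask, frame, lineage, min_area_um2,
                                 max_area_um2, pixel_size) {
  if (max_area_um2 < min_area_um2)
    stop("max_area_um2 must be >= min_area_um2")
  if (!any(mask)) return(list())
  labels <- cpp_label_components(mask, 8L)
  n <- max(labels)
  out <- list()
  oid <- 0L
  px_area <- pixel_size^2
  idx <- which(labels > 0, arr.ind = TRUE)
  by_label <- split(seq_len(nrow(idx)), labels[idx])
  for (lab in seq_len(n)) {
    rows <- idx[by_label[[as.character(lab)]], , drop = FALSE]
    area <- nrow(rows) * px_area
    if (area < min_area_um2 || area > max_area_um2) next
    oid <- oid + 1L
    pixels <- cbind(x = as.integer(rows[, 2] - 1L),
                    y = as.integer(rows[, 1] - 1L))
    out[[oid]] <- new_detection(frame, oid, lineage, pixels, pixel_size)
  }
  out
}

#' Otsu's automatic intensity threshold
#'
#' Maximises between-class variance on a 256-bin histogram of the image
#' range. Returns a threshold value on the intensity scale; binarise with
#' `image >= threshold`.
#'
#' @param image Numeric matrix.
#' @return A single threshold value.
#' @export
otsu_threshold <- function(image) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  nb <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  breaks[k + 1L]  # lower edge of the first background-excluded bin
}

#' Segment cytoplasmic (neutrophil) signal in one frame
#'
#' Binarises at a fixed empirical intensity (or Otsu's method), labels
#' 8-connected components, and discards components outside the size filter.
#' Detections are numbered in raster-scan order of their topmost-leftmost
#' pixel. A blank frame yields an empty list.
#'
#' @param frame_image Single-channel numeric matrix.
#' @param threshold_spec A fixed intensity, or `"otsu"`.
#' @param min_area_um2,max_area_um2 Inclusive size filter in um^2.
#' @param pixel_size um per pixel.
#' @param frame 0-based frame index stored on the detections.
#' @param lineage Lineage label stored on the detections.
#' @param smooth_sigma Optional Gaussian pre-smoothing SD in pixels (0 = off).
#' @return List of `ls_detection` objects.
#' @export
segment_cytoplasmic <- function(frame_image, threshold_spec = "otsu",
                                min_area_um2 = 30, max_area_um2 = 800,
                                pixel_size = 1, frame = 0L,
                                lineage = "neutrophil", smooth_sigma = 0) {
  stopifnot(is.matrix(frame_image))
  if (smooth_sigma > 0)
    frame_image <- cpp_sep_convolve(frame_image, gaussian_kernel(smooth_sigma))
  thr <- if (identical(threshold_spec, "otsu")) otsu_threshold(frame_image)
         else if (is.numeric(threshold_spec)) threshold_spec
         else stop("threshold_spec must be numeric or \"otsu\"")
  detections_from_mask(frame_image >= thr, frame, lineage,
                       min_area_um2, max_area_um2, pixel_size)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Multi-scale feature bank: raw intensity plus, per scale, the Gaussian
# smoothing, its gradient magnitude (central differences) and its Laplacian.
compute_feature_stack <- function(image, sigmas) {
  feats <- list(raw = image)
  h <- nrow(image); w <- ncol(image)
  shift <- function(m, dy, dx) {
    ys <- pmin(pmax(seq_len(h) + dy, 1L), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1L), w)
    m[ys, xs, drop = FALSE]
  }
  for (s in sigmas) {
    g <- cpp_sep_convolve(image, gaussian_kernel(s))
    gx <- (shift(g, 0L, 1L) - shift(g, 0L, -1L)) / 2
    gy <- (shift(g, 1L, 0L) - shift(g, -1L, 0L)) / 2
    lap <- shift(g, 0L, 1L) + shift(g, 0L, -1L) +
           shift(g, 1L, 0L) + shift(g, -1L, 0L) - 4 * g
    feats[[sprintf("gauss_s%g", s)]] <- g
    feats[[sprintf("gradmag_s%g", s)]] <- sqrt(gx^2 + gy^2)
    feats[[sprintf("laplacian_s%g", s)]] <- lap
  }
  feats
}

feature_matrix_at <- function(feats, xs, ys) {
  idx <- cbind(ys + 1L, xs + 1L)
  m <- vapply(feats, function(f) f[idx], numeric(length(xs)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}

#' Train a probabilistic pixel classifier for nuclei
#'
#' Fits a logistic model of P(nucleus) on a multi-scale feature bank (raw
#' intensity; Gaussian smoothing, gradient magnitude and Laplacian at each
#' scale) from sparse user labels. Training is deterministic given `seed`
#' (used only to subsample over-large label sets).
#'
#' @param images A single image matrix or a list of them.
#' @param labels Data frame with columns `image` (1-based index into
#'   `images`), `x`, `y` (0-based pixel coordinates) and `class`
#'   (`"nucleus"` or `"background"`). Both classes must be present.
#' @param seed Integer seed for label subsampling.
#' @param sigmas Feature-bank scales in pixels (>= 2 scales).
#' @param max_per_class Cap on labelled pixels per class.
#' @return An object of class `ls_pixel_classifier`.
#' @export
train_pixel_classifier <- function(images, labels, seed = 1L,
                                   sigmas = c(1, 2), max_per_class = 10000L) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(sigmas) >= 2)
  labels$class <- as.character(labels$class)
  if (!all(labels$class %in% c("nucleus", "background")))
    stop("label classes must be 'nucleus' or 'background'")
  counts <- table(factor(labels$class, c("nucleus", "background")))
  if (any(counts == 0))
    stop("need at least one labelled pixel per class; missing: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  if (is.null(labels$image)) labels$image <- 1L
  rows <- seq_len(nrow(labels))
  if (any(counts > max_per_class)) {
    set.seed(as.integer(seed))
    rows <- unlist(lapply(split(rows, labels$class), function(r)
      if (length(r) > max_per_class) sort(sample(r, max_per_class)) else r))
    rows <- sort(rows)
  }
  labels <- labels[rows, ]
  X <- NULL; y <- NULL
  for (i in sort(unique(labels$image))) {
    sub <- labels[labels$image == i, ]
    feats <- compute_feature_stack(images[[i]], sigmas)
    X <- rbind(X, feature_matrix_at(feats, as.integer(sub$x), as.integer(sub$y)))
    y <- c(y, as.integer(sub$class == "nucleus"))
  }
  df <- as.data.frame(X)
  df$.y <- y
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial(), control = list(maxit = 50)))
  structure(
    list(coefficients = stats::coef(fit), sigmas = sigmas,
         feature_names = colnames(X),
         n_labels = as.vector(table(factor(y, c(1, 0)))),
         seed = as.integer(seed)),
    class = "ls_pixel_classifier")
}

#' @export
print.ls_pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "Pixel classifier: %d features at scales %s; trained on %d nucleus / %d background px\n",
    length(x$feature_names), paste(x$sigmas, collapse = ", "),
    x$n_labels[1], x$n_labels[2]))
  invisible(x)
}

#' Per-pixel nucleus probability map
#'
#' @param classifier A trained [train_pixel_classifier()] model.
#' @param image Single-channel numeric matrix.
#' @return Matrix of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(classifier, image) {
  stopifnot(inherits(classifier, "ls_pixel_classifier"))
  feats <- compute_feature_stack(image, classifier$sigmas)
  beta <- classifier$coefficients
  eta <- matrix(beta[1], nrow(image), ncol(image))
  for (nm in classifier$feature_names) {
    b <- beta[match(c(nm, paste0("`", nm, "`")), names(beta))]
    b <- b[!is.na(b)][1]
    if (is.na(b)) next  # dropped (aliased) feature
    eta <- eta + b * feats[[nm]]
  }
  1 / (1 + exp(-eta))
}

#' Segment macrophage nuclei with a pixel classifier
#'
#' Thresholds the classifier's probability map at a fixed probability
#' (`map >= prob_threshold`), labels 8-connected components and applies the
#' size filter, with the same deterministic numbering as
#' [segment_cytoplasmic()].
#'
#' @inheritParams segment_cytoplasmic
#' @param classifier A trained [train_pixel_classifier()].
#' @param prob_threshold Probability cut in (0, 1); default 0.5.
#' @return List of `ls_detection` objects.
#' @export
segment_nuclei <- function(frame_image, classifier, prob_threshold = 0.5,
                           min_area_um2 = 10, max_area_um2 = 300,
                           pixel_size = 1, frame = 0L,
                           lineage = "macrophage") {
  if (!inherits(classifier, "ls_pixel_classifier"))
    stop("classifier must be a trained ls_pixel_classifier")
  stopifnot(prob_threshold > 0, prob_threshold < 1)
  pmap <- predict_probability(classifier, frame_image)
  detections_from_mask(pmap >= prob_threshold, frame, lineage,
                       min_area_um2, max_area_um2, pixel_size)
}
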