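# Minimal baseline-TIFF codec for calibrated grayscale stacks.
#
# Scope: uncompressed, single-sample-per-pixel pages; 8/16-bit unsigned or
# 32-bit float samples; little- or big-endian files; multi-page stacks with
# ImageJ-style hyperstack metadata ("images=/channels=/slices=/frames=") in
# the ImageDescription of the first page, channel index varying fastest.
# This covers stacks written by this package, by ImageJ/Fiji ("Save as
# Tiff"), and by tifffile's default writer. Tiled, compressed or RGB TIFFs
# are out of scope and rejected with a clear error.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

read_tiff_tag_values <- function(raw, pos, type, count, endian) {
  if (type < 1 || type > length(TIFF_TYPE_SIZES)) return(NULL)
  size <- TIFF_TYPE_SIZES[type]
  nbytes <- size * count
  val_field <- raw[pos:(pos + 3)]
  if (nbytes > 4) {
    off <- readBin(val_field, "integer", 1, 4, endian = endian)
    bytes <- raw[(off + 1):(off + nbytes)]
  } else {
    bytes <- val_field[1:nbytes]
  }
  switch(as.character(type),
    "1" = as.integer(bytes),
    "2" = rawToChar(bytes[bytes != as.raw(0)]),
    "3" = readBin(bytes, "integer", count, 2, signed = FALSE, endian = endian),
    "4" = readBin(bytes, "integer", count, 4, endian = endian),
    "5" = ,
    "10" = {  # (S)RATIONAL: numerator / denominator pairs
      v <- readBin(bytes, "integer", 2 * count, 4, endian = endian)
      v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
    },
    "11" = readBin(bytes, "double", count, 4, endian = endian),
    "12" = readBin(bytes, "double", count, 8, endian = endian),
    NULL)  # unknown type: ignore the tag
}

# Read every page of a TIFF file into a list(pages = list of matrices,
# description = chr or NULL). Matrices are [y, x].
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little"
            else if (order_tag == "MM") "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  magic <- readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = endian)
  if (magic != 42) stop("not a classic TIFF file: ", path)
  ifd_off <- readBin(raw[5:8], "integer", 1, 4, endian = endian)
  pages <- list()
  description <- NULL
  while (ifd_off > 0) {
    n_entries <- readBin(raw[(ifd_off + 1):(ifd_off + 2)], "integer", 1, 2,
                         signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      base <- ifd_off + 2 + (i - 1) * 12
      id <- readBin(raw[(base + 1):(base + 2)], "integer", 1, 2,
                    signed = FALSE, endian = endian)
      type <- readBin(raw[(base + 3):(base + 4)], "integer", 1, 2,
                      signed = FALSE, endian = endian)
      count <- readBin(raw[(base + 5):(base + 8)], "integer", 1, 4,
                       endian = endian)
      tags[[as.character(id)]] <-
        read_tiff_tag_values(raw, base + 9, type, count, endian)
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page missing required tag ", id)
        default
      } else v
    }
    width <- need(256); height <- need(257)
    bits <- need(258, 1L)[1]
    compression <- need(259, 1L)
    if (compression != 1) stop("compressed TIFFs are not supported")
    if (!is.null(tags[["322"]])) stop("tiled TIFFs are not supported")
    spp <- need(277, 1L)
    if (spp != 1) stop("only single-sample (grayscale) TIFFs are supported")
    sample_format <- need(339, 1L)
    offsets <- need(273); counts <- need(279)
    if (is.null(description) && !is.null(tags[["270"]]))
      description <- tags[["270"]]
    data <- raw(0)
    pieces <- vector("list", length(offsets))
    for (s in seq_along(offsets))
      pieces[[s]] <- raw[(offsets[s] + 1):(offsets[s] + counts[s])]
    data <- do.call(c, pieces)
    npx <- as.numeric(width) * height
    vals <- switch(paste(sample_format, bits),
      "1 8" = as.numeric(as.integer(data[1:npx])),
      "1 16" = as.numeric(readBin(data, "integer", npx, 2, signed = FALSE,
                                  endian = endian)),
      "1 32" = {
        v <- readBin(data, "integer", npx, 4, endian = endian)
        v[v < 0] <- v[v < 0] + 2^32
        as.numeric(v)
      },
      "3 32" = readBin(data, "double", npx, 4, endian = endian),
      stop(sprintf("unsupported sample layout: format %d, %d bits",
                   sample_format, bits)))
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, ncol = width,
                                          byrow = TRUE)
    next_off_pos <- ifd_off + 2 + n_entries * 12
    ifd_off <- readBin(raw[(next_off_pos + 1):(next_off_pos + 4)], "integer",
                       1, 4, endian = endian)
  }
  list(pages = pages, description = description)
}

parse_imagej_description <- function(description) {
  out <- list()
  if (is.null(description) || !grepl("ImageJ", description)) return(out)
  for (key in c("images", "channels", "slices", "frames")) {
    m <- regmatches(description,
                    regexpr(paste0(key, "=[0-9]+"), description))
    if (length(m)) out[[key]] <- as.integer(sub(".*=", "", m))
  }
  out
}

#' Read a calibrated movie from a TIFF stack
#'
#' Pages are interpreted as an ImageJ-style hyperstack (channel fastest,
#' then z, then time) using the embedded `ImageJ` description when present;
#' otherwise the channel count is taken from the calibration's channel
#' roles. Z-stacks are reduced to 2-d by maximum-intensity projection before
#' any analysis. Calibration always comes from the `calibration` argument;
#' embedded physical metadata is ignored.
#'
#' @param path Path to a TIFF/OME-TIFF file (uncompressed grayscale pages).
#' @param calibration An [calibration()] object.
#' @param n_channels Optional override for the number of channels when the
#'   file carries no hyperstack metadata and the page count is ambiguous.
#' @return An [movie_stack()].
#' @export
read_movie <- function(path, calibration, n_channels = NULL) {
  stopifnot(inherits(calibration, "ls_calibration"))
  tf <- read_tiff_pages(path)
  pages <- tf$pages
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  meta <- parse_imagej_description(tf$description)
  n_pages <- length(pages)
  nc <- if (!is.null(meta$channels)) meta$channels
        else if (!is.null(n_channels)) as.integer(n_channels)
        else length(calibration$channel_roles)
  nz <- if (!is.null(meta$slices)) meta$slices else 1L
  if (n_pages %% (nc * nz) != 0)
    stop(sprintf(paste0("cannot lay out %d pages as %d channel(s) x %d ",
                        "slice(s); pass n_channels to disambiguate"),
                 n_pages, nc, nz))
  nt <- n_pages %/% (nc * nz)
  if (nc != length(calibration$channel_roles))
    warning(sprintf(paste0("file reports %d channels but calibration lists ",
                           "%d roles; using the file layout"),
                    nc, length(calibration$channel_roles)))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(h, w, nc, nt))
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      # max-intensity projection over z
      acc <- pages[[(t - 1L) * nc * nz + c]]
      if (nz > 1L) {
        for (z in 2:nz) {
          pg <- pages[[(t - 1L) * nc * nz + (z - 1L) * nc + c]]
          acc <- pmax(acc, pg)
        }
      }
      arr[, , c, t] <- acc
    }
  }
  movie_stack(arr, calibration)
}

tiff_tag <- function(id, type, count, value_raw, endian = "little") {
  stopifnot(length(value_raw) <= 4)
  pad <- as.raw(rep(0, 4 - length(value_raw)))
  c(writeBin(as.integer(id), raw(), 2, endian = endian),
    writeBin(as.integer(type), raw(), 2, endian = endian),
    writeBin(as.integer(count), raw(), 4, endian = endian),
    value_raw, pad)
}

#' Write a movie (or plain pixel array) as a multi-page TIFF
#'
#' Writes uncompressed little-endian 16-bit pages (channel varying fastest)
#' with ImageJ hyperstack metadata, so the file round-trips through
#' [read_movie()] bit-exactly and opens in Fiji. Intensities must be
#' integers in `[0, 65535]`.
#'
#' @param movie An [movie_stack()] or a `[y, x, channel, frame]` array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  arr <- if (inherits(movie, "ls_movie")) movie$pixels else movie
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L, 1L)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  d <- dim(arr)
  if (any(arr < 0) || any(arr > 65535) || any(arr != round(arr)))
    stop("write_movie requires integer intensities in [0, 65535]")
  h <- d[1]; w <- d[2]; nc <- d[3]; nt <- d[4]
  n_pages <- nc * nt
  desc <- sprintf("ImageJ=1.53t\nimages=%d\nchannels=%d\nslices=1\nframes=%d\nhyperstack=true\n",
                  n_pages, nc, nt)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  u32 <- function(x) writeBin(as.integer(x), raw(), 4, endian = "little")
  u16v <- function(x) writeBin(as.integer(x), raw(), 2, endian = "little")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, 2, endian = "little")
  offset <- 8
  writeBin(u32(offset), con)  # first IFD immediately after header
  for (p in seq_len(n_pages)) {
    t <- (p - 1L) %/% nc + 1L
    ch <- (p - 1L) %% nc + 1L
    first <- p == 1L
    n_entries <- if (first) 10L else 9L
    ifd_size <- 2 + n_entries * 12 + 4
    desc_off <- offset + ifd_size
    data_off <- if (first) desc_off + length(desc_raw) else desc_off
    data_len <- h * w * 2
    entries <- c(
      tiff_tag(256, 4, 1, u32(w)),
      tiff_tag(257, 4, 1, u32(h)),
      tiff_tag(258, 3, 1, u16v(16)),
      tiff_tag(259, 3, 1, u16v(1)),
      tiff_tag(262, 3, 1, u16v(1)))
    if (first)
      entries <- c(entries, tiff_tag(270, 2, length(desc_raw), u32(desc_off)))
    entries <- c(entries,
      tiff_tag(273, 4, 1, u32(data_off)),
      tiff_tag(277, 3, 1, u16v(1)),
      tiff_tag(278, 4, 1, u32(h)),
      tiff_tag(279, 4, 1, u32(data_len)))
    next_ifd <- if (p == n_pages) 0 else data_off + data_len
    writeBin(u16v(n_entries), con)
    writeBin(entries, con)
    writeBin(u32(next_ifd), con)
    if (first) writeBin(desc_raw, con)
    page <- arr[, , ch, t]
    writeBin(as.integer(t(page)), con, 2, endian = "little")
    offset <- next_ifd
  }
  invisible(path)
}
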