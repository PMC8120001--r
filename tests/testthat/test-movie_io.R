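test_that("movie stacks normalise axes and validate calibration", {
  cal <- calibration(0.5, 2, c("neutrophil", "macrophage"))
  arr <- array(round(runif(16 * 16 * 2 * 60) * 100), c(16, 16, 2, 60))
  m <- movie_stack(arr, cal)
  expect_equal(m$n_frames, 60)
  expect_equal(m$n_channels, 2)
  expect_equal(m$height, 16)

  # degenerate single-frame single-channel image
  single <- movie_stack(matrix(1, 8, 8), calibration(1, 2, "neutrophil"))
  expect_equal(single$n_frames, 1)
  expect_equal(single$n_channels, 1)

  expect_error(calibration(0, 2), "pixel_size")
  expect_error(calibration(1, -1), ">")
  expect_error(calibration(1, 2, "nonsense"), "unknown channel role")
  expect_error(movie_stack(array(-1, c(4, 4, 1, 1)), calibration(1, 2, "other")),
               "non-negative")
  # channel-role count mismatch
  expect_error(movie_stack(arr, calibration(1, 2, "neutrophil")), "channels")
})

test_that("TIFF write/read round-trips pixel data bit-exactly", {
  cal <- calibration(1, 2, c("neutrophil", "macrophage"))
  arr <- array(sample(0:65535, 24 * 20 * 2 * 3, replace = TRUE),
               c(24, 20, 2, 3))
  m <- movie_stack(arr, cal)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(m, path)
  back <- read_movie(path, cal)
  expect_identical(back$pixels, m$pixels + 0)  # numeric storage
  expect_equal(back$n_frames, 3)
  expect_equal(back$n_channels, 2)
})

test_that("simulator movies survive the TIFF round trip", {
  sim <- small_sim()$sim
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(sim$movie, path)
  back <- read_movie(path, sim$movie$calibration)
  expect_identical(back$pixels, sim$movie$pixels)
})

test_that("our TIFFs agree with tifffile and vice versa", {
  skip_if_not(python_available(), "python/tifffile not available")
  cal <- calibration(1, 2, "neutrophil")
  arr <- array(sample(0:65535, 16 * 13 * 4, replace = TRUE), c(16, 13, 1, 4))
  ours <- withr::local_tempfile(fileext = ".tif")
  write_movie(movie_stack(arr, cal), ours)
  csv <- withr::local_tempfile(fileext = ".txt")
  # read with tifffile, dump flat (page-major, row-major within page)
  code <- sprintf(paste0(
    "import tifffile, numpy as np; a = tifffile.imread(%s); ",
    "np.savetxt(%s, a.reshape(-1).astype(np.int64), fmt='%%d')"),
    shQuote(ours), shQuote(csv))
  expect_equal(system2("python", c("-c", shQuote(code))), 0)
  vals <- scan(csv, what = integer(), quiet = TRUE)
  # tifffile flattens row-major over (page, y, x): x fastest, page slowest
  expect_identical(vals, as.integer(aperm(arr[, , 1, ], c(2, 1, 3))))

  # tifffile-written stack read by us
  theirs <- withr::local_tempfile(fileext = ".tif")
  code2 <- sprintf(paste0(
    "import tifffile, numpy as np; rng = np.random.default_rng(5); ",
    "a = rng.integers(0, 65535, size=(5, 11, 17), dtype=np.uint16); ",
    "tifffile.imwrite(%s, a); np.savetxt(%s, a.reshape(-1), fmt='%%d')"),
    shQuote(theirs), shQuote(csv))
  expect_equal(system2("python", c("-c", shQuote(code2))), 0)
  ref <- scan(csv, what = integer(), quiet = TRUE)
  got <- read_movie(theirs, calibration(1, 2, "neutrophil"))
  expect_equal(got$n_frames, 5)
  expect_identical(as.integer(aperm(got$pixels[, , 1, ], c(2, 1, 3))), ref)
})

test_that("JSON annotation dialect round-trips vertices exactly", {
  verts1 <- cbind(x = c(3.25, 40.5, 41, 5), y = c(2, 3.75, 30, 28))
  verts2 <- verts1 + 7
  ann <- annotation_file("clone_a", list(
    list(frame = 0L, vertices = verts1),
    list(frame = 30L, vertices = verts2)))
  expect_equal(length(ann$keyframes), 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$lesion_id, "clone_a")
  expect_identical(back[[1]]$keyframes[[1]]$vertices, verts1)
  expect_identical(back[[1]]$keyframes[[2]]$vertices, verts2)
})

test_that("annotation validation rejects malformed polygons", {
  two_pts <- list(list(frame = 0L, vertices = cbind(c(1, 2), c(1, 2))))
  expect_error(annotation_file("x", two_pts), "fewer than 3")
  bowtie <- list(list(frame = 0L,
                      vertices = cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))))
  expect_error(annotation_file("x", bowtie), "self-intersecting")
  dup <- list(list(frame = 3L, vertices = cbind(c(0, 5, 0), c(0, 0, 5))),
              list(frame = 3L, vertices = cbind(c(0, 5, 0), c(0, 0, 5))))
  expect_error(annotation_file("x", dup), "duplicate")
  ok <- annotation_file("x", list(list(frame = 0L,
                                       vertices = cbind(c(0, 200, 0), c(0, 0, 50)))))
  expect_error(lesionscope:::validate_annotation_bounds(ok, 100, 100),
               "outside")
})

test_that("ImageJ ROI files are parsed with 1-based frames mapped to 0-based", {
  xs <- c(10L, 60L, 55L, 12L); ys <- c(5L, 8L, 40L, 42L)
  # single .roi written by the independent byte writer, tagged t = 15
  roi_path <- withr::local_tempfile(fileext = ".roi")
  writeBin(oracle_roi_bytes(xs, ys, 15L), roi_path)
  anns <- read_annotations(roi_path)
  expect_equal(length(anns), 1)
  kf <- anns[[1]]$keyframes[[1]]
  expect_equal(kf$frame, 14L)
  expect_equal(kf$vertices, cbind(x = as.numeric(xs), y = as.numeric(ys)))

  # zip of three ROIs at t = 1, 15, 45 -> one lesion, keyframes 0, 14, 44
  skip_if_not(nzchar(Sys.which("python")), "python needed to build a zip")
  dir <- withr::local_tempdir()
  for (t in c(1L, 15L, 45L))
    writeBin(oracle_roi_bytes(xs + t, ys, t),
             file.path(dir, sprintf("roi_t%02d.roi", t)))
  zip_path <- file.path(dir, "wound.zip")
  code <- sprintf(paste0(
    "import zipfile, glob, os; z = zipfile.ZipFile(%s, 'w'); ",
    "[z.write(f, os.path.basename(f)) for f in sorted(glob.glob(%s))]; z.close()"),
    shQuote(zip_path), shQuote(file.path(dir, "*.roi")))
  expect_equal(system2("python", c("-c", shQuote(code))), 0)
  anns <- read_annotations(zip_path)
  expect_equal(length(anns), 1)
  expect_equal(anns[[1]]$lesion_id, "wound")
  expect_equal(vapply(anns[[1]]$keyframes, `[[`, integer(1), "frame"),
               c(0L, 14L, 44L))
  expect_equal(anns[[1]]$keyframes[[2]]$vertices[, 1], as.numeric(xs + 15))
})

test_that("package-written ROIs re-read identically", {
  verts <- cbind(x = c(3, 30, 28, 2), y = c(4, 6, 25, 27))
  path <- withr::local_tempfile(fileext = ".roi")
  write_imagej_roi(verts, frame = 9L, path)
  back <- read_annotations(path)[[1]]$keyframes[[1]]
  expect_equal(back$frame, 9L)
  expect_equal(back$vertices, cbind(x = as.numeric(verts[, 1]),
                                    y = as.numeric(verts[, 2])))
})

test_that("write_tables emits sorted CSVs with stable schemas", {
  dir <- withr::local_tempdir()
  # empty results -> header-only events.csv
  empty <- list(detections = list(), tracks = list(),
                distances = measure_distances(list(), list()),
                events = classify_and_extract_events(
                  measure_distances(list(), list())),
                metrics = metrics_table(list(), calibration(1, 2, "other")),
                summary = summarise_interactions(
                  classify_and_extract_events(
                    measure_distances(list(), list()))),
                fish = "f1")
  paths <- write_tables(empty, dir)
  ev <- read.csv(paths[["events"]])
  expect_equal(nrow(ev), 0)
  expect_true(all(c("fish", "track_id", "lesion_id", "start_frame",
                    "end_frame", "class", "min_distance_um", "duration_min")
                  %in% names(ev)))

  # one event at 2 min/frame: frames 10-14 -> duration 10 min
  one_ev <- data.frame(track_id = 3L, lesion_id = "lesion_1",
                       lineage = "neutrophil", frame = 10:14,
                       distance_um = c(12, 11, 9, 9, 10), overlap = FALSE)
  events <- classify_and_extract_events(one_ev, frame_interval = 2)
  expect_equal(nrow(events), 1)
  expect_equal(events$duration_min, 10)
  res1 <- empty; res1$events <- events; res1$fish <- "f2"
  res0 <- empty
  paths <- write_tables(list(res1, res0), dir)  # interleaved fish order
  ev <- read.csv(paths[["events"]])
  expect_equal(ev$fish, "f2")
  expect_equal(ev$duration_min, 10)

  # rows grouped by fish then track
  d2 <- data.frame(track_id = c(2L, 1L), lesion_id = "l", lineage = "neutrophil",
                   frame = c(0L, 0L), distance_um = c(1, 2), overlap = FALSE)
  resA <- empty; resA$distances <- d2; resA$fish <- "zfish"
  resB <- empty; resB$distances <- d2; resB$fish <- "afish"
  paths <- write_tables(list(resA, resB), dir)
  dd <- read.csv(paths[["distances"]])
  expect_equal(dd$fish, c("afish", "afish", "zfish", "zfish"))
  expect_equal(dd$track_id, c(1L, 2L, 1L, 2L))
})
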