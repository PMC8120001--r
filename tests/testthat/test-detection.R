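make_disc_frame <- function(h, w, centres, r, fg = 200, bg = 10) {
  img <- matrix(bg, h, w)
  for (i in seq_len(nrow(centres))) {
    d <- raster_disc(centres[i, 1], centres[i, 2], r, h, w)
    img[cbind(d[, 2] + 1, d[, 1] + 1)] <- fg
  }
  img
}

test_that("cytoplasmic segmentation: thresholds, labelling, size filter", {
  # blank frame
  expect_equal(segment_cytoplasmic(matrix(0, 32, 32), 50), list())

  # two discs of radius 5 px; per-disc area = rasterised pixel count
  img <- make_disc_frame(64, 64, rbind(c(15, 15), c(45, 45)), 5)
  expected_px <- nrow(raster_disc(15, 15, 5, 64, 64))
  dets <- segment_cytoplasmic(img, 100, min_area_um2 = 20,
                              max_area_um2 = 800, pixel_size = 1)
  expect_equal(length(dets), 2)
  expect_equal(vapply(dets, `[[`, numeric(1), "area_um2"),
               rep(expected_px, 2))
  # raster-scan numbering: disc at (15,15) first
  expect_lt(dets[[1]]$centroid_px["y"], dets[[2]]$centroid_px["y"])

  # 50 random bright single pixels are removed by the size filter
  set.seed(99)
  noisy <- img
  hits <- sample(which(noisy < 100), 50)
  noisy[hits] <- 250
  dets2 <- segment_cytoplasmic(noisy, 100, min_area_um2 = 20,
                               max_area_um2 = 800, pixel_size = 1)
  # compare against the brute-force oracle with the same filter
  lab <- oracle_label(noisy >= 100)
  sizes <- table(lab[lab > 0])
  expect_equal(length(dets2), sum(sizes >= 20 & sizes <= 800))
  expect_equal(length(dets2), 2)

  expect_error(segment_cytoplasmic(img, 100, min_area_um2 = 50,
                                   max_area_um2 = 10), "min_area")
})

test_that("otsu threshold separates a bimodal image", {
  img <- make_disc_frame(64, 64, rbind(c(30, 30)), 8, fg = 200, bg = 20)
  thr <- otsu_threshold(img)
  expect_gt(thr, 20)
  expect_lt(thr, 200)
  dets <- segment_cytoplasmic(img, "otsu", 20, 800, 1)
  expect_equal(length(dets), 1)
})

test_that("component labelling matches the flood-fill oracle on random masks", {
  set.seed(1234)
  for (i in 1:40) {
    mask <- random_mask(sample(8:48, 1), sample(8:48, 1),
                        p = runif(1, 0.2, 0.6))
    ours <- lesionscope:::cpp_label_components(mask, 8L)
    expect_identical(label_partition(ours), label_partition(oracle_label(mask)))
    # partition property: labels cover exactly the mask
    expect_identical(ours > 0, mask)
  }
})

test_that("size filter property holds on random frames", {
  set.seed(77)
  for (i in 1:10) {
    img <- matrix(runif(48 * 48) * 255, 48, 48)
    lo <- runif(1, 1, 5); hi <- runif(1, 10, 100)
    dets <- segment_cytoplasmic(img, 128, lo, hi, pixel_size = 1)
    areas <- vapply(dets, `[[`, numeric(1), "area_um2")
    expect_true(all(areas >= lo & areas <= hi))
  }
})

test_that("boundary pixels are object pixels with a 4-neighbour outside", {
  mask <- matrix(FALSE, 7, 7); mask[2:6, 2:6] <- TRUE
  b <- boundary_mask(mask)
  expect_equal(sum(b), 16)           # perimeter of a 5x5 square
  expect_false(b[4, 4])              # interior
  inner <- mask & !b
  expect_equal(sum(inner), 9)
})

test_that("pixel classifier learns a separable fixture and is deterministic", {
  set.seed(5)
  img <- make_disc_frame(96, 96, rbind(c(20, 20), c(70, 30), c(40, 70)), 6,
                         fg = 180, bg = 15)
  img <- img + matrix(rnorm(96 * 96, 0, 8), 96, 96)
  truth_mask <- matrix(FALSE, 96, 96)
  for (c in list(c(20, 20), c(70, 30), c(40, 70))) {
    d <- raster_disc(c[1], c[2], 6, 96, 96)
    truth_mask[cbind(d[, 2] + 1, d[, 1] + 1)] <- TRUE
  }
  labels <- sample_training_labels(truth_mask, 150, seed = 3)
  clf <- train_pixel_classifier(img, labels, seed = 3)
  # held-out nucleus pixels (not in the training set) get P >= 0.9
  pmap <- predict_probability(clf, img)
  train_keys <- paste(labels$x, labels$y)
  fg_px <- mask_to_pixels(truth_mask)
  held <- fg_px[!paste(fg_px[, 1], fg_px[, 2]) %in% train_keys, , drop = FALSE]
  expect_gt(nrow(held), 0)
  expect_true(all(pmap[cbind(held[, 2] + 1, held[, 1] + 1)] >= 0.9))

  # determinism: same inputs + seed -> identical probability maps
  clf2 <- train_pixel_classifier(img, labels, seed = 3)
  expect_identical(pmap, predict_probability(clf2, img))

  # one-class labels error
  expect_error(train_pixel_classifier(img, labels[labels$class == "nucleus", ]),
               "per class")
})

test_that("nucleus segmentation recovers counts and centroids; monotone in threshold", {
  fx <- small_sim()
  img <- get_frame(fx$sim$movie, 3, "macrophage")
  dets <- segment_nuclei(img, fx$clf, 0.5, 10, 300, pixel_size = 1, frame = 3)
  truth <- fx$sim$truth$tracks
  tru <- truth[truth$lineage == "macrophage" & truth$frame == 3, ]
  expect_equal(length(dets), nrow(tru))
  cents <- t(vapply(dets, `[[`, numeric(2), "centroid_um"))
  for (i in seq_len(nrow(tru))) {
    d <- sqrt((cents[, 1] - tru$x_um[i])^2 + (cents[, 2] - tru$y_um[i])^2)
    expect_lt(min(d), 1)
  }
  # probability map identically ~0 -> no detections
  blank <- segment_nuclei(matrix(0, 64, 64) + 15, fx$clf, 0.5, 10, 300, 1)
  expect_equal(length(blank), 0)
  # monotonicity of the probability cut
  strict <- segment_nuclei(img, fx$clf, 0.99, 10, 300, 1)
  expect_lte(length(strict), length(dets))
  expect_error(segment_nuclei(img, "not a classifier", 0.5, 10, 300, 1),
               "classifier")
})

test_that("manual corrections: delete, merge, split, add", {
  px <- 1
  shape <- c(40L, 40L)
  two <- rbind(
    cbind(x = rep(2:7, each = 5), y = rep(2:6, 6)),        # 30 px blob
    cbind(x = rep(10:14, each = 10), y = rep(7:16, 5)))    # 50 px blob
  d1 <- lesionscope:::new_detection(0L, 1L, "macrophage",
                                    two[1:30, ], px)
  d2 <- lesionscope:::new_detection(0L, 2L, "macrophage",
                                    two[31:80, ], px)

  # delete the only detection in a frame
  expect_equal(apply_corrections(list(d1),
                                 list(list(action = "delete", frame = 0L,
                                           object_id = 1L)), px, shape),
               list())

  # merge two blobs that touch: areas 30 + 50 -> 80
  touching <- lesionscope:::new_detection(0L, 2L, "macrophage",
    cbind(x = rep(8:12, each = 10), y = rep(2:11, 5)), px)
  merged <- apply_corrections(list(d1, touching),
                              list(list(action = "merge", frame = 0L,
                                        object_ids = c(1L, 2L))), px, shape)
  expect_equal(length(merged), 1)
  expect_equal(merged[[1]]$area_um2, 80)

  # merging disjoint blobs errors
  expect_error(apply_corrections(list(d1, d2),
                                 list(list(action = "merge", frame = 0L,
                                           object_ids = c(1L, 2L))),
                                 px, shape), "disconnected")

  # split a bar with a vertical polyline -> two parts, pixels conserved
  bar <- lesionscope:::new_detection(0L, 1L, "macrophage",
    cbind(x = rep(5:14, each = 4), y = rep(5:8, 10)), px)
  parts <- apply_corrections(list(bar),
    list(list(action = "split", frame = 0L, object_id = 1L,
              polyline = cbind(c(9, 9), c(0, 39)))), px, shape)
  expect_equal(length(parts), 2)
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "area_um2")), 40)
  # ids renumbered deterministically (raster order)
  expect_equal(vapply(parts, `[[`, integer(1), "object_id"), 1:2)

  # polyline that misses the object does not partition it
  expect_error(apply_corrections(list(bar),
    list(list(action = "split", frame = 0L, object_id = 1L,
              polyline = cbind(c(30, 30), c(0, 39)))), px, shape),
    "partition")

  # add a polygon on an empty frame: area = rasterised polygon area
  sq <- cbind(c(3, 13, 13, 3), c(3, 3, 13, 13))
  added <- apply_corrections(list(),
    list(list(action = "add", frame = 2L, polygon = sq)), px, shape)
  expect_equal(length(added), 1)
  expect_equal(added[[1]]$area_um2, 100)  # pixel-centre rule: 10 x 10
  expect_equal(added[[1]]$frame, 2L)

  # directive referencing a nonexistent object
  expect_error(apply_corrections(list(d1),
    list(list(action = "delete", frame = 0L, object_id = 9L)), px, shape),
    "no detection")
})
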