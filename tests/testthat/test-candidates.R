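test_that("equivalent_diameter follows the area-equivalent closed form", {
  expect_equal(equivalent_diameter(100, 0.5), 2 * sqrt(100 / pi) * 0.5)
  expect_equal(equivalent_diameter(1, 1), 2 * sqrt(1 / pi))
  # linear in spacing
  expect_equal(equivalent_diameter(50, 1.4), 2 * equivalent_diameter(50, 0.7))
})

test_that("elongation separates discs from bars and is rotation invariant", {
  disc <- which(disc_mask(25, 13, 13, 10), arr.ind = TRUE)
  expect_lt(abs(elongation_from_coords(disc) - 1), 0.05)
  bar <- cbind(rep(1, 20), 1:20)
  expect_gte(elongation_from_coords(bar), 10)
  expect_equal(elongation_from_coords(bar),
               elongation_from_coords(bar[, 2:1]))   # 90 degree rotation
  expect_equal(elongation_from_coords(cbind(3, 7)), 1)  # single pixel
})

test_that("extract_rois finds dense components with geometry", {
  n <- 64
  px <- matrix(-800, n, n)
  mask <- matrix(TRUE, n, n)
  img <- gray_image(px, "HU", 0.7)
  expect_equal(nrow(extract_rois(img, mask, -400)), 0)
  # empty mask
  expect_equal(nrow(extract_rois(img, matrix(FALSE, n, n), -400)), 0)
  # one implanted disc
  px[disc_mask(n, 20.5, 30.5, 6)] <- 0
  img <- gray_image(px, "HU", 0.7)
  r <- extract_rois(img, mask, -400)
  expect_equal(nrow(r), 1)
  expect_lt(abs(r$centroid_row - 20.5), 1)
  expect_lt(abs(r$centroid_col - 30.5), 1)
  expect_equal(r$area_px, sum(disc_mask(n, 20.5, 30.5, 6)))
  # two separated discs
  px[disc_mask(n, 48.5, 48.5, 4)] <- 0
  r2 <- extract_rois(gray_image(px, "HU", 0.7), mask, -400)
  expect_equal(nrow(r2), 2)
  expect_length(attr(r2, "pixels"), 2)
})

test_that("prune labels regions by the diameter and elongation rules", {
  n <- 200
  px <- matrix(-800, n, n)
  spacing <- 0.5
  # 2 mm disc (r = 2 px), 10 mm disc (r = 10), 35 mm disc (r = 35), 1x30 bar
  px[disc_mask(n, 20, 20, 2)] <- 0
  px[disc_mask(n, 60, 60, 10)] <- 0
  px[disc_mask(n, 140, 140, 35)] <- 0
  px[30, 120:149] <- 0
  img <- gray_image(px, "HU", spacing)
  regions <- prune(extract_rois(img, matrix(TRUE, n, n), -400))
  expect_equal(nrow(regions), 4)
  lab <- regions$label[order(regions$diameter_mm)]
  # smallest: the bar has area 30 px -> diameter ~3.1 mm but elongation >> 3
  expect_setequal(regions$label, c("pruned_small", "candidate",
                                   "pruned_large", "pruned_vessel"))
  small <- regions[regions$label == "pruned_small", ]
  expect_lt(small$diameter_mm, 3)
  big <- regions[regions$label == "pruned_large", ]
  expect_gt(big$diameter_mm, 30)
  vessel <- regions[regions$label == "pruned_vessel", ]
  expect_gt(vessel$elongation, 3)
  # partition property: labels exhaust the input
  expect_equal(sum(table(regions$label)), nrow(regions))
  # survivors within all bounds
  surv <- regions[regions$label == "candidate", ]
  expect_true(all(surv$diameter_mm >= 3 & surv$diameter_mm <= 30 &
                    surv$elongation <= 3))
})

test_that("median_slice_threshold uses the median slice and separates the modes", {
  ph <- generate_slice(test_phantom_spec(seed = 31))
  mask <- ph$truth$lung_mask
  thr1 <- median_slice_threshold(list(ph$image), list(mask), seed = 1)
  # 5-slice stack with distinct slices: threshold comes from slice 3 only
  slices <- lapply(1:5, function(s) generate_slice(test_phantom_spec(seed = s))$image)
  masks <- lapply(1:5, function(s) generate_slice(test_phantom_spec(seed = s))$truth$lung_mask)
  thr5 <- median_slice_threshold(slices, masks, seed = 1)
  thr3 <- median_slice_threshold(slices[3], masks[3], seed = 1)
  expect_equal(thr5, thr3)
  # separates parenchyma from nodules
  expect_gt(thr1, -700)
  expect_lt(thr1, -100)
  expect_error(median_slice_threshold(slices, lapply(1:5, function(i) matrix(FALSE, 160, 160))),
               "empty")
})

test_that("implanted nodules survive pruning and vessels are rejected", {
  hits <- 0; total <- 0
  for (seed in c(101, 202)) {
    ph <- generate_slice(phantom_spec(seed = seed))
    mask <- segment_lungs(ph$image, seed = seed)
    thr <- median_slice_threshold(list(ph$image), list(mask), seed = seed)
    regions <- prune(extract_rois(ph$image, mask, thr))
    surv <- regions[regions$label == "candidate", ]
    nd <- ph$truth$nodule_records
    for (k in seq_len(nrow(nd))) {
      total <- total + 1
      d <- sqrt((surv$centroid_row - nd$row[k])^2 +
                  (surv$centroid_col - nd$col[k])^2)
      if (any(d <= nd$radius_px[k])) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
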