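test_that("compute_histogram normalizes gray-level frequencies", {
  h <- compute_histogram(gray_image(matrix(9, 4, 4), "uint8"))
  expect_equal(h$levels, 9)
  expect_equal(h$probs, 1)
  h <- compute_histogram(matrix(c(0, 0, 1, 2), 2, 2))
  expect_equal(h$levels, c(0, 1, 2))
  expect_equal(h$probs, c(0.5, 0.25, 0.25))
  set.seed(1)
  h <- compute_histogram(matrix(rnorm(400, 100, 30), 20, 20))
  expect_equal(sum(h$probs), 1, tolerance = 1e-9)
  expect_false(is.unsorted(h$levels, strictly = TRUE))
})

test_that("fit_mixture_from_partition computes interval moments", {
  # two delta spikes
  h <- compute_histogram(c(rep(10, 50), rep(200, 50)))
  m <- fit_mixture_from_partition(h, 100)
  expect_equal(m$weights, c(0.5, 0.5))
  expect_equal(m$means, c(10, 200))
  expect_equal(m$sds, c(1e-3, 1e-3))  # floored
  # discrete uniform on 0..255 split at 128
  h <- structure(list(levels = 0:255, probs = rep(1 / 256, 256)),
                 class = "gray_histogram")
  m <- fit_mixture_from_partition(h, 128)
  expect_equal(m$weights, c(0.5, 0.5))
  expect_equal(m$means, c(63.5, 191.5))
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  # K = 3 partition masses sum to one
  m3 <- fit_mixture_from_partition(h, c(50, 180))
  expect_equal(sum(m3$weights), 1, tolerance = 1e-9)
  expect_equal(m3$K, 3L)
  # degenerate interval errors
  expect_error(fit_mixture_from_partition(h, c(100.2, 100.7)), "degenerate")
  expect_error(fit_mixture_from_partition(h, c(5, 3)), "increasing")
})

test_that("classification_error is the wrong-side Gaussian mass", {
  sep <- structure(list(K = 2L, weights = c(0.5, 0.5),
                        means = c(50, 200), sds = c(5, 5)),
                   class = "gaussian_mixture")
  expect_lt(classification_error(sep, 125), 1e-10)
  same <- structure(list(K = 2L, weights = c(0.5, 0.5),
                         means = c(100, 100), sds = c(10, 10)),
                    class = "gaussian_mixture")
  for (t in c(50, 100, 173)) {
    expect_equal(classification_error(same, t), 0.5)
  }
  # equal-sigma equal-weight classes: minimum at the midpoint
  mid <- structure(list(K = 2L, weights = c(0.5, 0.5),
                        means = c(80, 160), sds = c(12, 12)),
                   class = "gaussian_mixture")
  grid <- seq(81, 159, by = 0.5)
  errs <- vapply(grid, function(t) classification_error(mid, t), numeric(1))
  expect_equal(grid[which.min(errs)], 120)
  expect_error(classification_error(mid, c(1, 2)), "K - 1")
})

test_that("DE thresholds match exhaustive search on synthetic histograms", {
  # bimodal, K = 2
  h2 <- synthetic_histogram(c(60, 180), c(10, 10), c(0.5, 0.5), seed = 5)
  bf <- brute_force_thresholds(h2, 2)
  for (seed in c(1, 7, 23)) {
    de <- de_optimal_thresholds(h2, K = 2, seed = seed)
    expect_lte(abs(de$thresholds - bf$thresholds), 3)
  }
  # trimodal, K = 3
  h3 <- synthetic_histogram(c(40, 120, 210), c(8, 10, 8),
                            c(1, 1, 1) / 3, seed = 9)
  bf3 <- brute_force_thresholds(h3, 3)
  de3 <- de_optimal_thresholds(h3, K = 3, seed = 4)
  expect_true(all(abs(de3$thresholds - bf3$thresholds) <= 3))
  # determinism
  expect_identical(de_optimal_thresholds(h2, K = 2, seed = 11),
                   de_optimal_thresholds(h2, K = 2, seed = 11))
  # infeasible histogram
  h1 <- compute_histogram(rep(5, 10))
  expect_error(de_optimal_thresholds(h1, K = 2), "infeasible")
})

test_that("iterative intermeans threshold finds its fixed point", {
  img <- gray_image(matrix(c(rep(-1000, 50), rep(0, 50)), 10, 10), "HU")
  expect_equal(iterative_initial_threshold(img), -500, tolerance = 0.5)
  expect_warning(t <- iterative_initial_threshold(gray_image(matrix(10, 4, 4), "HU")),
                 "one side")
  expect_equal(t, -950)
  # on clean parenchyma the fixed point stays inside the lung HU band
  ph <- generate_slice(phantom_spec(image_size = 160, n_nodules = 0,
                                    n_vessels = 0, n_clumps = 0, seed = 2))
  t <- iterative_initial_threshold(ph$image, mask = ph$truth$lung_mask)
  expect_gt(t, -950)
  expect_lt(t, -500)
  expect_error(iterative_initial_threshold(gray_image(matrix(1, 3, 3), "uint8")),
               "HU")
})

test_that("remove_background clears border-connected runs only", {
  # dark frame around a bright disc on a 16x16 fixture
  px <- matrix(0, 16, 16)
  px[disc_mask(16, 8.5, 8.5, 5)] <- 200
  img <- gray_image(px, "uint8")
  fg <- remove_background(img, bg_range = c(0, 24))
  expect_true(all(fg[disc_mask(16, 8.5, 8.5, 5)]))
  expect_false(any(fg & px == 0))
  # image entirely in range: empty foreground
  allbg <- gray_image(matrix(5, 8, 8), "uint8")
  expect_false(any(remove_background(allbg, bg_range = c(0, 24))))
  # corner pixels in range are never foreground
  set.seed(12)
  px <- matrix(sample(0:255, 100, TRUE), 10, 10)
  px[1, 1] <- 0
  fg <- remove_background(gray_image(px, "uint8"), bg_range = c(0, 24))
  expect_false(fg[1, 1])
})

test_that("corner-seeded growing removes only corner components", {
  m <- matrix(FALSE, 12, 12)
  m[1:4, 1:4] <- TRUE              # corner-touching
  m[7:9, 7:9] <- TRUE              # interior blob
  out <- corner_seeded_region_growing(m)
  expect_false(any(out[1:4, 1:4]))
  expect_true(all(out[7:9, 7:9]))
  expect_equal(corner_seeded_region_growing(matrix(FALSE, 5, 5)),
               matrix(FALSE, 5, 5))
  interior <- matrix(FALSE, 8, 8); interior[4:5, 4:5] <- TRUE
  expect_equal(corner_seeded_region_growing(interior), interior)
})

test_that("fill_holes fills interior holes and is idempotent", {
  ring <- disc_mask(21, 11, 11, 8) & !disc_mask(21, 11, 11, 4)
  filled <- fill_holes(ring)
  expect_equal(filled, disc_mask(21, 11, 11, 8))
  disc <- disc_mask(15, 8, 8, 5)
  expect_equal(fill_holes(disc), disc)
  # two rings -> two discs, component count preserved
  two <- (disc_mask(40, 10, 10, 7) & !disc_mask(40, 10, 10, 3)) |
    (disc_mask(40, 28, 28, 7) & !disc_mask(40, 28, 28, 3))
  f2 <- fill_holes(two)
  n_before <- attr(label_components(two, 8L), "n_components")
  n_after <- attr(label_components(f2, 8L), "n_components")
  expect_equal(n_before, n_after)
  expect_equal(fill_holes(f2), f2)
})

test_that("segment_lungs recovers phantom lung fields", {
  for (seed in c(3, 14)) {
    ph <- generate_slice(test_phantom_spec(seed = seed))
    mask <- segment_lungs(ph$image, seed = seed)
    dice <- 2 * sum(mask & ph$truth$lung_mask) /
      (sum(mask) + sum(ph$truth$lung_mask))
    expect_gte(dice, 0.95)
    frac <- mean(mask)
    expect_gt(frac, 0.05)
    expect_lt(frac, 0.6)
  }
  # solid body, no lungs: empty mask + warning
  solid <- matrix(-1000, 96, 96)
  solid[20:76, 20:76] <- 40
  expect_warning(m <- segment_lungs(gray_image(solid, "HU"), seed = 1),
                 "empty mask")
  expect_false(any(m))
})
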