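#' Synthetic thorax phantom specification
#'
#' The phantom emulates a single axial chest CT slice at the intensity
#' scale the pipeline's rules are written for: scanner air background at
#' -1000 HU, a soft-tissue body ellipse at ~40 HU, two elliptical lung
#' fields filled with smoothly varying parenchyma inside the -950..-500 HU
#' band, tubular vessels (~-50 HU) drawn as jittered random walks, and
#' smooth-profile nodule discs with diameters in the 3-30 mm plausibility
#' window (5-20 mm by default, the size range detection focuses on).
#' Additive Gaussian noise and an optional global contrast compression
#' emulate acquisition noise and low-contrast scans.
#'
#' @param image_size side length in pixels, default 256.
#' @param spacing_mm isotropic in-plane spacing, default 0.7 mm (mid LIDC
#'   in-plane resolution range).
#' @param n_nodules nodules per slice, default 2.
#' @param nodule_diameter_range_mm sampled diameter range, default c(5, 20).
#' @param nodule_hu_range sampled mean nodule density, default c(-100, 100)
#'   HU (subsolid through solid), >= 300 HU above parenchyma so the optimal
#'   threshold has a recoverable optimum.
#' @param n_vessels random-walk vessels per slice, default 3.
#' @param n_clumps focal opacity clumps per slice, default 2: irregular
#'   unions of small discs at -250..-120 HU that emulate scarring /
#'   ground-glass opacities — dense enough to be extracted as candidates,
#'   compact enough to survive pruning, so they provide the non-nodule
#'   class the false-positive-reduction classifier must reject.
#' @param n_specks sub-3 mm distractor discs (exercise the small-diameter
#'   pruning rule), default 0.
#' @param noise_sigma_hu additive Gaussian noise, default 20 HU.
#' @param contrast_degradation in \[0, 1\]; compresses the intensity range
#'   about its mean by this fraction, default 0.
#' @param seed integer; the same seed gives bitwise-identical output.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, spacing_mm = 0.7,
                         n_nodules = 2L,
                         nodule_diameter_range_mm = c(5, 20),
                         nodule_hu_range = c(-100, 100),
                         n_vessels = 3L, n_clumps = 2L, n_specks = 0L,
                         noise_sigma_hu = 20,
                         contrast_degradation = 0, seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               spacing_mm = spacing_mm,
               n_nodules = as.integer(n_nodules),
               nodule_diameter_range_mm = nodule_diameter_range_mm,
               nodule_hu_range = nodule_hu_range,
               n_vessels = as.integer(n_vessels),
               n_clumps = as.integer(n_clumps),
               n_specks = as.integer(n_specks),
               noise_sigma_hu = noise_sigma_hu,
               contrast_degradation = contrast_degradation,
               seed = as.integer(seed))
  stopifnot(spec$image_size >= 64L, spec$spacing_mm > 0,
            spec$n_nodules >= 0L, spec$noise_sigma_hu >= 0,
            spec$contrast_degradation >= 0, spec$contrast_degradation <= 1,
            diff(spec$nodule_diameter_range_mm) >= 0)
  class(spec) <- "phantom_spec"
  spec
}

#' Generate one phantom slice with ground truth
#'
#' See [phantom_spec()] for the emulated geometry. Nodule centres are
#' sampled inside the lung fields with a margin so every nodule lies fully
#' within a lung, and rejected if they overlap an already placed nodule;
#' after 200 failed retries an error reports how many were placed. Vessel
#' walks terminate when they approach a nodule so implanted nodules stay
#' geometrically isolated (their intensities would otherwise merge into
#' one elongated region and be pruned as vessels).
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (HU [gray_image()]) and `truth` — a list with
#'   `lung_mask`, `vessel_mask` (logical matrices), `nodule_records` and
#'   `speck_records` (data frames: `row`, `col`, `diameter_mm`,
#'   `radius_px`, `mean_hu`).
#' @export
generate_slice <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)

  n <- spec$image_size
  rc <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  ctr <- (n + 1) / 2
  img <- matrix(-1000, n, n)

  # body and lung ellipses
  body <- ((rc - ctr) / (0.40 * n))^2 + ((cc - ctr) / (0.46 * n))^2 <= 1
  img[body] <- 40
  lung_l <- ((rc - ctr) / (0.27 * n))^2 +
    ((cc - (ctr - 0.22 * n)) / (0.15 * n))^2 <= 1
  lung_r <- ((rc - ctr) / (0.27 * n))^2 +
    ((cc - (ctr + 0.22 * n)) / (0.15 * n))^2 <= 1
  lung <- lung_l | lung_r

  # parenchyma: smooth correlated texture clipped into the lung HU band
  field <- smooth_field(n, width = 9L)
  paren <- pmin(pmax(-800 + 70 * field, -945), -545)
  img[lung] <- paren[lung]

  # nodule geometry first (vessels must keep clear of it)
  nd <- sample_nodules(spec, lung, n)
  keep_clear <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(nd))) {
    keep_clear <- keep_clear |
      (rc - nd$row[k])^2 + (cc - nd$col[k])^2 <= (nd$radius_px[k] + 4)^2
  }

  # vessels: jittered random walks stamped as tubes
  vessel_mask <- matrix(FALSE, n, n)
  for (v in seq_len(spec$n_vessels)) {
    vessel_mask <- vessel_mask |
      vessel_walk(lung, keep_clear, n, width_px = sample(1:4, 1L))
  }
  img[vessel_mask] <- -50 + stats::rnorm(sum(vessel_mask), 0, 10)

  # focal opacity clumps: lumpy unions of small discs, kept clear of nodules
  clump_mask <- matrix(FALSE, n, n)
  for (cl in seq_len(spec$n_clumps)) {
    for (try in seq_len(100L)) {
      i <- stats::runif(1, 1, n); j <- stats::runif(1, 1, n)
      if (!inside_eroded(lung, i, j, 8) ||
          keep_clear[round(i), round(j)]) next
      n_sub <- sample(3:5, 1L)
      for (s in seq_len(n_sub)) {
        di <- i + stats::rnorm(1, 0, 3); dj <- j + stats::rnorm(1, 0, 3)
        r_s <- stats::runif(1, 2, 5)
        hu_s <- stats::runif(1, -250, -120)
        d2 <- sqrt((rc - di)^2 + (cc - dj)^2)
        w <- pmin(pmax((r_s - d2) / 0.8, 0), 1) * lung * !keep_clear
        sel <- w > 0
        img[sel] <- img[sel] + w[sel] * (hu_s - img[sel])
        clump_mask <- clump_mask | (sel & lung)
      }
      break
    }
  }

  # nodules: smooth-profile discs blended over the parenchyma
  for (k in seq_len(nrow(nd))) {
    d2 <- sqrt((rc - nd$row[k])^2 + (cc - nd$col[k])^2)
    w <- pmin(pmax((nd$radius_px[k] - d2) / 1.5, 0), 1)
    sel <- w > 0
    img[sel] <- img[sel] + w[sel] * (nd$mean_hu[k] - img[sel])
  }

  # sub-3 mm specks: same construction, diameter 2 mm
  sp <- sample_specks(spec, lung, keep_clear | vessel_mask, n)
  for (k in seq_len(nrow(sp))) {
    d2 <- sqrt((rc - sp$row[k])^2 + (cc - sp$col[k])^2)
    w <- pmin(pmax((sp$radius_px[k] - d2) / 1.0, 0), 1)
    sel <- w > 0
    img[sel] <- img[sel] + w[sel] * (sp$mean_hu[k] - img[sel])
  }

  if (spec$noise_sigma_hu > 0) {
    img <- img + stats::rnorm(n * n, 0, spec$noise_sigma_hu)
  }
  if (spec$contrast_degradation > 0) {
    m <- mean(img)
    img <- m + (1 - spec$contrast_degradation) * (img - m)
  }

  list(image = gray_image(img, "HU", spec$spacing_mm),
       truth = list(lung_mask = lung, vessel_mask = vessel_mask,
                    clump_mask = clump_mask,
                    nodule_records = nd, speck_records = sp))
}

# Correlated Gaussian field: white noise box-blurred twice, unit variance.
smooth_field <- function(n, width = 9L) {
  f <- matrix(stats::rnorm(n * n), n, n)
  for (pass in 1:2) {
    f <- box_blur_1d(f, width)
    f <- t(box_blur_1d(t(f), width))
  }
  (f - mean(f)) / stats::sd(f)
}

box_blur_1d <- function(m, width) {
  k <- rep(1 / width, width)
  n <- nrow(m)
  padded <- rbind(m[width:1, , drop = FALSE], m,
                  m[n:(n - width + 1L), , drop = FALSE])
  out <- stats::filter(padded, k, sides = 2)   # column-wise
  matrix(out[width + seq_len(n), ], n, ncol(m))
}

sample_nodules <- function(spec, lung, n) {
  rec <- data.frame(row = numeric(0), col = numeric(0),
                    diameter_mm = numeric(0), radius_px = numeric(0),
                    mean_hu = numeric(0))
  for (k in seq_len(spec$n_nodules)) {
    d_mm <- stats::runif(1, spec$nodule_diameter_range_mm[1],
                         spec$nodule_diameter_range_mm[2])
    r_px <- d_mm / (2 * spec$spacing_mm)
    hu <- stats::runif(1, spec$nodule_hu_range[1], spec$nodule_hu_range[2])
    placed <- FALSE
    for (try in seq_len(200L)) {
      i <- stats::runif(1, 1, n); j <- stats::runif(1, 1, n)
      if (!inside_eroded(lung, i, j, r_px + 2)) next
      if (nrow(rec) > 0 &&
          any(sqrt((rec$row - i)^2 + (rec$col - j)^2) <
                rec$radius_px + r_px + 4)) next
      rec <- rbind(rec, data.frame(row = i, col = j, diameter_mm = d_mm,
                                   radius_px = r_px, mean_hu = hu))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("could not place nodule %d without overlap (%d placed)",
                   k, nrow(rec)), call. = FALSE)
    }
  }
  rec
}

sample_specks <- function(spec, lung, avoid, n) {
  rec <- data.frame(row = numeric(0), col = numeric(0),
                    diameter_mm = numeric(0), radius_px = numeric(0),
                    mean_hu = numeric(0))
  for (k in seq_len(spec$n_specks)) {
    r_px <- 2 / (2 * spec$spacing_mm)          # 2 mm diameter
    for (try in seq_len(200L)) {
      i <- stats::runif(1, 1, n); j <- stats::runif(1, 1, n)
      ii <- round(i); jj <- round(j)
      if (!inside_eroded(lung, i, j, r_px + 2) || avoid[ii, jj]) next
      rec <- rbind(rec, data.frame(row = i, col = j, diameter_mm = 2,
                                   radius_px = r_px, mean_hu = 50))
      break
    }
  }
  rec
}

# crude erosion test: the disc of radius r around (i, j) stays inside mask
inside_eroded <- function(mask, i, j, r) {
  n <- nrow(mask)
  probes <- rbind(c(i, j), c(i + r, j), c(i - r, j), c(i, j + r),
                  c(i, j - r), c(i + 0.71 * r, j + 0.71 * r),
                  c(i + 0.71 * r, j - 0.71 * r),
                  c(i - 0.71 * r, j + 0.71 * r),
                  c(i - 0.71 * r, j - 0.71 * r))
  probes <- round(probes)
  if (any(probes < 1 | probes > n)) return(FALSE)
  all(mask[probes])
}

vessel_walk <- function(lung, keep_clear, n, width_px, n_steps = 70L) {
  mask <- matrix(FALSE, n, n)
  inside <- which(lung & !keep_clear)
  if (length(inside) == 0L) return(mask)
  start <- arrayInd(sample(inside, 1L), c(n, n))
  pos <- as.numeric(start)
  ang <- stats::runif(1, 0, 2 * pi)
  r <- max(width_px / 2, 0.5)
  for (s in seq_len(n_steps)) {
    ang <- ang + stats::rnorm(1, 0, 0.3)
    pos <- pos + c(sin(ang), cos(ang))
    ii <- round(pos[1]); jj <- round(pos[2])
    if (ii < 1 || ii > n || jj < 1 || jj > n) break
    if (!lung[ii, jj] || keep_clear[ii, jj]) break
    ri <- max(1, ii - ceiling(r)):min(n, ii + ceiling(r))
    ci <- max(1, jj - ceiling(r)):min(n, jj + ceiling(r))
    for (a in ri) for (b in ci) {
      if ((a - pos[1])^2 + (b - pos[2])^2 <= r^2 && lung[a, b]) {
        mask[a, b] <- TRUE
      }
    }
  }
  mask
}
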