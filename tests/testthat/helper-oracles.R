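# Independent oracles and small fixture builders shared across the suite.

# Direct double-sum evaluation of the orthonormal 2D DCT definition:
# D(u,v) = rho(u) rho(v) sum_x sum_y d(x,y) cos((2x+1)u pi / 2M) cos((2y+1)v pi / 2N)
dct2_direct <- function(d) {
  M <- nrow(d); N <- ncol(d)
  rho <- function(k, n) if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  D <- matrix(0, M, N)
  for (u in 0:(M - 1)) {
    for (v in 0:(N - 1)) {
      s <- 0
      for (x in 0:(M - 1)) {
        for (y in 0:(N - 1)) {
          s <- s + d[x + 1, y + 1] *
            cos((2 * x + 1) * u * pi / (2 * M)) *
            cos((2 * y + 1) * v * pi / (2 * N))
        }
      }
      D[u + 1, v + 1] <- rho(u, M) * rho(v, N) * s
    }
  }
  D
}

# Per-pixel loop evaluation of the differential excitation definition with
# reflected borders: eps = arctan(alpha * sum_i (x_i - x_c) / max(x_c, 1)).
wld_excitation_direct <- function(patch, alpha = 3) {
  nr <- nrow(patch); nc <- ncol(patch)
  reflect <- function(i, n) if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          s <- s + patch[reflect(i + di, nr), reflect(j + dj, nc)] - patch[i, j]
        }
      }
      out[i, j] <- atan(alpha * s / max(patch[i, j], 1))
    }
  }
  out
}

# Exhaustive integer-threshold minimization of the same objective DE uses.
brute_force_thresholds <- function(hist, K) {
  obj <- function(tvec) {
    m <- tryCatch(fit_mixture_from_partition(hist, tvec),
                  error = function(e) NULL)
    if (is.null(m)) return(Inf)
    classification_error(m, tvec)
  }
  lv <- seq(min(hist$levels) + 1, max(hist$levels))
  if (K == 2) {
    errs <- vapply(lv, obj, numeric(1))
    list(thresholds = lv[which.min(errs)], error = min(errs))
  } else if (K == 3) {
    best <- NULL; best_err <- Inf
    for (a in lv) {
      for (b in lv[lv > a]) {
        e <- obj(c(a, b))
        if (e < best_err) { best_err <- e; best <- c(a, b) }
      }
    }
    list(thresholds = best, error = best_err)
  } else stop("oracle supports K = 2, 3")
}

# Synthetic 8-bit histogram from a mixture of discretized Gaussians.
synthetic_histogram <- function(means, sds, weights, n = 20000, seed = 1) {
  set.seed(seed)
  comp <- sample(seq_along(means), n, replace = TRUE, prob = weights)
  x <- round(rnorm(n, means[comp], sds[comp]))
  compute_histogram(pmin(pmax(x, 0), 255))
}

# Disc mask fixture (rasterized, pixel-centre rule).
disc_mask <- function(n, ctr_r, ctr_c, radius) {
  rc <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  (rc - ctr_r)^2 + (cc - ctr_c)^2 <= radius^2
}

# Small fast phantom used by unit tests (full-size phantoms are exercised
# in the acceptance suite).
test_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(image_size = 160L, n_nodules = 1L,
               nodule_diameter_range_mm = c(6, 10), seed = seed, ...)
}

# Strip gray_image attributes down to a plain matrix for comparisons.
as_mat <- function(img) {
  attributes(img) <- list(dim = dim(img))
  img
}
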