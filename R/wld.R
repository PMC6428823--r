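#' Weber Local Descriptor maps
#'
#' The WLD texture descriptor combines two per-pixel maps computed over
#' the 8-neighborhood (x1..x8 clockwise from North):
#'
#' * differential excitation
#'   `eps_m = arctan(alpha * sum_i (x_i - x_c) / x_c)` — the arctan
#'   compresses the relative intensity differences so large excursions
#'   (often noise) saturate instead of dominating; flat areas score ~0.
#'   A center value of 0 is replaced by 1 (uint8 domain) so the ratio
#'   stays bounded and monotone.
#' * gradient orientation
#'   `theta = atan2(x1 - x5, x3 - x7)` mapped to `[0, 2pi)` — the
#'   quadrant-corrected angle of the (North - South, East - West) cross
#'   differences; both-zero differences map to 0.
#'
#' Borders are handled by symmetric reflection, so the maps are congruent
#' with the input.
#'
#' @param patch numeric matrix, at least 3x3 (gray levels).
#' @param alpha positive excitation gain, default 3 (the typical WLD
#'   literature setting; larger alpha saturates earlier).
#' @param zero_floor value substituted for a zero center pixel, default 1.
#' @return numeric matrix congruent with `patch`; excitation in
#'   `(-pi/2, pi/2)`, orientation in `[0, 2pi)`.
#' @export
differential_excitation <- function(patch, alpha = 3, zero_floor = 1) {
  check_patch(patch)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("alpha must be > 0", call. = FALSE)
  }
  nb <- neighbor_stack(patch)
  xc <- pmax(patch, zero_floor)
  s <- Reduce(`+`, nb) - 8 * patch
  atan(alpha * s / xc)
}

#' @rdname differential_excitation
#' @export
gradient_orientation <- function(patch) {
  check_patch(patch)
  nb <- neighbor_stack(patch)
  dv <- nb[["N"]] - nb[["S"]]
  dh <- nb[["E"]] - nb[["W"]]
  theta <- atan2(dv, dh)
  theta <- ifelse(theta < 0, theta + 2 * pi, theta)
  theta[dv == 0 & dh == 0] <- 0
  theta
}

check_patch <- function(patch) {
  if (!is.matrix(patch) || !is.numeric(patch) ||
      nrow(patch) < 3L || ncol(patch) < 3L) {
    stop("patch must be a numeric matrix of at least 3x3", call. = FALSE)
  }
}

# Reflect-padded 8-neighborhood as named shifted matrices.
neighbor_stack <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  up <- c(2L, seq_len(nr - 1L))        # row index of the pixel above
  dn <- c(seq_len(nr)[-1L], nr - 1L)   # below (reflected at the border)
  lt <- c(2L, seq_len(nc - 1L))
  rt <- c(seq_len(nc)[-1L], nc - 1L)
  list(N  = patch[up, , drop = FALSE],
       NE = patch[up, rt, drop = FALSE],
       E  = patch[, rt, drop = FALSE],
       SE = patch[dn, rt, drop = FALSE],
       S  = patch[dn, , drop = FALSE],
       SW = patch[dn, lt, drop = FALSE],
       W  = patch[, lt, drop = FALSE],
       NW = patch[up, lt, drop = FALSE])
}

#' Per-block normalized histograms of a feature map
#'
#' The map is cut into a rectangular grid of `n_blocks` tiles (a near
#' square grid, e.g. 2x2 for 4) and each tile is histogrammed into
#' `n_bins` equal bins over `value_range`; every histogram is normalized
#' to sum to 1. Values outside the range are clamped into the end bins.
#'
#' @param map numeric matrix.
#' @param n_blocks number of tiles; must factor into a grid no wider than
#'   the map.
#' @param n_bins bins per histogram.
#' @param value_range length-2 numeric range spanned by the bins.
#' @return list of numeric vectors, one normalized histogram per block in
#'   row-major block order.
#' @export
block_histograms <- function(map, n_blocks, n_bins, value_range) {
  stopifnot(is.matrix(map), n_bins >= 1L)
  grid <- block_grid(n_blocks)
  if (grid[1] > nrow(map) || grid[2] > ncol(map)) {
    stop("n_blocks does not fit the map", call. = FALSE)
  }
  row_edges <- round(seq(0, nrow(map), length.out = grid[1] + 1L))
  col_edges <- round(seq(0, ncol(map), length.out = grid[2] + 1L))
  out <- vector("list", n_blocks)
  k <- 1L
  for (i in seq_len(grid[1])) {
    for (j in seq_len(grid[2])) {
      tile <- map[(row_edges[i] + 1L):row_edges[i + 1L],
                  (col_edges[j] + 1L):col_edges[j + 1L]]
      b <- floor((tile - value_range[1]) /
                   diff(value_range) * n_bins) + 1L
      b <- pmin(pmax(b, 1L), n_bins)
      h <- tabulate(b, nbins = n_bins)
      out[[k]] <- h / sum(h)
      k <- k + 1L
    }
  }
  out
}

block_grid <- function(n_blocks) {
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 1L) {
    stop("n_blocks must be >= 1", call. = FALSE)
  }
  r <- floor(sqrt(n_blocks))
  while (n_blocks %% r != 0L) r <- r - 1L
  if (r < 1L) stop("n_blocks is not a realizable grid", call. = FALSE)
  c(r, n_blocks %/% r)
}

#' Fused WLD feature vector of an image patch
#'
#' The feature-extraction stage: the patch (a candidate's bounding box plus
#' margin, resized to a fixed size) is mapped to its differential
#' excitation and gradient orientation images; each map is divided into
#' `n_blocks` tiles whose normalized histograms (`fs_bins` bins each, the
#' "FS-k" family) are concatenated, excitation histograms first, then
#' orientation histograms. Two identical patches always give identical
#' vectors; a constant patch concentrates all excitation mass in the bin
#' containing zero and is flagged degenerate.
#'
#' @param patch numeric matrix (gray levels), at least 3x3.
#' @param fs_bins bins per histogram per component (FS-k), default 14.
#' @param n_blocks tiles per map, default 4 (2x2 grid).
#' @param alpha excitation gain, default 3.
#' @return numeric vector of length `n_blocks * 2 * fs_bins` with
#'   attributes `layout = c(n_blocks, fs_bins, fs_bins)` and `degenerate`
#'   (TRUE for an all-constant patch).
#' @export
extract_features <- function(patch, fs_bins = 14L, n_blocks = 4L,
                             alpha = 3) {
  check_patch(patch)
  exc <- differential_excitation(patch, alpha = alpha)
  ori <- gradient_orientation(patch)
  eh <- block_histograms(exc, n_blocks, fs_bins, c(-pi / 2, pi / 2))
  oh <- block_histograms(ori, n_blocks, fs_bins, c(0, 2 * pi))
  v <- c(unlist(eh), unlist(oh))
  structure(v,
            layout = c(n_blocks = n_blocks, bins_excitation = fs_bins,
                       bins_orientation = fs_bins),
            degenerate = max(patch) == min(patch))
}

#' Extract and standardize a candidate patch from a slice
#'
#' Cuts the candidate's bounding box plus a 4-pixel margin out of the
#' (uint8-windowed, typically enhanced) slice and bilinearly resizes it to
#' `patch_size` x `patch_size`, so every candidate yields a feature vector
#' of identical layout regardless of its size.
#'
#' @param image uint8 `gray_image` (use the enhanced slice).
#' @param region one row of a `candidate_regions` data frame, or a list
#'   with `centroid_row`, `centroid_col`, `diameter_mm`.
#' @param pixels optional 2-column coordinate matrix of the region; when
#'   given, the bounding box comes from it, otherwise from the centroid
#'   and diameter.
#' @param margin_px margin around the bounding box, default 4.
#' @param patch_size output side length, default 32.
#' @return numeric `patch_size` x `patch_size` matrix.
#' @export
candidate_patch <- function(image, region, pixels = NULL, margin_px = 4L,
                            patch_size = 32L) {
  px <- as_plain_matrix(image)
  if (!is.null(pixels)) {
    r0 <- min(pixels[, 1]); r1 <- max(pixels[, 1])
    c0 <- min(pixels[, 2]); c1 <- max(pixels[, 2])
  } else {
    half <- max(1, region$diameter_mm / (2 * image_spacing(image)[1]))
    r0 <- floor(region$centroid_row - half); r1 <- ceiling(region$centroid_row + half)
    c0 <- floor(region$centroid_col - half); c1 <- ceiling(region$centroid_col + half)
  }
  r0 <- max(1L, r0 - margin_px); r1 <- min(nrow(px), r1 + margin_px)
  c0 <- max(1L, c0 - margin_px); c1 <- min(ncol(px), c1 + margin_px)
  resize_bilinear(px[r0:r1, c0:c1, drop = FALSE], patch_size, patch_size)
}

# Bilinear resampling of a matrix to out_r x out_c (pixel-centre aligned).
resize_bilinear <- function(m, out_r, out_c) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- if (out_r == 1L) rep(1, 1) else seq(1, nr, length.out = out_r)
  cc <- if (out_c == 1L) rep(1, 1) else seq(1, nc, length.out = out_c)
  r0 <- pmin(floor(rr), nr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cc), nc - 1L); c0 <- pmax(c0, 1L)
  fr <- rr - r0; fc <- cc - c0
  if (nr == 1L) { r0 <- rep(1L, out_r); fr <- rep(0, out_r) }
  if (nc == 1L) { c0 <- rep(1L, out_c); fc <- rep(0, out_c) }
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  FR <- matrix(fr, out_r, out_c)
  FC <- matrix(fc, out_r, out_c, byrow = TRUE)
  (1 - FR) * (1 - FC) * m[r0, c0, drop = FALSE] +
    (1 - FR) * FC * m[r0, c1, drop = FALSE] +
    FR * (1 - FC) * m[r1, c0, drop = FALSE] +
    FR * FC * m[r1, c1, drop = FALSE]
}
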