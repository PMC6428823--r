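#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a grid of tiles; each tile's gray-level
#' histogram is clipped at `clip_limit` (expressed as a fraction of the
#' tile's pixel count) with the excess mass redistributed uniformly, and a
#' per-tile mapping `J = (j_max - j_min) * P(f) + j_min` is built from the
#' clipped cumulative distribution `P(f)`. `j_min`/`j_max` are the global
#' display range of the input (its minimum and maximum gray level), so a
#' constant image maps to itself and output never leaves the input range.
#' Pixel values are remapped by bilinear interpolation between the four
#' surrounding tile mappings, which removes tile-boundary artifacts.
#'
#' Input must be in the uint8 domain (or `"real"`-domain values that are
#' binned to 256 levels over their own range, as used for the low-frequency
#' component of the frequency split).
#'
#' @param image `gray_image` in uint8 or real domain.
#' @param clip_limit positive fraction of tile pixels at which each
#'   histogram bin is clipped; default 0.01. Larger values enhance more.
#' @param tile_grid length-2 integer `(rows, cols)` of the tile grid,
#'   default `c(8, 8)`.
#' @param n_bins number of histogram bins, default 256.
#' @return `gray_image` in the same domain, values within the input's
#'   global `[j_min, j_max]` range.
#' @export
clahe <- function(image, clip_limit = 0.01, tile_grid = c(8L, 8L),
                  n_bins = 256L) {
  stopifnot(inherits(image, "gray_image"))
  if (image_domain(image) == "HU") {
    stop("clahe expects gray levels; window HU images first (window_to_uint8)",
         call. = FALSE)
  }
  if (!is.finite(clip_limit) || clip_limit <= 0) {
    stop("clip_limit must be > 0", call. = FALSE)
  }
  if (length(tile_grid) == 1L) tile_grid <- rep(tile_grid, 2L)
  tile_grid <- pmax(1L, as.integer(tile_grid))
  px <- as_plain_matrix(image)
  j_min <- min(px); j_max <- max(px)
  if (j_max == j_min) return(image)   # constant image: identity

  nr <- nrow(px); nc <- ncol(px)
  gr <- min(tile_grid[1], nr); gc <- min(tile_grid[2], nc)

  # bin index of every pixel (1..n_bins over the global range)
  bin <- pmin(floor((px - j_min) / (j_max - j_min) * n_bins) + 1L, n_bins)

  # tile boundaries and centres (in pixel coordinates)
  row_edges <- round(seq(0, nr, length.out = gr + 1L))
  col_edges <- round(seq(0, nc, length.out = gc + 1L))
  row_ctr <- (row_edges[-1] + row_edges[-(gr + 1L)] + 1) / 2
  col_ctr <- (col_edges[-1] + col_edges[-(gc + 1L)] + 1) / 2

  # per-tile clipped-CDF lookup tables: n_bins x (gr*gc)
  luts <- matrix(0, n_bins, gr * gc)
  for (i in seq_len(gr)) {
    rows <- (row_edges[i] + 1L):row_edges[i + 1L]
    for (j in seq_len(gc)) {
      cols <- (col_edges[j] + 1L):col_edges[j + 1L]
      h <- tabulate(bin[rows, cols], nbins = n_bins)
      luts[, (j - 1L) * gr + i] <- clipped_cdf(h, clip_limit)
    }
  }

  # bilinear blend of the four surrounding tile mappings per pixel
  ri <- findInterval(seq_len(nr), row_ctr)          # tile centre below
  ci <- findInterval(seq_len(nc), col_ctr)
  r0 <- pmax(ri, 1L); r1 <- pmin(ri + 1L, gr)
  c0 <- pmax(ci, 1L); c1 <- pmin(ci + 1L, gc)
  wr <- ifelse(r1 > r0,
               (seq_len(nr) - row_ctr[r0]) / (row_ctr[r1] - row_ctr[r0]), 0)
  wc <- ifelse(c1 > c0,
               (seq_len(nc) - col_ctr[c0]) / (col_ctr[c1] - col_ctr[c0]), 0)
  wr <- pmin(pmax(wr, 0), 1); wc <- pmin(pmax(wc, 0), 1)

  lut_at <- function(rtile, ctile) {
    idx <- (ctile[col(px)] - 1L) * gr + rtile[row(px)]
    matrix(luts[cbind(as.vector(bin), as.vector(idx))], nr, nc)
  }
  WR <- matrix(wr, nr, nc); WC <- matrix(wc, nr, nc, byrow = TRUE)
  P <- (1 - WR) * (1 - WC) * lut_at(r0, c0) +
       (1 - WR) * WC       * lut_at(r0, c1) +
       WR       * (1 - WC) * lut_at(r1, c0) +
       WR       * WC       * lut_at(r1, c1)

  out <- (j_max - j_min) * P + j_min
  if (image_domain(image) == "uint8") out <- round(out)
  same_geometry(image, out)
}

# Clip a tile histogram at clip_limit * n_pixels, redistribute the excess
# uniformly (one redistribution pass, then renormalize), return the CDF.
clipped_cdf <- function(h, clip_limit) {
  n <- sum(h)
  if (n == 0) return(seq_along(h) / length(h))
  clip <- max(clip_limit * n, 1)
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / length(h)
  cumsum(h) / sum(h)
}
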