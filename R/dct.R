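#' Two-dimensional discrete cosine transform (orthonormal, type II)
#'
#' `dct2()` computes the 2D DCT of a square block with orthonormal scaling,
#' so the top-left coefficient is the DC term `sqrt(1/M)*sqrt(1/N)*sum(x)`
#' (`M*c/ sqrt(M*N)` etc.), Parseval's identity holds exactly, and
#' `idct2()` is the exact inverse. Implemented as `C %*% X %*% t(C)` with
#' `C` the orthonormal cosine basis, which is both the fastest route at the
#' 8x8 block sizes used here and numerically identical to the double-sum
#' definition.
#'
#' @param block square numeric matrix of pixel values.
#' @return coefficient matrix of the same size; `[1,1]` is DC.
#' @examples
#' b <- matrix(5, 8, 8)
#' dct2(b)[1, 1] # == 8 * 5
#' @export
dct2 <- function(block) {
  C <- dct_basis(check_square_block(block))
  C %*% block %*% t(C)
}

#' @rdname dct2
#' @param coeffs square coefficient matrix as produced by [dct2()].
#' @export
idct2 <- function(coeffs) {
  C <- dct_basis(check_square_block(coeffs))
  t(C) %*% coeffs %*% C
}

check_square_block <- function(block) {
  if (!is.matrix(block) || !is.numeric(block)) {
    stop("block must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(block)
  if (n < 1L || ncol(block) != n) {
    stop("block must be square with side >= 1", call. = FALSE)
  }
  n
}

# Orthonormal DCT-II basis: C[u+1, x+1] = rho(u) cos((2x+1) u pi / (2N)).
# Cached per size; blocks are small so the cache stays tiny.
dct_basis <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    u <- 0:(n - 1)
    x <- 0:(n - 1)
    C <- sqrt(2 / n) * cos(outer(u, 2 * x + 1) * pi / (2 * n))
    C[1, ] <- sqrt(1 / n)
    cache[[key]] <- C
    C
  }
})

#' DCT power spectrum
#'
#' `P(u, v) = |D(u, v)|^2`. Because the transform is orthonormal, the total
#' spectral power equals the total squared pixel intensity (Parseval).
#'
#' @param coeffs DCT coefficient matrix.
#' @return nonnegative matrix of the same size.
#' @export
power_spectrum <- function(coeffs) {
  check_square_block(coeffs)
  coeffs^2
}

#' Zig-zag enumeration of block frequencies
#'
#' Enumerates all `block_size^2` coefficient positions from the upper-left
#' (DC) corner to the lower-right corner along antidiagonals with
#' alternating direction — the JPEG traversal in order of increasing
#' spatial frequency. Used to decide which leading coefficients count as
#' the low-frequency component.
#'
#' @param block_size positive integer side length.
#' @return integer matrix with columns `u`, `v` (0-based frequency indices),
#'   one row per position, in zig-zag order.
#' @examples
#' zigzag_order(2)
#' @export
zigzag_order <- function(block_size) {
  n <- as.integer(block_size)
  if (is.na(n) || n < 1L) stop("block_size must be >= 1", call. = FALSE)
  out <- matrix(0L, n * n, 2, dimnames = list(NULL, c("u", "v")))
  k <- 1L
  for (s in 0:(2L * n - 2L)) {        # antidiagonal index u + v = s
    idx <- max(0L, s - n + 1L):min(s, n - 1L)
    if (s %% 2L == 0L) idx <- rev(idx)    # even diagonals run upward
    for (u in idx) {
      out[k, ] <- c(u, s - u)
      k <- k + 1L
    }
  }
  out
}

#' Split an image into low- and high-frequency components
#'
#' Tiles the image with non-overlapping `block_size` x `block_size` blocks
#' (symmetric-reflection padding when the size is not a multiple, cropped
#' away after reconstruction), transforms each block with [dct2()], keeps
#' the first `lf_cutoff` zig-zag coefficients as the low-frequency part and
#' the remainder as high frequency, and inverse-transforms both back to
#' image space. By linearity `lf + hf` reconstructs the input to round-trip
#' tolerance.
#'
#' @param image a [gray_image()].
#' @param block_size block side, default 8.
#' @param lf_cutoff number of leading zig-zag coefficients classed as low
#'   frequency, in `[1, block_size^2]`; default 16 (DC + first 15 AC) keeps
#'   the coarse structure in LF while leaving texture and noise in HF.
#' @return list with `lf_image`, `hf_image` (both `gray_image` in the
#'   `"real"` domain), `block_size`, `lf_cutoff`.
#' @export
split_frequency <- function(image, block_size = 8L, lf_cutoff = 16L) {
  stopifnot(inherits(image, "gray_image"))
  block_size <- as.integer(block_size)
  lf_cutoff <- as.integer(lf_cutoff)
  if (block_size < 1L) stop("block_size must be >= 1", call. = FALSE)
  if (is.na(lf_cutoff) || lf_cutoff < 1L || lf_cutoff > block_size^2) {
    stop("lf_cutoff must lie in [1, block_size^2]", call. = FALSE)
  }
  px <- as_plain_matrix(image)
  padded <- pad_reflect(px, block_size)
  zz <- zigzag_order(block_size)
  lf_mask <- matrix(FALSE, block_size, block_size)
  lf_mask[zz[seq_len(lf_cutoff), , drop = FALSE] + 1L] <- TRUE

  lf <- matrix(0, nrow(padded), ncol(padded))
  hf <- lf
  for (i in seq_len(nrow(padded) / block_size)) {
    rows <- ((i - 1L) * block_size + 1L):(i * block_size)
    for (j in seq_len(ncol(padded) / block_size)) {
      cols <- ((j - 1L) * block_size + 1L):(j * block_size)
      D <- dct2(padded[rows, cols])
      lf[rows, cols] <- idct2(D * lf_mask)
      hf[rows, cols] <- idct2(D * !lf_mask)
    }
  }
  crop <- function(m) m[seq_len(nrow(px)), seq_len(ncol(px)), drop = FALSE]
  list(lf_image = same_geometry(image, crop(lf), value_domain = "real"),
       hf_image = same_geometry(image, crop(hf), value_domain = "real"),
       block_size = block_size, lf_cutoff = lf_cutoff)
}

# Reflect-pad a matrix so both dimensions are multiples of block_size.
pad_reflect <- function(px, block_size) {
  pad_r <- (block_size - nrow(px) %% block_size) %% block_size
  pad_c <- (block_size - ncol(px) %% block_size) %% block_size
  if (pad_r > 0) {
    src <- nrow(px) - seq_len(min(pad_r, nrow(px))) + 1L
    src <- rep_len(src, pad_r)
    px <- rbind(px, px[src, , drop = FALSE])
  }
  if (pad_c > 0) {
    src <- ncol(px) - seq_len(min(pad_c, ncol(px))) + 1L
    src <- rep_len(src, pad_c)
    px <- cbind(px, px[, src, drop = FALSE])
  }
  px
}
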