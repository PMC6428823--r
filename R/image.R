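#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix (rows x cols) carrying two attributes:
#' the value domain (`"HU"` for calibrated Hounsfield units, `"uint8"` for
#' 8-bit gray levels) and the in-plane pixel spacing in millimetres.
#' All nodulescan stages consume and produce this container.
#'
#' Coordinate convention used throughout the package: row-major matrices,
#' 1-based indices as usual in R, pixel centres; masks are logical matrices
#' congruent with their source image.
#'
#' @param pixels numeric matrix of intensities.
#' @param value_domain `"HU"`, `"uint8"`, or `"real"` (unconstrained
#'   intermediate values such as frequency-component reconstructions).
#' @param spacing_mm length-2 positive numeric `(row, col)` spacing in mm,
#'   or a single value used for both.
#' @return object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0, 4, 4), "uint8", 0.7)
#' image_domain(img)
#' @export
gray_image <- function(pixels, value_domain = c("HU", "uint8", "real"),
                       spacing_mm = c(1, 1)) {
  value_domain <- match.arg(value_domain)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be positive and finite", call. = FALSE)
  }
  if (value_domain == "uint8" &&
      (min(pixels) < 0 || max(pixels) > 255)) {
    stop("uint8 images must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels,
            value_domain = value_domain,
            spacing_mm = as.numeric(spacing_mm),
            class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @param x a `gray_image`.
#' @export
image_domain <- function(x) attr(x, "value_domain") %||% "uint8"

#' @rdname gray_image
#' @export
image_spacing <- function(x) attr(x, "spacing_mm") %||% c(1, 1)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, domain=%s, spacing=%.3fx%.3f mm, range=[%.4g, %.4g]>\n",
              nrow(x), ncol(x), image_domain(x),
              image_spacing(x)[1], image_spacing(x)[2],
              min(x), max(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild a gray_image around new pixel values, keeping metadata.
same_geometry <- function(template, pixels, value_domain = NULL) {
  gray_image(pixels,
             value_domain %||% image_domain(template),
             image_spacing(template))
}

as_plain_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Window an HU image to 8-bit gray levels
#'
#' Linearly maps the Hounsfield window to \[0, 255\], clipping outside. The
#' default window \[-1000, 400\] HU spans air through soft tissue, which is
#' where the lung anatomy of interest lives; histogram-equalization style
#' enhancement is defined on gray levels, so HU slices pass through here
#' before enhancement and feature extraction.
#'
#' @param image HU-domain `gray_image`.
#' @param window length-2 numeric, inclusive HU window, low < high.
#' @return uint8-domain `gray_image`.
#' @examples
#' img <- gray_image(matrix(c(-1000, -300, 400, 1000), 2, 2), "HU", 0.7)
#' window_to_uint8(img)
#' @export
window_to_uint8 <- function(image, window = c(-1000, 400)) {
  stopifnot(inherits(image, "gray_image"))
  if (image_domain(image) != "HU") {
    stop("window_to_uint8 expects an HU-domain image", call. = FALSE)
  }
  if (length(window) != 2L || !(window[1] < window[2])) {
    stop("window must be a length-2 increasing numeric", call. = FALSE)
  }
  v <- (as_plain_matrix(image) - window[1]) / (window[2] - window[1])
  v <- pmin(pmax(v, 0), 1)
  same_geometry(image, round(v * 255), value_domain = "uint8")
}
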