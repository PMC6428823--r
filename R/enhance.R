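#' Frequency-domain contrast enhancement
#'
#' The enhancement stage of the pipeline: the image is decomposed with
#' [split_frequency()] into a low-frequency (coarse structure) and a
#' high-frequency (texture and noise) component via block DCT and the
#' zig-zag coefficient split; [clahe()] is applied to the low-frequency
#' image only; the untouched high-frequency residual is added back and the
#' result is clipped to the value domain. Enhancing only the low-frequency
#' part raises contrast without amplifying the noise that lives in the
#' high-frequency component, and leaves edges and texture numerically
#' identical to the input's high-frequency content.
#'
#' HU-domain images are windowed to uint8 first (see [window_to_uint8()]);
#' the result stays in the uint8 domain for the downstream stages that
#' consume gray levels (feature extraction).
#'
#' @param image a [gray_image()]; HU images are windowed with `window`.
#' @param block_size DCT block side, default 8.
#' @param lf_cutoff leading zig-zag coefficients kept as low frequency,
#'   default 16 of 64.
#' @param clip_limit,tile_grid CLAHE parameters, see [clahe()].
#' @param window HU display window used when `image` is HU-domain.
#' @param details if `TRUE`, return a list with the enhanced image and the
#'   `lf_image`/`hf_image` components (useful for testing the contract that
#'   HF is unchanged).
#' @return enhanced uint8 `gray_image`, or a list when `details = TRUE`.
#' @export
enhance <- function(image, block_size = 8L, lf_cutoff = 16L,
                    clip_limit = 0.01, tile_grid = c(8L, 8L),
                    window = c(-1000, 400), details = FALSE) {
  stopifnot(inherits(image, "gray_image"))
  if (image_domain(image) == "HU") image <- window_to_uint8(image, window)
  dec <- split_frequency(image, block_size, lf_cutoff)
  lf_enh <- clahe(dec$lf_image, clip_limit = clip_limit,
                  tile_grid = tile_grid)
  out <- as_plain_matrix(lf_enh) + as_plain_matrix(dec$hf_image)
  out <- round(pmin(pmax(out, 0), 255))
  enhanced <- same_geometry(image, out, value_domain = "uint8")
  if (!details) return(enhanced)
  list(enhanced = enhanced, lf_image = dec$lf_image,
       hf_image = dec$hf_image, lf_enhanced = lf_enh)
}
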