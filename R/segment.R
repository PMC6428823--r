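#' Scanline background removal from the image border
#'
#' Emulates the classic corner-seeded background-removal operator: starting
#' at the four corners, every row is scanned inward from its left and right
#' ends and every column from its top and bottom ends, removing pixels
#' whose value lies in `bg_range` until a pixel outside the range stops the
#' run; additionally the middle column is traversed top to bottom and its
#' in-range pixels removed. The result marks foreground (everything not
#' reached by a background run).
#'
#' @param image a [gray_image()].
#' @param bg_range inclusive `(low, high)` intensity interval considered
#'   background. Default: `[-1024, -1000]` HU for HU images, `[min, min+24]`
#'   gray levels otherwise.
#' @return logical matrix, `TRUE` = foreground.
#' @export
remove_background <- function(image, bg_range = NULL) {
  stopifnot(inherits(image, "gray_image"))
  px <- as_plain_matrix(image)
  if (is.null(bg_range)) {
    bg_range <- if (image_domain(image) == "HU") c(-1024, -1000)
                else c(min(px), min(px) + 24)
  }
  inr <- px >= bg_range[1] & px <= bg_range[2]
  bg <- matrix(FALSE, nrow(px), ncol(px))

  run_len <- function(v) {            # length of the leading in-range run
    stop_at <- which(!v)
    if (length(stop_at) == 0L) length(v) else stop_at[1L] - 1L
  }
  for (i in seq_len(nrow(px))) {
    l <- run_len(inr[i, ]);          if (l > 0) bg[i, seq_len(l)] <- TRUE
    r <- run_len(rev(inr[i, ]));     if (r > 0) bg[i, ncol(px) - seq_len(r) + 1L] <- TRUE
  }
  for (j in seq_len(ncol(px))) {
    t <- run_len(inr[, j]);          if (t > 0) bg[seq_len(t), j] <- TRUE
    b <- run_len(rev(inr[, j]));     if (b > 0) bg[nrow(px) - seq_len(b) + 1L, j] <- TRUE
  }
  mid <- max(1L, ncol(px) %/% 2L)    # middle top-to-bottom traversal
  bg[inr[, mid], mid] <- TRUE
  !bg
}

#' Remove corner-connected components from a binary mask
#'
#' Flood fill seeded at the four image corners: any connected component of
#' the mask that touches a corner is removed. Applied to the below-threshold
#' (air) class of a thresholded thorax slice, this deletes the air outside
#' the body and isolates the lung fields.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8, default 8.
#' @return logical matrix with corner-touching components cleared.
#' @export
corner_seeded_region_growing <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  nr <- nrow(mask); nc <- ncol(mask)
  corner_labels <- unique(lab[cbind(c(1L, 1L, nr, nr), c(1L, nc, 1L, nc))])
  corner_labels <- corner_labels[corner_labels > 0L]
  if (length(corner_labels) == 0L) return(mask)
  mask & !(lab %in% corner_labels)
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected to the image border become
#' foreground. In the lung mask this recovers dense structures (nodules,
#' vessels) that the air threshold carved out of the lung interior, so they
#' are retained for candidate extraction. Idempotent.
#'
#' @param mask logical matrix.
#' @param connectivity connectivity of the background, default 4 (the dual
#'   of 8-connected foreground).
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask, connectivity = 4L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_components(!mask, connectivity)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  border <- border[border > 0L]
  mask | !(lab %in% c(0L, border))
}

#' Segment the lung fields of an HU slice
#'
#' Pipeline composition:
#' 1. [remove_background()] discards the scanner air reachable from the
#'    image border, leaving the body (chest wall + lungs).
#' 2. [iterative_initial_threshold()] starting at -950 HU finds a coarse
#'    air/tissue threshold on the body pixels.
#' 3. [de_optimal_thresholds()] (K = 2) refines it on the histogram of body
#'    pixels below soft tissue, minimizing the Gaussian misclassification
#'    error.
#' 4. Pixels below the refined threshold form the air class;
#'    [corner_seeded_region_growing()] removes the components connected to
#'    the image corners (residual outside air), leaving the lungs.
#' 5. [fill_holes()] restores dense interior structures to the mask.
#'
#' @param image HU-domain `gray_image`.
#' @param K number of classes for the DE refinement, default 2.
#' @param de_params list overriding [de_optimal_thresholds()] controls
#'   (`pop_size`, `F`, `CR`, `generations`).
#' @param min_area_px connected components smaller than this are dropped
#'   from the final mask (specks), default 64.
#' @param seed RNG seed for the DE stage.
#' @return logical lung mask; empty with a warning when no lung-like
#'   region is found.
#' @export
segment_lungs <- function(image, K = 2L, de_params = list(),
                          min_area_px = 64L, seed = 1L) {
  stopifnot(inherits(image, "gray_image"))
  if (image_domain(image) != "HU") {
    stop("segment_lungs expects an HU-domain slice", call. = FALSE)
  }
  px <- as_plain_matrix(image)
  body <- remove_background(image)
  empty <- matrix(FALSE, nrow(px), ncol(px))
  if (!any(body)) {
    warning("background removal left no body pixels; empty mask returned")
    return(empty)
  }

  t0 <- suppressWarnings(iterative_initial_threshold(image, mask = body))

  # DE refinement on the body interior below soft tissue: window the body
  # histogram around the coarse threshold so the two classes are lung air
  # vs. everything denser.
  v <- px[body]
  v_win <- v[v <= t0 + 400]
  thr <- t0
  if (length(unique(round(v_win))) >= K + 1L) {
    hist <- compute_histogram(v_win)
    de_args <- utils::modifyList(
      list(hist = hist, K = K, seed = seed), de_params)
    ts <- tryCatch(do.call(de_optimal_thresholds, de_args),
                   error = function(e) NULL)
    if (!is.null(ts)) thr <- ts$thresholds[1L]
  }

  air <- px < thr
  lungs <- corner_seeded_region_growing(air)
  lungs <- lungs & body
  if (any(lungs)) {
    lab <- label_components(lungs, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area_px)
    lungs <- matrix(lab %in% keep, nrow(px), ncol(px))
  }
  lungs <- fill_holes(lungs)
  if (!any(lungs)) {
    warning("no lung region found; empty mask returned")
    return(empty)
  }
  lungs
}
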