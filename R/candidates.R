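#' Candidate nodule regions
#'
#' Candidate extraction finds connected regions inside the lung mask that
#' are denser than the parenchyma (nodules and vessels), computes their
#' geometry (area-equivalent diameter in mm, second-moment elongation) and
#' prunes implausible ones by the 3-30 mm nodule diameter rule and a
#' vessel elongation rule.
#'
#' @name candidates
NULL

#' Multilevel threshold from the median slice of a stack
#'
#' For a stack of slices with lung masks, the dense-structure threshold is
#' computed once — on the median-index slice's lung-interior histogram with
#' [de_optimal_thresholds()] — and reused for every slice, which keeps the
#' candidate definition consistent across the stack.
#'
#' The DE search is windowed to +/- `window_hu` around the intermeans
#' fixed point of the lung-interior intensities and run with a minimum
#' class mass of 2\%; both guards exclude the degenerate far-tail minima
#' of the misclassification criterion (see [de_optimal_thresholds()]) so
#' the returned threshold separates parenchyma from the dense structures
#' (vessels, opacities, nodules) rather than splitting inside a tail.
#'
#' @param stack list of HU `gray_image` slices.
#' @param lung_masks list of logical lung masks congruent with the slices.
#' @param K classes for the threshold model: 2 gives a single
#'   parenchyma/dense threshold, 3 additionally separates subsolid from
#'   solid densities.
#' @param seed RNG seed for the DE search.
#' @param window_hu half-width of the search window around the intermeans
#'   fixed point, default 350 HU.
#' @param min_mass minimum class probability mass, default 0.02.
#' @return numeric vector of K - 1 thresholds (HU).
#' @export
median_slice_threshold <- function(stack, lung_masks, K = 2L, seed = 1L,
                                   window_hu = 350, min_mass = 0.02) {
  stopifnot(length(stack) == length(lung_masks), length(stack) >= 1L)
  nonempty <- vapply(lung_masks, any, logical(1))
  if (!any(nonempty)) stop("all lung masks are empty", call. = FALSE)
  idx_pool <- which(nonempty)
  med <- idx_pool[ceiling(length(idx_pool) / 2)]  # median of indices 0..n-1
  px <- as_plain_matrix(stack[[med]])
  v <- px[lung_masks[[med]]]
  t0 <- suppressWarnings(iterative_initial_threshold(v, t0_hu = stats::median(v)))
  v_win <- v[v >= t0 - window_hu & v <= t0 + window_hu]
  hist <- compute_histogram(v_win)
  if (length(hist$levels) < K + 1L) {
    stop("median-slice lung histogram too degenerate for K = ", K,
         call. = FALSE)
  }
  de_optimal_thresholds(hist, K = K, seed = seed,
                        min_mass = min_mass)$thresholds
}

#' Extract dense regions of interest inside the lung mask
#'
#' Connected components (8-connectivity) of the lung-interior pixels at or
#' above `threshold`, each returned with its geometry populated.
#'
#' @param slice HU `gray_image`.
#' @param lung_mask logical matrix.
#' @param threshold scalar intensity; for a K = 3 model pass the lower of
#'   the two thresholds.
#' @param source_slice slice index recorded on each region, default 1.
#' @return `data.frame` of class `candidate_regions`: one row per region
#'   with `slice`, `region_id`, `centroid_row`, `centroid_col`, `area_px`,
#'   `diameter_mm`, `elongation`, `label` (all `"candidate"`), plus the
#'   pixel sets in `attr(, "pixels")` (list of index matrices).
#' @export
extract_rois <- function(slice, lung_mask, threshold, source_slice = 1L) {
  stopifnot(inherits(slice, "gray_image"), is.logical(lung_mask))
  px <- as_plain_matrix(slice)
  dense <- lung_mask & px >= threshold[1L]
  lab <- label_components(dense, 8L)
  n <- attr(lab, "n_components")
  spacing <- image_spacing(slice)
  rows <- vector("list", n)
  out <- data.frame(slice = integer(0), region_id = integer(0),
                    centroid_row = numeric(0), centroid_col = numeric(0),
                    area_px = integer(0), diameter_mm = numeric(0),
                    elongation = numeric(0), label = character(0),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(structure(out, pixels = list(),
                                class = c("candidate_regions", "data.frame")))
  idx <- which(lab > 0L)
  coords <- arrayInd(idx, dim(lab))
  split_by <- lab[idx]
  pix_list <- split.data.frame(coords, split_by)
  recs <- lapply(seq_len(n), function(k) {
    pts <- pix_list[[as.character(k)]]
    data.frame(slice = as.integer(source_slice), region_id = k,
               centroid_row = mean(pts[, 1]), centroid_col = mean(pts[, 2]),
               area_px = nrow(pts),
               diameter_mm = equivalent_diameter(nrow(pts), spacing[1]),
               elongation = elongation_from_coords(pts),
               label = "candidate", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  structure(out, pixels = unname(pix_list[as.character(seq_len(n))]),
            class = c("candidate_regions", "data.frame"))
}

#' Area-equivalent diameter in millimetres
#'
#' Diameter of the disc with the same area as the region:
#' `2 * sqrt(area_px / pi) * spacing_mm`. In-plane spacing is assumed
#' isotropic (the row spacing is used).
#'
#' @param area_px positive pixel count.
#' @param spacing_mm in-plane pixel spacing (mm).
#' @return diameter in mm.
#' @examples
#' equivalent_diameter(100, 0.5) # ~5.64 mm
#' @export
equivalent_diameter <- function(area_px, spacing_mm = 1) {
  stopifnot(all(area_px > 0), spacing_mm > 0)
  2 * sqrt(area_px / pi) * spacing_mm
}

#' Second-moment elongation of a pixel region
#'
#' Ratio of the major to the minor axis of the inertia-equivalent ellipse,
#' computed from the eigenvalues of the pixel-coordinate covariance matrix.
#' Each axis variance is floored at 1/12 (the variance of a single pixel's
#' extent) so one-pixel-wide bars stay finite; a disc scores ~1, tubular
#' vessels score high.
#'
#' @param coords 2-column matrix of (row, col) pixel coordinates.
#' @return elongation >= 1.
#' @export
elongation_from_coords <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L, nrow(coords) >= 1L)
  if (nrow(coords) == 1L) return(1)
  cv <- stats::cov(coords) * (nrow(coords) - 1) / nrow(coords)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1 / 12)
  sqrt(ev[1] / ev[2])
}

#' Prune candidate regions by nodule plausibility rules
#'
#' Nodules are 3-30 mm across; smaller regions are noise, larger ones are
#' lesions or vessel conglomerates, and highly elongated regions are
#' vessels. Non-destructive: every input region is returned with exactly
#' one label — `pruned_small` (diameter < `d_min`), `pruned_large`
#' (> `d_max`), `pruned_vessel` (elongation > `elong_max`), or
#' `candidate` (survivor). Diameter rules are checked before the vessel
#' rule.
#'
#' @param regions `candidate_regions` from [extract_rois()].
#' @param d_min,d_max diameter bounds in mm, defaults 3 and 30.
#' @param elong_max maximum elongation for a nodule, default 3.
#' @return the input with updated `label` column.
#' @export
prune <- function(regions, d_min = 3, d_max = 30, elong_max = 3) {
  stopifnot(inherits(regions, "candidate_regions") ||
              is.data.frame(regions))
  lab <- rep("candidate", nrow(regions))
  lab[regions$elongation > elong_max] <- "pruned_vessel"
  lab[regions$diameter_mm > d_max] <- "pruned_large"
  lab[regions$diameter_mm < d_min] <- "pruned_small"
  regions$label <- lab
  regions
}
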