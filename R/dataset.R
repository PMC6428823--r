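#' Run the full pipeline over generated phantom slices
#'
#' Stands in for an annotated CT pool: generates `n_slices` independent
#' phantom slices, segments each lung field, computes the shared
#' median-slice candidate threshold, extracts and prunes candidates,
#' computes WLD feature vectors from the enhanced slices, and labels every
#' surviving candidate `nodule` / `non_nodule` by whether its centroid
#' falls inside a ground-truth nodule disc. Non-nodule candidates arise
#' from vessels and texture. The returned dataset is balanced by seeded
#' subsampling of the majority class.
#'
#' The first slice of every dataset carries one sub-3 mm speck so the
#' small-diameter pruning rule is always exercised; vessels exercise the
#' elongation rule.
#'
#' @param n_slices number of slices, default 20.
#' @param spec base [phantom_spec()]; its seed is rederived per slice.
#' @param seed master seed for slice generation, segmentation,
#'   thresholding and subsampling.
#' @param fs_bins,n_blocks,alpha WLD feature configuration.
#' @param d_min,d_max,elong_max pruning parameters, see [prune()].
#' @param balance subsample the majority class to balance, default TRUE.
#' @return list with `dataset` (a [labeled_dataset()]), `candidates`
#'   (data frame over all slices with labels and match status),
#'   `detection` (one row per implanted nodule with a `detected` flag),
#'   `thresholds`, `masks`, `slices`, `truths`.
#' @export
generate_dataset <- function(n_slices = 20L, spec = phantom_spec(),
                             seed = 17L, fs_bins = 14L, n_blocks = 4L,
                             alpha = 3, d_min = 3, d_max = 30,
                             elong_max = 3, balance = TRUE) {
  stopifnot(n_slices >= 1L)
  slices <- truths <- masks <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    s_i <- spec
    s_i$seed <- derive_seed(seed, i)
    if (i == 1L) s_i$n_specks <- max(s_i$n_specks, 1L)
    ph <- generate_slice(s_i)
    slices[[i]] <- ph$image
    truths[[i]] <- ph$truth
    masks[[i]] <- segment_lungs(ph$image, seed = derive_seed(seed, i))
  }
  thr <- median_slice_threshold(slices, masks, seed = derive_seed(seed, 0L))

  feats <- list(); labels <- character(0); ids <- character(0)
  cand_rows <- list()
  det_rows <- list()
  for (i in seq_len(n_slices)) {
    regions <- extract_rois(slices[[i]], masks[[i]], thr, source_slice = i)
    regions <- prune(regions, d_min = d_min, d_max = d_max,
                     elong_max = elong_max)
    pix <- attr(regions, "pixels")
    nodules <- truths[[i]]$nodule_records
    surv <- which(regions$label == "candidate")
    is_pos <- rep(FALSE, nrow(regions))
    if (nrow(nodules) > 0 && nrow(regions) > 0) {
      for (k in seq_len(nrow(regions))) {
        d <- sqrt((nodules$row - regions$centroid_row[k])^2 +
                    (nodules$col - regions$centroid_col[k])^2)
        is_pos[k] <- any(d <= nodules$radius_px)
      }
    }
    regions$class <- ifelse(is_pos, "nodule", "non_nodule")
    cand_rows[[i]] <- as.data.frame(regions)

    if (length(surv) > 0) {
      enhanced <- enhance(slices[[i]])
      for (k in surv) {
        patch <- candidate_patch(enhanced, regions[k, ],
                                 pixels = pix[[k]])
        feats[[length(feats) + 1L]] <-
          extract_features(patch, fs_bins = fs_bins, n_blocks = n_blocks,
                           alpha = alpha)
        labels <- c(labels, regions$class[k])
        ids <- c(ids, sprintf("s%03d_r%03d", i, k))
      }
    }
    if (nrow(nodules) > 0) {
      detected <- vapply(seq_len(nrow(nodules)), function(m) {
        if (length(surv) == 0) return(FALSE)
        d <- sqrt((regions$centroid_row[surv] - nodules$row[m])^2 +
                    (regions$centroid_col[surv] - nodules$col[m])^2)
        any(d <= nodules$radius_px[m])
      }, logical(1))
      det_rows[[i]] <- data.frame(slice = i,
                                  diameter_mm = nodules$diameter_mm,
                                  mean_hu = nodules$mean_hu,
                                  detected = detected)
    }
  }
  if (length(feats) == 0L) {
    stop("pipeline produced zero surviving candidates", call. = FALSE)
  }
  X <- do.call(rbind, feats)
  data <- labeled_dataset(X, labels, ids)
  if (balance) data <- balance_dataset(data, seed = derive_seed(seed, -1L))

  list(dataset = data,
       candidates = do.call(rbind, cand_rows),
       detection = do.call(rbind, det_rows),
       thresholds = thr, masks = masks, slices = slices, truths = truths)
}

#' @rdname generate_dataset
#' @param data a [labeled_dataset()] to balance by subsampling the
#'   majority class.
#' @export
balance_dataset <- function(data, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  tab <- table(data$labels)
  if (length(tab) < 2L) return(data)
  n_min <- min(tab)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(data$labels == cl)
    if (length(idx) > n_min) sample(idx, n_min) else idx
  }))
  subset_dataset(data, sort(keep))
}

# Small deterministic seed derivation that stays inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + (i + 2) * 9973) %% 2147483647)
}
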