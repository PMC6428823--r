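#' Pipeline configuration
#'
#' A single nested configuration object carrying every stage's parameters
#' with their defaults, serializable to JSON and back without loss.
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param ... named overrides; either top-level sections
#'   (`enhancement = list(lf_cutoff = 12)`) or the scalars `seed`,
#'   `spacing_mm`, `verbose`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 17L,
    spacing_mm = 0.7,
    verbose = FALSE,
    enhancement = list(block_size = 8L, lf_cutoff = 16L,
                       clip_limit = 0.01, tile_grid = c(8L, 8L),
                       window = c(-1000, 400)),
    segmentation = list(K = 2L, pop_size = 20L, F = 0.5, CR = 0.9,
                        generations = 100L, min_area_px = 64L),
    candidates = list(K = 2L, d_min = 3, d_max = 30, elong_max = 3),
    features = list(fs_bins = 14L, n_blocks = 4L, alpha = 3,
                    patch_size = 32L, margin_px = 4L),
    classifier = list(kernel = "rbf", C = 1, gamma = NA,  # NA = scale heuristic
                      train_fraction = 0.7)
  )
  out <- merge_config(defaults, list(...))
  class(out) <- "pipeline_config"
  out
}

merge_config <- function(base, over, path = "") {
  if (length(over) == 0) return(base)
  nm <- names(over)
  if (is.null(nm) || any(nm == "")) stop("config overrides must be named",
                                         call. = FALSE)
  for (key in nm) {
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", paste0(path, key), call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(over[[key]])) {
      base[[key]] <- merge_config(base[[key]], over[[key]],
                                  paste0(path, key, "."))
    } else if (is.null(over[[key]])) {
      base[[key]] <- NA          # JSON null round-trips as NA
    } else {
      base[[key]] <- over[[key]]
    }
  }
  base
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- rapply(raw, function(x) x, how = "replace")
  do.call(pipeline_config, coerce_config_types(raw))
}

# JSON round-trips integers as doubles; restore the documented types.
coerce_config_types <- function(x) {
  ints <- c("seed", "block_size", "lf_cutoff", "tile_grid", "K",
            "pop_size", "generations", "min_area_px", "fs_bins",
            "n_blocks", "patch_size", "margin_px")
  walk <- function(node, name = "") {
    if (is.list(node)) {
      nm <- names(node)
      out <- lapply(seq_along(node), function(k) {
        walk(node[[k]], if (is.null(nm)) "" else nm[k])
      })
      names(out) <- nm
      out
    } else if (name %in% ints && !is.null(node) && !anyNA(node)) {
      as.integer(node)
    } else node
  }
  walk(x)
}

#' Run the detection pipeline end to end
#'
#' Executes enhance -> segment -> detect (extract + prune) -> features ->
#' predict on a list of slices, logging per-stage parameter and count
#' information, and returns the per-stage outputs plus a run report.
#' Deterministic for a fixed configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param slices list of HU `gray_image` slices (e.g. phantom slices or
#'   images loaded with [read_image()]).
#' @param model optional trained [train_svm()] model; when present the
#'   surviving candidates are classified and predictions reported.
#' @return list with `masks`, `thresholds`, `candidates` (pruned-labelled
#'   data frame), `features` (matrix over survivors), `predictions`
#'   (or NULL), and `report` (named counts per stage).
#' @export
run_pipeline <- function(config, slices, model = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(slices, "gray_image")) slices <- list(slices)
  n <- length(slices)
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  stage <- "enhancement"
  result <- tryCatch({
    enhanced <- lapply(slices, function(s) {
      do.call(enhance, c(list(image = s), config$enhancement))
    })
    log_msg("enhanced %d slices (block=%d, lf_cutoff=%d)", n,
            config$enhancement$block_size, config$enhancement$lf_cutoff)

    stage <- "segmentation"
    seg <- config$segmentation
    masks <- lapply(slices, function(s) {
      segment_lungs(s, K = seg$K,
                    de_params = seg[c("pop_size", "F", "CR", "generations")],
                    min_area_px = seg$min_area_px, seed = config$seed)
    })
    log_msg("segmented %d slices", n)

    stage <- "candidate detection"
    thr <- median_slice_threshold(slices, masks, K = config$candidates$K,
                                  seed = config$seed)
    cands <- list(); pix_all <- list()
    for (i in seq_len(n)) {
      r <- extract_rois(slices[[i]], masks[[i]], thr, source_slice = i)
      r <- prune(r, d_min = config$candidates$d_min,
                 d_max = config$candidates$d_max,
                 elong_max = config$candidates$elong_max)
      pix_all[[i]] <- attr(r, "pixels")
      cands[[i]] <- as.data.frame(r)
    }
    candidates <- do.call(rbind, cands)
    survivors <- which(candidates$label == "candidate")
    log_msg("detected %d regions, %d survive pruning",
            nrow(candidates), length(survivors))

    stage <- "feature extraction"
    fcfg <- config$features
    feats <- NULL
    if (length(survivors) > 0) {
      rows <- lapply(survivors, function(k) {
        i <- candidates$slice[k]
        local_id <- candidates$region_id[k]
        patch <- candidate_patch(enhanced[[i]], candidates[k, ],
                                 pixels = pix_all[[i]][[local_id]],
                                 margin_px = fcfg$margin_px,
                                 patch_size = fcfg$patch_size)
        extract_features(patch, fs_bins = fcfg$fs_bins,
                         n_blocks = fcfg$n_blocks, alpha = fcfg$alpha)
      })
      feats <- do.call(rbind, rows)
    }

    stage <- "prediction"
    predictions <- NULL
    if (!is.null(model) && !is.null(feats)) {
      predictions <- predict(model, feats)
      candidates$predicted <- NA_character_
      candidates$predicted[survivors] <- predictions$labels
    }

    list(masks = masks, thresholds = thr, candidates = candidates,
         features = feats, predictions = predictions,
         report = list(
           n_slices = n,
           n_regions = nrow(candidates),
           n_candidates = length(survivors),
           n_pruned_small = sum(candidates$label == "pruned_small"),
           n_pruned_large = sum(candidates$label == "pruned_large"),
           n_pruned_vessel = sum(candidates$label == "pruned_vessel"),
           n_predicted_nodule = if (is.null(predictions)) NA_integer_
                                else sum(predictions$labels == "nodule"),
           thresholds = thr,
           seed = config$seed))
  }, error = function(e) {
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}
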