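#' End-to-end phantom detection experiment
#'
#' Runs the full pipeline over `n_datasets` independently seeded phantom
#' datasets of `n_slices` slices each (defaults: 25 datasets of 20 slices,
#' 2 implanted 5-20 mm nodules per slice) and pools the results. Reports
#' candidate-level detection sensitivity (fraction of implanted nodules
#' recovered by a surviving candidate whose centroid lies inside the
#' truth disc, pooled over all nodules) and the pooled balanced candidate
#' dataset for classifier experiments.
#'
#' This is the desk-scale stand-in for a full annotated CT cohort
#' evaluation: it validates the pipeline's plumbing and discriminative
#' power on the stated synthetic world, not clinical performance.
#'
#' @param n_datasets number of independently seeded datasets, default 25.
#' @param n_slices slices per dataset, default 20.
#' @param spec base [phantom_spec()] (seed rederived per dataset).
#' @param seed master seed.
#' @param progress print one line per dataset, default FALSE.
#' @return list with `detection_sensitivity`, `detection` (per-nodule data
#'   frame), `pooled` (balanced [labeled_dataset()] over all datasets) and
#'   `per_dataset` (data frame of per-dataset counts).
#' @export
phantom_experiment <- function(n_datasets = 25L, n_slices = 20L,
                               spec = phantom_spec(), seed = 17L,
                               progress = FALSE) {
  det <- list(); pools <- list(); summaries <- list()
  for (d in seq_len(n_datasets)) {
    ds <- generate_dataset(n_slices = n_slices, spec = spec,
                           seed = derive_seed(seed, 131 * d))
    det[[d]] <- cbind(dataset = d, ds$detection)
    pools[[d]] <- ds$dataset
    summaries[[d]] <- data.frame(
      dataset = d,
      n_candidates = length(ds$dataset$labels),
      n_nodules = nrow(ds$detection),
      n_detected = sum(ds$detection$detected))
    if (progress) {
      message(sprintf("dataset %d/%d: %d/%d nodules detected, %d samples",
                      d, n_datasets, summaries[[d]]$n_detected,
                      summaries[[d]]$n_nodules, summaries[[d]]$n_candidates))
    }
  }
  detection <- do.call(rbind, det)
  pooled <- labeled_dataset(
    do.call(rbind, lapply(pools, function(p) p$features)),
    unlist(lapply(pools, function(p) p$labels)))
  pooled <- balance_dataset(pooled, seed = derive_seed(seed, -7L))
  list(detection_sensitivity = mean(detection$detected),
       detection = detection,
       pooled = pooled,
       per_dataset = do.call(rbind, summaries))
}

#' Subsample a balanced dataset to an exact per-class size
#'
#' Seeded subsampling without replacement to `n_per_class` samples of each
#' class (used to assemble the 786 + 786 protocol dataset).
#'
#' @param data a [labeled_dataset()].
#' @param n_per_class target size per class.
#' @param seed RNG seed.
#' @return a [labeled_dataset()] with `2 * n_per_class` samples.
#' @export
subsample_per_class <- function(data, n_per_class, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  tab <- table(data$labels)
  if (any(tab < n_per_class)) {
    stop("not enough samples per class: have ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(names(tab), function(cl) {
    sample(which(data$labels == cl), n_per_class)
  }))
  subset_dataset(data, sort(keep))
}
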