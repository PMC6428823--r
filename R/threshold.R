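#' Normalized gray-level histogram
#'
#' Frequency of each gray level present in the image, normalized to sum to
#' one. Real-valued (HU) images are rounded to integer levels first; the
#' thresholding model treats the histogram as a discrete probability
#' distribution p(x).
#'
#' @param image a [gray_image()] or numeric vector/matrix of intensities.
#' @return list of class `gray_histogram` with `levels` (strictly
#'   increasing numeric) and `probs` (nonnegative, summing to 1).
#' @export
compute_histogram <- function(image) {
  v <- if (inherits(image, "gray_image")) as.vector(as_plain_matrix(image))
       else as.vector(image)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty image", call. = FALSE)
  tab <- table(round(v))
  levels <- as.numeric(names(tab))
  o <- order(levels)
  structure(list(levels = levels[o],
                 probs = as.numeric(tab)[o] / length(v)),
            class = "gray_histogram")
}

#' Gaussian mixture fitted to a threshold partition
#'
#' Given thresholds `T_1 < ... < T_{K-1}`, the histogram is cut into K
#' classes (`class i` holds levels `x` with `T_{i-1} <= x < T_i`, with
#' `T_0 = -Inf`, `T_K = +Inf`). Each class contributes a Gaussian
#' component: weight `P_i` = class probability mass, mean and standard
#' deviation = the class's moments under the histogram, with the standard
#' deviation floored at `sigma_floor` so degenerate single-level classes
#' remain well defined.
#'
#' @param hist a `gray_histogram` from [compute_histogram()].
#' @param thresholds strictly increasing numeric vector inside the
#'   histogram range.
#' @param sigma_floor positive floor for component standard deviations.
#' @return list of class `gaussian_mixture` with `K`, `weights`, `means`,
#'   `sds`.
#' @export
fit_mixture_from_partition <- function(hist, thresholds,
                                       sigma_floor = 1e-3) {
  stopifnot(inherits(hist, "gray_histogram"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  cls <- findInterval(hist$levels, thresholds) + 1L   # x < T_1 -> class 1
  K <- length(thresholds) + 1L
  weights <- means <- sds <- numeric(K)
  for (i in seq_len(K)) {
    sel <- cls == i
    if (!any(sel)) {
      stop("degenerate partition: interval ", i, " holds no histogram mass",
           call. = FALSE)
    }
    p <- hist$probs[sel]
    x <- hist$levels[sel]
    weights[i] <- sum(p)
    means[i] <- sum(p * x) / weights[i]
    sds[i] <- max(sqrt(sum(p * (x - means[i])^2) / weights[i]), sigma_floor)
  }
  structure(list(K = K, weights = weights, means = means, sds = sds),
            class = "gaussian_mixture")
}

#' Total Gaussian misclassification error of a threshold vector
#'
#' For each threshold `T_i` between adjacent classes i and i+1, the error
#' contribution is the probability mass each class places on the wrong side
#' of the threshold:
#' `e(T_i) = P_i * Pr[X_i > T_i] + P_{i+1} * Pr[X_{i+1} < T_i]`,
#' with Gaussian tails evaluated through the error function (`pnorm`). The
#' total `E(T)` is the sum over all K-1 thresholds; well-separated classes
#' drive it to zero, identical adjacent classes give `(P_i + P_{i+1}) / 2`.
#' Optimal thresholding minimizes this quantity.
#'
#' @param model a `gaussian_mixture` from [fit_mixture_from_partition()].
#' @param thresholds strictly increasing vector of length `K - 1`.
#' @return nonnegative scalar error.
#' @export
classification_error <- function(model, thresholds) {
  stopifnot(inherits(model, "gaussian_mixture"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != model$K - 1L) {
    stop("need K - 1 thresholds", call. = FALSE)
  }
  if (length(thresholds) > 1L && is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  i <- seq_len(model$K - 1L)
  wrong_hi <- model$weights[i] *
    stats::pnorm(thresholds, model$means[i], model$sds[i],
                 lower.tail = FALSE)
  wrong_lo <- model$weights[i + 1L] *
    stats::pnorm(thresholds, model$means[i + 1L], model$sds[i + 1L])
  sum(wrong_hi + wrong_lo)
}

# Objective for threshold search: fit the partition mixture, score it.
# Degenerate partitions (an empty class, or one below the optional mass
# floor) are infeasible -> +Inf. The mass floor guards against the
# known degeneracy of the misclassification criterion: a threshold pushed
# into a far tail isolates a near-empty, near-zero-variance class whose
# wrong-side mass is ~0, which minimizes E(T) without being a meaningful
# segmentation.
threshold_objective <- function(hist, thresholds, min_mass = 0) {
  model <- tryCatch(fit_mixture_from_partition(hist, thresholds),
                    error = function(e) NULL)
  if (is.null(model)) return(Inf)
  if (min_mass > 0 && any(model$weights < min_mass)) return(Inf)
  classification_error(model, thresholds)
}

#' Optimal multilevel thresholds by differential evolution
#'
#' Searches for the K-1 thresholds minimizing [classification_error()] of
#' the partition-fit Gaussian mixture, using the classic DE/rand/1/bin
#' differential evolution strategy: for each population member, a mutant is
#' formed from three distinct others as `a + F * (b - c)`, crossed over
#' coordinate-wise with probability `CR`, repaired by sorting and clamping
#' to the histogram range, and kept if it scores no worse. The search is
#' deterministic for a fixed `seed`.
#'
#' @param hist a `gray_histogram`.
#' @param K number of classes (>= 2); K - 1 thresholds are returned.
#' @param pop_size population size, default 20.
#' @param F differential weight, default 0.5.
#' @param CR crossover probability, default 0.9.
#' @param generations number of generations, default 100.
#' @param seed integer RNG seed.
#' @param min_mass optional minimum probability mass per class (default 0,
#'   i.e. off): partitions leaving any class below the floor are
#'   infeasible. Pipeline stages use a small positive floor to exclude the
#'   degenerate far-tail minima of the misclassification criterion.
#' @return list of class `threshold_set` with `thresholds` (increasing
#'   numeric of length K - 1) and `error` (the minimized total error).
#' @export
de_optimal_thresholds <- function(hist, K = 2L, pop_size = 20L, F = 0.5,
                                  CR = 0.9, generations = 100L, seed = 1L,
                                  min_mass = 0) {
  stopifnot(inherits(hist, "gray_histogram"))
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (length(hist$levels) < K) {
    stop("histogram has fewer than K distinct levels: infeasible",
         call. = FALSE)
  }
  d <- K - 1L
  lo <- min(hist$levels); hi <- max(hist$levels)

  repair <- function(v) sort(pmin(pmax(v, lo), hi))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  pop <- t(replicate(pop_size, repair(stats::runif(d, lo, hi))))
  pop <- matrix(pop, nrow = pop_size, ncol = d)
  fit <- apply(pop, 1L, function(v) threshold_objective(hist, v, min_mass))

  for (g in seq_len(generations)) {
    for (i in seq_len(pop_size)) {
      abc <- sample(setdiff(seq_len(pop_size), i), 3L)
      mutant <- pop[abc[1L], ] + F * (pop[abc[2L], ] - pop[abc[3L], ])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE   # at least one mutant coordinate
      trial <- repair(ifelse(cross, mutant, pop[i, ]))
      f_trial <- threshold_objective(hist, trial, min_mass)
      if (f_trial <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
      }
    }
  }
  best <- which.min(fit)
  structure(list(thresholds = pop[best, ], error = fit[best]),
            class = "threshold_set")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Iterative intermeans threshold from an HU starting point
#'
#' Starting from `t0_hu` (default -950 HU, below which almost only air and
#' lung parenchyma lie), each iteration replaces the threshold with the
#' mean of the two class means: `T <- (mean(x <= T) + mean(x > T)) / 2`,
#' until the update falls below 0.5 HU or 100 iterations elapse. On typical
#' thorax slices the fixed point lands between the lung band and the soft
#' tissue of the chest wall.
#'
#' @param image HU-domain `gray_image` (or numeric values).
#' @param t0_hu starting threshold, default -950.
#' @param mask optional logical matrix restricting the pixels considered.
#' @return converged threshold (HU). If every pixel lies on one side of
#'   `t0_hu`, `t0_hu` is returned with a warning.
#' @export
iterative_initial_threshold <- function(image, t0_hu = -950, mask = NULL) {
  if (inherits(image, "gray_image") && image_domain(image) != "HU") {
    stop("iterative_initial_threshold expects an HU-domain image",
         call. = FALSE)
  }
  v <- if (inherits(image, "gray_image")) as.vector(as_plain_matrix(image))
       else as.vector(image)
  if (!is.null(mask)) v <- v[as.vector(mask)]
  v <- v[is.finite(v)]
  t <- t0_hu
  if (all(v <= t) || all(v > t)) {
    warning("all pixels lie on one side of the initial threshold")
    return(t0_hu)
  }
  for (k in seq_len(100L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 0.5) return(t_new)
    t <- t_new
  }
  t
}
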