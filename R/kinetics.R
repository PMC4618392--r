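# Temporal analysis: peaks x time-points occupancy matrix, row Z-scores,
# k-means partition into fast and slow kinetic classes labeled by mean
# time of maximal signal.

#' Build the peaks-by-time-points occupancy matrix
#'
#' Entry (i, j) is the sum of cleavage signal in the `width`-bp window
#' centered on peak i's midpoint in the track for time point j.
#'
#' @param tracks Named list of `signal_track` objects; names are the time
#'   points in seconds (coercible to numeric), in any order.
#' @param peaks Peak tibble with `chrom` and `midpoint`.
#' @param width Window width in bp (default 50).
#' @return A `time_course_matrix`: tibble with `peak_id`, `chrom`,
#'   `midpoint` and one `t_<seconds>` column per time point (increasing
#'   time order); attributes `times` (numeric) and `zscored` (FALSE).
#' @export
build_time_matrix <- function(tracks, peaks, width = 50) {
  if (length(tracks) < 2L) abort("need at least two time points")
  times <- suppressWarnings(as.numeric(names(tracks)))
  if (anyNA(times)) abort("track names must be numeric time points (seconds)")
  ord <- order(times)
  tracks <- tracks[ord]
  times <- times[ord]
  out <- tibble(peak_id = peaks$peak_id, chrom = peaks$chrom,
                midpoint = interval_midpoints(peaks))
  for (j in seq_along(tracks)) {
    out[[paste0("t_", format(times[j], trim = TRUE, scientific = FALSE))]] <-
      window_sum(tracks[[j]], peaks, width)
  }
  attr(out, "times") <- times
  attr(out, "zscored") <- FALSE
  class(out) <- c("time_course_matrix", class(out))
  out
}

tcm_values <- function(tcm) {
  as.matrix(tcm[, grep("^t_", names(tcm)), drop = FALSE])
}

tcm_times <- function(tcm) attr(tcm, "times")

#' Z-score the rows of a time-course matrix
#'
#' Each row is centered and scaled by its population (divide-by-n) standard
#' deviation so signal is comparable across time points within a site.
#' Constant rows map to all zeros and are flagged in a `degenerate` column.
#'
#' @param tcm A `time_course_matrix` (>= 2 time-point columns).
#' @return The matrix with Z-scored time columns, `zscored` attribute TRUE
#'   and a logical `degenerate` column marking constant rows.
#' @export
zscore_rows <- function(tcm) {
  x <- tcm_values(tcm)
  if (ncol(x) < 2L) abort("need at least two time-point columns")
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))    # population sd
  degenerate <- sdp == 0
  z <- (x - mu) / ifelse(degenerate, 1, sdp)
  z[degenerate, ] <- 0
  tcm[, grep("^t_", names(tcm))] <- as.data.frame(z)
  tcm$degenerate <- degenerate
  attr(tcm, "zscored") <- TRUE
  tcm
}

#' Time point of maximal signal per peak
#'
#' Ties are resolved to the earliest time point, conservatively favoring the
#' fast class.
#'
#' @param tcm A `time_course_matrix`.
#' @return Numeric vector: per peak, the time (seconds) at which its row
#'   maximum is first attained.
#' @export
argmax_time <- function(tcm) {
  x <- tcm_values(tcm)
  if (nrow(x) == 0L) abort("empty time-course matrix")
  tcm_times(tcm)[apply(x, 1L, which.max)]   # which.max takes the first tie
}

#' Partition peaks into fast and slow kinetic classes
#'
#' Runs k-means (Euclidean, `nstart` restarts, fixed seed) on the Z-scored
#' time-course rows. With `k = 2`, the class whose members reach maximal
#' signal earlier on average is labeled `"fast"`, the other `"slow"`.
#' Degenerate (constant) rows are assigned to the slow class: they show no
#' detectable early maximum.
#'
#' @param tcm A Z-scored `time_course_matrix`.
#' @param k Number of classes (default 2).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @return A `chec_kinetics` object: list with `classes` (tibble: `peak_id`,
#'   `cluster`, `class`, `argmax_time`), `centers`, `class_argmax` (mean
#'   argmax time per class), `k`, `seed`.
#' @export
cluster_kinetics <- function(tcm, k = 2, seed = 1L, nstart = 10L) {
  if (!isTRUE(attr(tcm, "zscored"))) {
    abort("time-course matrix must be Z-scored first (zscore_rows)")
  }
  x <- tcm_values(tcm)
  if (nrow(x) < k) abort("fewer rows than clusters")
  amax <- argmax_time(tcm)
  degenerate <- if ("degenerate" %in% names(tcm)) tcm$degenerate else
    rep(FALSE, nrow(x))
  if (k == 1L) {
    warn("k = 1: single class labeled fast")
    cl <- rep(1L, nrow(x))
    centers <- matrix(colMeans(x), nrow = 1)
  } else {
    fit <- withr_seed(seed, kmeans(x, centers = k, nstart = nstart,
                                   iter.max = 100L))
    cl <- fit$cluster
    centers <- fit$centers
  }
  # label clusters by mean time of row maximum (earliest = fast)
  mean_amax <- vapply(seq_len(max(cl)), function(g) mean(amax[cl == g]), 0)
  ord <- order(mean_amax)
  labels <- rep("slow", max(cl))
  labels[ord[1]] <- "fast"
  if (max(cl) > 2L) labels[ord[-1]] <- paste0("slow", seq_len(max(cl) - 1L))
  class_lab <- labels[cl]
  class_lab[degenerate] <- "slow"
  res <- structure(list(
    classes = tibble(peak_id = tcm$peak_id, cluster = cl,
                     class = class_lab, argmax_time = amax),
    centers = centers,
    class_argmax = tibble(class = labels[seq_len(max(cl))],
                          mean_argmax = mean_amax),
    k = k, seed = seed),
    class = "chec_kinetics")
  if (k == 2L && !all(degenerate)) {
    fast_m <- mean(amax[class_lab == "fast"])
    slow_m <- mean(amax[class_lab == "slow"])
    stopifnot(fast_m <= slow_m)
  }
  res
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' @export
print.chec_kinetics <- function(x, ...) {
  cat("<chec_kinetics> k =", x$k, "\n")
  print(dplyr::count(x$classes, .data$class))
  invisible(x)
}

#' @describeIn cluster_kinetics Per-peak class assignments as a tibble.
#' @param x A `chec_kinetics` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.chec_kinetics <- function(x, ...) x$classes

#' @describeIn cluster_kinetics One row per class with size and mean time of
#'   maximal signal.
#' @exportS3Method generics::glance
glance.chec_kinetics <- function(x, ...) {
  x$classes %>%
    group_by(class = .data$class) %>%
    summarise(n = dplyr::n(), mean_argmax = mean(.data$argmax_time),
              .groups = "drop")
}
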