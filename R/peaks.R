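# Peak calling on the maximum-over-time composite track by genome-wide
# thresholding: positions with value >= fold * genome-wide mean (zeros
# included) qualify; qualifying positions within the merge distance are
# joined into one peak.

#' Per-position maximum across time-point tracks
#'
#' @param tracks List of `signal_track` objects on the same genome
#'   (typically depth-normalized, one per digestion time point).
#' @return A `signal_track` holding the positionwise maximum.
#' @export
composite_max <- function(tracks) {
  if (length(tracks) < 1L) abort("need at least one track")
  out <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!same_genome(out, t)) abort("genome mismatch between tracks")
    if (!identical(out$units, t$units)) abort("units mismatch between tracks")
    out$values <- purrr::map2(out$values, t$values, pmax)
  }
  out$units <- paste0("max_", out$units)
  out
}

#' Call peaks by genome-wide thresholding
#'
#' The threshold is `fold` times the genome-wide average signal, computed
#' over every base of every chromosome with zeros included. Positions with
#' value at or above the threshold are kept; qualifying positions whose
#' coordinates differ by at most `merge_dist` are merged into a single peak
#' reported as `[first, last + 1)` with midpoint `floor((start + end) / 2)`.
#'
#' @param track A `signal_track` (typically the composite maximum).
#' @param fold Fold-over-mean threshold (default 10).
#' @param merge_dist Maximum tolerated gap between qualifying positions, bp
#'   (default 30).
#' @return A tibble of peaks (`peak_id`, `chrom`, `start`, `end`,
#'   `midpoint`, `n_qualifying`, `max_value`), with attributes `threshold`,
#'   `fold`, `merge_dist`, `genome_mean`.
#' @export
call_peaks <- function(track, fold = 10, merge_dist = 30) {
  if (fold <= 0) abort("fold must be > 0")
  if (merge_dist < 0) abort("merge_dist must be >= 0")
  mu <- track_mean(track)
  threshold <- fold * mu
  peaks <- vector("list", length(track$values))
  if (mu == 0) {
    warn("all-zero track: no peaks called")
  } else {
    for (ci in seq_along(track$values)) {
      chrom <- names(track$values)[ci]
      v <- track$values[[ci]]
      qual <- which(v >= threshold) - 1L    # 0-based qualifying positions
      if (!length(qual)) next
      brk <- which(diff(qual) > merge_dist)
      ngrp <- length(brk) + 1L
      grp <- factor(rep.int(seq_len(ngrp), diff(c(0L, brk, length(qual)))),
                    levels = seq_len(ngrp))
      first <- qual[c(1L, brk + 1L)]
      last <- qual[c(brk, length(qual))]
      peaks[[ci]] <- tibble(
        chrom = chrom, start = first, end = last + 1L,
        n_qualifying = as.integer(table(grp)),
        max_value = vapply(split(v[qual + 1L], grp), max, 0,
                           USE.NAMES = FALSE))
    }
  }
  out <- bind_rows(peaks)
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_qualifying = integer(), max_value = numeric())
  }
  out <- mutate(out,
                midpoint = as.integer(floor((.data$start + .data$end) / 2)),
                peak_id = paste0("peak_", dplyr::row_number()))
  out <- out[, c("peak_id", "chrom", "start", "end", "midpoint",
                 "n_qualifying", "max_value")]
  attr(out, "threshold") <- threshold
  attr(out, "fold") <- fold
  attr(out, "merge_dist") <- merge_dist
  attr(out, "genome_mean") <- mu
  out
}

# width-bp window centered on a midpoint: [m - floor(w/2), m + ceiling(w/2))
window_around <- function(midpoint, width) {
  half <- floor(width / 2)
  tibble(start = midpoint - half, end = midpoint + (width - half))
}

#' Sum of track signal in fixed-width windows around interval midpoints
#'
#' For each interval, sums track values over the `width`-bp window centered
#' on its midpoint, `[m - floor(w/2), m + ceiling(w/2))`, clipped at
#' chromosome edges.
#'
#' @param track A `signal_track`.
#' @param intervals Tibble with `chrom` and either `midpoint` or
#'   `start`/`end` (midpoint computed as `floor((start+end)/2)`).
#' @param width Window width in bp (50 for temporal analysis, 100 for
#'   ChIP-style comparisons).
#' @return Numeric vector of per-interval occupancy sums.
#' @export
window_sum <- function(track, intervals, width) {
  if (width <= 0) abort("width must be > 0")
  if (nrow(intervals) == 0L) return(numeric())
  mid <- interval_midpoints(intervals)
  win <- window_around(mid, width)
  out <- numeric(nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    v <- track$values[[intervals$chrom[k]]]
    if (is.null(v)) abort(paste0("unknown chromosome: ", intervals$chrom[k]))
    a <- max(win$start[k], 0L)
    b <- min(win$end[k], length(v))
    out[k] <- if (a < b) sum(v[(a + 1L):b]) else 0
  }
  out
}

interval_midpoints <- function(intervals) {
  if ("midpoint" %in% names(intervals)) return(intervals$midpoint)
  as.integer(floor((intervals$start + intervals$end) / 2))
}

iranges_by_chrom <- function(intervals) {
  split(IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
        intervals$chrom)
}

# logical: does each interval in a overlap (>= 1 shared bp) any interval in b
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical())
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  hit <- rep(FALSE, nrow(a))
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chrom)
    ib <- which(b$chrom == chrom)
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    hit[ia] <- IRanges::overlapsAny(ra, rb)
  }
  hit
}

#' False discovery rate from free-MNase control peaks
#'
#' The FDR is the percentage of TF peaks that overlap (share at least 1 bp
#' with) any peak called on the free-MNase control.
#'
#' @param tf_peaks Peak tibble for the TF-MNase sample.
#' @param control_peaks Peak tibble for the free-MNase control (may be
#'   empty, giving 0).
#' @return FDR as a percentage in \[0, 100\].
#' @export
overlap_fdr <- function(tf_peaks, control_peaks) {
  if (nrow(tf_peaks) == 0L) abort("empty TF peak set")
  100 * sum(overlaps_any(tf_peaks, control_peaks)) / nrow(tf_peaks)
}

#' Overlap of two site sets via fixed-width midpoint windows
#'
#' Both sets are expanded to `width`-bp windows centered on their midpoints;
#' a reference site counts as hit when its window shares at least 1 bp with
#' any query window (half-open convention: abutting windows do not overlap).
#'
#' @param query Site tibble (e.g. high-scoring ChEC-seq sites).
#' @param reference Site tibble the percentage refers to (e.g. ChIP peaks).
#' @param width Window width in bp (default 100).
#' @return One-row tibble: `n_overlap`, `n_reference`, `pct` (percentage of
#'   reference sites hit).
#' @export
intersect_window_sets <- function(query, reference, width = 100) {
  qm <- interval_midpoints(query)
  rm_ <- interval_midpoints(reference)
  qw <- dplyr::bind_cols(tibble(chrom = query$chrom), window_around(qm, width))
  rw <- dplyr::bind_cols(tibble(chrom = reference$chrom),
                         window_around(rm_, width))
  n <- sum(overlaps_any(rw, qw))
  tibble(n_overlap = n, n_reference = nrow(reference),
         pct = if (nrow(reference)) 100 * n / nrow(reference) else NA_real_)
}

#' Fraction of sites unique to one factor
#'
#' Percentage of `sites` whose midpoint window overlaps no window of any
#' site set in `others` — used to ask whether slow sites are shared between
#' factors (a chromatin-accessibility artifact) or factor-specific.
#'
#' @param sites Site tibble for the factor of interest.
#' @param others List of site tibbles for the other factors.
#' @param width Window width in bp (default 100).
#' @return One-row tibble: `n_unique`, `n_total`, `pct`.
#' @export
fraction_unique <- function(sites, others, width = 100) {
  m <- interval_midpoints(sites)
  sw <- dplyr::bind_cols(tibble(chrom = sites$chrom), window_around(m, width))
  shared <- rep(FALSE, nrow(sites))
  for (o in others) {
    om <- interval_midpoints(o)
    ow <- dplyr::bind_cols(tibble(chrom = o$chrom), window_around(om, width))
    shared <- shared | overlaps_any(sw, ow)
  }
  tibble(n_unique = sum(!shared), n_total = nrow(sites),
         pct = 100 * sum(!shared) / nrow(sites))
}

#' Spearman correlation of replicate peak occupancies
#'
#' @param occ1,occ2 Equal-length numeric vectors of per-peak occupancy sums
#'   from two replicates (n >= 3).
#' @return Spearman's rho (average ranks for ties).
#' @export
spearman_reproducibility <- function(occ1, occ2) {
  if (length(occ1) != length(occ2)) abort("occupancy vectors differ in length")
  if (length(occ1) < 3L) abort("need at least 3 peaks")
  if (sd(occ1) == 0 || sd(occ2) == 0) {
    abort("constant occupancy vector: Spearman correlation undefined")
  }
  cor(occ1, occ2, method = "spearman")
}
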