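# Strand-oriented average cleavage-end profiles around motif matches, with
# genome-scaled normalization, control subtraction, bootstrap confidence
# bands, and a scalar asymmetry index.

#' Strand-oriented average fragment-end profile around motif matches
#'
#' For each site the `2 * flank`-bp window around the motif-match center is
#' extracted from the end-count track; minus-strand sites are reflected so
#' offsets always increase in the motif's 5' to 3' direction. The profile
#' is the per-offset mean over included sites. Sites whose window exceeds
#' the chromosome are skipped and counted.
#'
#' @param track A `signal_track` of fragment-end counts.
#' @param sites Tibble with `chrom`, `center` (0-based genome coordinate of
#'   the motif-match center) and `strand` (`"+"`/`"-"`).
#' @param flank Flank size in bp (default 50, i.e. a 100-bp window).
#' @return A `chec_profile` tibble: `offset` (-flank .. flank-1), `mean`,
#'   with attributes `n_sites`, `n_skipped`, `flank`, `normalization`.
#' @export
oriented_end_profile <- function(track, sites, flank = 50) {
  if (nrow(sites) == 0L) abort("no sites")
  width <- 2L * flank
  acc <- numeric(width)
  n_used <- 0L
  n_skipped <- 0L
  for (k in seq_len(nrow(sites))) {
    v <- track$values[[sites$chrom[k]]]
    if (is.null(v)) abort(paste0("unknown chromosome: ", sites$chrom[k]))
    a <- sites$center[k] - flank
    b <- sites$center[k] + flank
    if (a < 0 || b > length(v)) {
      n_skipped <- n_skipped + 1L
      next
    }
    win <- v[(a + 1L):b]
    if (identical(sites$strand[k], "-")) win <- rev(win)
    acc <- acc + win
    n_used <- n_used + 1L
  }
  if (n_used == 0L) abort("all site windows exceeded chromosome bounds")
  if (n_skipped > 0L) {
    inform(paste0(n_skipped, " site window(s) clipped at chromosome edge; ",
                  "skipped"))
  }
  new_profile(tibble(offset = seq.int(-flank, flank - 1L),
                     mean = acc / n_used),
              n_sites = n_used, n_skipped = n_skipped, flank = flank,
              normalization = track$units)
}

new_profile <- function(df, ...) {
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("chec_profile", class(df))
  df
}

#' Genome-scale normalize two profiles and subtract the control
#'
#' Each profile is scaled by `genome_size / n_fragments` of its own sample,
#' then the free-MNase control is subtracted elementwise from the TF
#' profile. Negative values are retained.
#'
#' @param profile_tf TF profile from [oriented_end_profile()].
#' @param profile_control Free-MNase control profile on the same offsets.
#' @param n_fragments_tf,n_fragments_control Fragments mapped in each
#'   sample's time point.
#' @param genome_size Genome size in bp (default [YEAST_GENOME_SIZE]).
#' @return A `chec_profile` with normalized, control-subtracted means.
#' @export
normalize_and_subtract <- function(profile_tf, profile_control,
                                   n_fragments_tf, n_fragments_control,
                                   genome_size = YEAST_GENOME_SIZE) {
  if (missing(n_fragments_tf) || missing(n_fragments_control) ||
      is.null(n_fragments_tf) || is.null(n_fragments_control)) {
    abort("fragment counts for both samples are required")
  }
  if (n_fragments_tf <= 0 || n_fragments_control <= 0) {
    abort("fragment counts must be > 0")
  }
  if (!identical(profile_tf$offset, profile_control$offset)) {
    abort("profiles have different offset axes")
  }
  out <- profile_tf
  out$mean <- profile_tf$mean * genome_size / n_fragments_tf -
    profile_control$mean * genome_size / n_fragments_control
  attr(out, "normalization") <- "genome_scaled_minus_control"
  out
}

#' Average signal around sites with a bootstrap confidence band
#'
#' Per-offset mean of track signal over site windows, with a 95% percentile
#' bootstrap band obtained by resampling sites.
#'
#' @param track A `signal_track`.
#' @param sites Tibble with `chrom`, `center`, optional `strand` (oriented
#'   extraction as in [oriented_end_profile()]).
#' @param flank Flank in bp.
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @param conf Band coverage (default 0.95).
#' @return A `chec_profile` tibble: `offset`, `mean`, `lo`, `hi`.
#' @export
average_signal_ci <- function(track, sites, flank = 50, n_boot = 200L,
                              seed = 1L, conf = 0.95) {
  width <- 2L * flank
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  rows <- list()
  for (k in seq_len(nrow(sites))) {
    v <- track$values[[sites$chrom[k]]]
    a <- sites$center[k] - flank
    b <- sites$center[k] + flank
    if (a < 0 || b > length(v)) next
    win <- v[(a + 1L):b]
    if (identical(strand[k], "-")) win <- rev(win)
    rows[[length(rows) + 1L]] <- win
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) abort("no usable sites")
  mu <- colMeans(m)
  offsets <- seq.int(-flank, flank - 1L)
  if (nrow(m) < 2L) {
    warn("fewer than 2 sites: returning mean without confidence band")
    return(new_profile(tibble(offset = offsets, mean = mu,
                              lo = NA_real_, hi = NA_real_),
                       n_sites = nrow(m), flank = flank, conf = conf))
  }
  alpha <- (1 - conf) / 2
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      colMeans(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE])
    }, numeric(width))
  })
  new_profile(tibble(offset = offsets, mean = mu,
                     lo = apply(boots, 1L, quantile, alpha),
                     hi = apply(boots, 1L, quantile, 1 - alpha)),
              n_sites = nrow(m), flank = flank, conf = conf)
}

#' Cleavage asymmetry index of an oriented profile
#'
#' `(U - D) / (U + D)` where U is the summed signal strictly upstream of the
#' motif match and D strictly downstream; the match interior is excluded
#' (cleavage inside the motif, e.g. within linker sequence, is a separate
#' phenomenon). +1 means all cleavage upstream, 0 symmetric, -1 all
#' downstream.
#'
#' @param profile A `chec_profile` with the motif-match center at offset 0.
#' @param motif_width Width of the motif match in bp; interior offsets
#'   `-floor(w/2) .. w - floor(w/2) - 1` are excluded.
#' @return Scalar in \[-1, 1\], or `NA` when U + D = 0.
#' @export
asymmetry_index <- function(profile, motif_width) {
  lo <- -floor(motif_width / 2)
  hi <- motif_width - floor(motif_width / 2) - 1L
  up <- sum(profile$mean[profile$offset < lo])
  down <- sum(profile$mean[profile$offset > hi])
  if (up + down == 0) return(NA_real_)
  (up - down) / (up + down)
}

#' @export
print.chec_profile <- function(x, ...) {
  cat("<chec_profile> ", nrow(x), " offsets, ", attr(x, "n_sites"),
      " sites\n", sep = "")
  NextMethod()
}

#' Plot a cleavage or signal profile
#'
#' @param object A `chec_profile`.
#' @param ... Unused.
#' @return A ggplot: mean signal per offset, with the confidence ribbon when
#'   the profile carries `lo`/`hi` columns.
#' @exportS3Method ggplot2::autoplot
autoplot.chec_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$offset,
                                            y = .data$mean))
  if (all(c("lo", "hi") %in% names(object)) && !all(is.na(object$lo))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo,
                                               ymax = .data$hi),
                                  alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "position relative to motif center (bp)",
                  y = "mean signal")
}
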