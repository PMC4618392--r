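# Fragment-end coverage and the two normalization schemes:
#   depth-scaled   — v / total read ends * total mapped bases (track display)
#   genome-scaled  — v * genome size / fragments mapped (profile analysis)

#' Count fragment ends per base position
#'
#' Every fragment contributes one count at its first base (`start`) and one
#' at its last base (`end - 1`); both MNase cut sites land on real bases
#' under half-open coordinates. A length-1 fragment therefore contributes 2
#' at its single position. The track sum is exactly twice the fragment count.
#'
#' @param frags Fragment tibble (see [read_fragments()]).
#' @param genome A [genome_index()].
#' @return A `signal_track` of raw end counts, with attributes
#'   `n_fragments`, `n_ends`, `mapped_bases`.
#' @export
end_counts <- function(frags, genome) {
  validate_fragments(frags, genome)
  track <- signal_track(NULL, genome, units = "raw_ends")
  if (nrow(frags)) {
    for (chrom in unique(frags$chrom)) {
      f <- frags[frags$chrom == chrom, ]
      len <- chrom_length(genome, chrom)
      # 0-based positions start and end-1 -> 1-based indices start+1 and end
      track$values[[chrom]] <- as.numeric(
        tabulate(c(f$start + 1L, f$end), nbins = len))
    }
  }
  st <- fragment_stats(frags)
  attr(track, "n_fragments") <- st$n_fragments
  attr(track, "n_ends") <- st$n_ends
  attr(track, "mapped_bases") <- st$mapped_bases
  track
}

#' Depth-scaled normalization for track visualization
#'
#' Divides each position by the total number of mapped read ends in the
#' sample, then scales by the total number of mapped bases:
#' `v' = v / n_ends * mapped_bases`. This puts samples of different
#' sequencing depth on a common scale.
#'
#' @param track A `signal_track`.
#' @param n_ends Total mapped read ends in the sample; defaults to the
#'   `n_ends` attribute set by [end_counts()].
#' @param mapped_bases Total mapped bases (sum of fragment lengths);
#'   defaults to the track attribute.
#' @return Normalized `signal_track` with units `"depth_scaled"`.
#' @export
depth_normalize <- function(track, n_ends = attr(track, "n_ends"),
                            mapped_bases = attr(track, "mapped_bases")) {
  if (is.null(n_ends) || is.null(mapped_bases)) {
    abort("n_ends and mapped_bases must be supplied or present as attributes")
  }
  if (n_ends <= 0) abort("total read ends must be > 0")
  k <- mapped_bases / n_ends
  track$values <- lapply(track$values, `*`, k)
  track$units <- "depth_scaled"
  track
}

#' Genome-scaled normalization for profile analysis
#'
#' Multiplies each position by the genome size divided by the number of
#' fragments mapped: `v' = v * genome_size / n_fragments`. The default
#' genome size is the budding yeast genome, 12,495,000 bp.
#'
#' @param track A `signal_track`.
#' @param n_fragments Fragments mapped in the sample; defaults to the track
#'   attribute set by [end_counts()].
#' @param genome_size Genome size in bp (default [YEAST_GENOME_SIZE]).
#' @return Normalized `signal_track` with units `"genome_scaled"`.
#' @export
genome_scale_normalize <- function(track,
                                   n_fragments = attr(track, "n_fragments"),
                                   genome_size = YEAST_GENOME_SIZE) {
  if (is.null(n_fragments)) abort("n_fragments must be supplied")
  if (n_fragments <= 0) abort("fragments mapped must be > 0")
  k <- genome_size / n_fragments
  track$values <- lapply(track$values, `*`, k)
  track$units <- "genome_scaled"
  track
}

#' Subtract a free-MNase control track
#'
#' Elementwise difference of two identically normalized tracks. Negative
#' values are retained, not clipped, so that averages over sites stay
#' unbiased.
#'
#' @param tf_track TF-MNase `signal_track`.
#' @param control_track Free-MNase `signal_track` on the same genome and
#'   normalization scheme.
#' @return Difference `signal_track`.
#' @export
subtract_control <- function(tf_track, control_track) {
  if (!same_genome(tf_track, control_track)) abort("genome mismatch")
  if (!identical(tf_track$units, control_track$units)) {
    abort(paste0("normalization scheme mismatch: ", tf_track$units,
                 " vs ", control_track$units))
  }
  tf_track$values <- purrr::map2(tf_track$values, control_track$values, `-`)
  tf_track
}
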