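# End-to-end orchestration: normalize -> composite -> peaks -> kinetics ->
# motifs -> profiles -> shape -> discrimination, with every stage's
# parameters recorded in the returned object (and a JSON sidecar when
# writing to disk).

#' Run the full ChEC-seq analysis pipeline
#'
#' @param fragments Named list of fragment tibbles, one per digestion time
#'   point; names are seconds.
#' @param control Free-MNase control fragment tibble.
#' @param seqs Genome `DNAStringSet`.
#' @param genome A [genome_index()]; default derived from `seqs`.
#' @param motif_counts Position count matrix for the factor's motif.
#' @param shape_table Optional `shape_table`; when `NULL` the shape stage is
#'   skipped with a warning.
#' @param fold Peak threshold in fold over the genome-wide mean (default 10).
#' @param merge_dist Peak merge distance, bp (default 30).
#' @param window_temporal Window for time-course occupancies, bp (default 50).
#' @param window_chip Window for motif-centered analyses, bp (default 100).
#' @param alpha Motif p-value split for high/low classes (default 0.001).
#' @param flank Profile flank, bp (default 50).
#' @param genome_size Genome size for genome-scaled normalization; defaults
#'   to the actual genome total (use [YEAST_GENOME_SIZE] for yeast data).
#' @param pseudocount,background Motif model parameters; background defaults
#'   to the genome's base composition.
#' @param lambda,folds Ridge penalty and cross-validation folds for the
#'   discrimination stage.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional directory; when given, stage outputs and a
#'   parameter manifest are written there.
#' @return A `chec_pipeline` list: tracks and composite, `peaks`,
#'   `time_matrix`, `kinetics`, `matches` (classified, with genome
#'   coordinates), `control_peaks`, `fdr_pct`, `profiles` (per motif class,
#'   raw and control-subtracted, each with its own `asymmetry`),
#'   `asymmetry` (directionality index over reliably oriented sites:
#'   high-scoring matches in the fast kinetic class), `shape` (profiles +
#'   comparisons, or NULL), `discrimination` (AUROCs), `params`.
#' @export
run_pipeline <- function(fragments, control, seqs,
                         genome = genome_index_from_fasta(seqs),
                         motif_counts, shape_table = NULL,
                         fold = 10, merge_dist = 30,
                         window_temporal = 50, window_chip = 100,
                         alpha = 0.001, flank = 50,
                         genome_size = genome_total(genome),
                         pseudocount = 0.1,
                         background = background_from_genome(seqs),
                         lambda = 1, folds = 10L,
                         seed = 1L, out_dir = NULL) {
  params <- list(fold = fold, merge_dist = merge_dist,
                 window_temporal = window_temporal,
                 window_chip = window_chip, alpha = alpha, flank = flank,
                 genome_size = genome_size, pseudocount = pseudocount,
                 lambda = lambda, folds = folds, seed = seed)

  ## normalize ------------------------------------------------------------
  raw_tracks <- lapply(fragments, end_counts, genome = genome)
  norm_tracks <- lapply(raw_tracks, depth_normalize)
  ctrl_raw <- end_counts(control, genome)

  ## composite + peaks ----------------------------------------------------
  composite <- composite_max(norm_tracks)
  peaks <- call_peaks(composite, fold = fold, merge_dist = merge_dist)
  if (nrow(peaks) == 0L) abort("no peaks called")

  ## control peaks + FDR --------------------------------------------------
  ctrl_norm <- depth_normalize(ctrl_raw)
  control_peaks <- call_peaks(ctrl_norm, fold = fold,
                              merge_dist = merge_dist)
  fdr_pct <- overlap_fdr(peaks, control_peaks)

  ## kinetics ---------------------------------------------------------------
  tcm <- build_time_matrix(norm_tracks, peaks, width = window_temporal)
  tcm_z <- zscore_rows(tcm)
  kin <- cluster_kinetics(tcm_z, k = 2, seed = seed + 1L)

  ## motifs -----------------------------------------------------------------
  model <- build_motif(motif_counts, background = background,
                       pseudocount = pseudocount)
  w <- model$width
  half <- window_temporal %/% 2L
  win <- tibble(chrom = peaks$chrom,
                start = peaks$midpoint - half,
                end = peaks$midpoint + (window_temporal - half))
  in_bounds <- win$start >= 0 &
    win$end <= chrom_length(genome, win$chrom)
  if (any(!in_bounds)) {
    inform(paste0(sum(!in_bounds), " peak window(s) clipped at chromosome",
                  " edge; excluded from motif analysis"))
  }
  win_seq <- fetch_sequence(seqs, win[in_bounds, ])
  matches <- best_match(model, win_seq)
  matches$peak_id <- peaks$peak_id[in_bounds]
  matches$chrom <- peaks$chrom[in_bounds]
  matches$match_start <- win$start[in_bounds] + matches$offset
  matches$center <- matches$match_start + w %/% 2L
  matches <- classify_sites(matches, alpha = alpha)
  matches <- left_join(matches,
                       kin$classes[, c("peak_id", "class", "argmax_time")] %>%
                         dplyr::rename(kinetic_class = "class"),
                       by = "peak_id")

  ## profiles ---------------------------------------------------------------
  # per kinetic class, the time point with maximal summed raw signal
  raw_tcm <- build_time_matrix(raw_tracks, peaks, width = window_temporal)
  times <- tcm_times(raw_tcm)
  xs <- tcm_values(raw_tcm)
  ctrl_frags <- fragment_stats(control)$n_fragments
  profiles <- list()
  for (cls in c("high", "low")) {
    m_cls <- matches[matches$class == cls & matches$matched, ]
    if (nrow(m_cls) == 0L) next
    rows <- match(m_cls$peak_id, raw_tcm$peak_id)
    t_best <- times[which.max(colSums(xs[rows, , drop = FALSE]))]
    track_best <- raw_tracks[[format(t_best, trim = TRUE,
                                     scientific = FALSE)]]
    prof_raw <- oriented_end_profile(track_best, m_cls, flank = flank)
    prof_ctrl <- oriented_end_profile(ctrl_raw, m_cls, flank = flank)
    prof <- normalize_and_subtract(
      prof_raw, prof_ctrl,
      n_fragments_tf = attr(track_best, "n_fragments"),
      n_fragments_control = ctrl_frags, genome_size = genome_size)
    # asymmetry on the raw count profile: count sums are nonnegative, so
    # the index stays in [-1, 1]
    profiles[[cls]] <- list(time = t_best, raw = prof_raw,
                            subtracted = prof,
                            asymmetry = asymmetry_index(prof_raw, w))
  }

  ## cleavage directionality ------------------------------------------------
  # Orientation of degenerate motif matches is ambiguous (a weak site can
  # score better on the opposite strand), so the directionality index is
  # measured on the sites whose orientation is reliable: high-scoring
  # matches in the fast kinetic class, at that subset's maximal-signal
  # time point.
  asym <- NULL
  fast_hi <- matches[matches$class == "high" & matches$matched &
                       !is.na(matches$kinetic_class) &
                       matches$kinetic_class == "fast", ]
  if (nrow(fast_hi) > 0L) {
    rows <- match(fast_hi$peak_id, raw_tcm$peak_id)
    t_fh <- times[which.max(colSums(xs[rows, , drop = FALSE]))]
    tr_fh <- raw_tracks[[format(t_fh, trim = TRUE, scientific = FALSE)]]
    prof_fh <- oriented_end_profile(tr_fh, fast_hi, flank = flank)
    asym <- list(index = asymmetry_index(prof_fh, w), time = t_fh,
                 n_sites = attr(prof_fh, "n_sites"), profile = prof_fh)
  }

  ## shape + discrimination ---------------------------------------------------
  halfc <- window_chip %/% 2L
  site_win <- function(m) {
    ww <- tibble(chrom = m$chrom, start = m$center - halfc,
                 end = m$center + (window_chip - halfc), strand = m$strand)
    ww[ww$start >= 0 & ww$end <= chrom_length(genome, ww$chrom), ]
  }
  hi <- matches[matches$class == "high" & matches$matched, ]
  lo <- matches[matches$class == "low" & matches$matched, ]
  shape_res <- NULL
  disc <- NULL
  if (nrow(hi) >= 5L && nrow(lo) >= 5L) {
    hi_win <- site_win(hi)
    lo_win <- site_win(lo)
    exclude <- bind_rows(hi_win[, 1:3], lo_win[, 1:3])
    rand_win <- generate_random_sites(genome, n = nrow(lo_win),
                                      width = window_chip,
                                      exclude = exclude, seed = seed + 2L)
    hi_seq <- fetch_sequence(seqs, hi_win)
    lo_seq <- fetch_sequence(seqs, lo_win)
    rand_seq <- fetch_sequence(seqs, rand_win)
    if (is.null(shape_table)) {
      warn("no shape table supplied: shape stage skipped")
    } else {
      sp <- list(high = class_average_shape(hi_seq, shape_table),
                 low = class_average_shape(lo_seq, shape_table),
                 random = class_average_shape(rand_seq, shape_table))
      shape_res <- list(
        profiles = sp,
        high_vs_low = compare_shape_profiles(sp$high, sp$low),
        high_vs_random = compare_shape_profiles(sp$high, sp$random))
    }
    disc <- discriminate_classes(hi_seq, lo_seq, rand_seq, shape_table,
                                 lambda = lambda, folds = folds,
                                 seed = seed + 3L)
  }

  res <- structure(list(
    tracks = norm_tracks, raw_tracks = raw_tracks, composite = composite,
    peaks = peaks, control_peaks = control_peaks, fdr_pct = fdr_pct,
    time_matrix = tcm_z, kinetics = kin, matches = matches,
    profiles = profiles, asymmetry = asym, shape = shape_res,
    discrimination = disc,
    params = params), class = "chec_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

# sequence- and shape-model AUROCs for high-vs-low and high-vs-random
discriminate_classes <- function(hi_seq, lo_seq, rand_seq, shape_table,
                                 lambda = 1, folds = 10L, seed = 1L) {
  run_pair <- function(pos, neg) {
    seqs <- c(pos, neg)
    labels <- rep(1:0, c(length(pos), length(neg)))
    Xs <- encode_sequence(seqs)
    out <- list(sequence = ridge_auroc(Xs, labels[attr(Xs, "kept")],
                                       lambda = lambda, folds = folds,
                                       seed = seed))
    if (!is.null(shape_table)) {
      Xh <- encode_shape(seqs, shape_table)
      out$shape <- ridge_auroc(Xh, labels[attr(Xh, "kept")],
                               lambda = lambda, folds = folds, seed = seed)
    }
    out
  }
  list(high_vs_low = run_pair(hi_seq, lo_seq),
       high_vs_random = run_pair(hi_seq, rand_seq))
}

#' @export
print.chec_pipeline <- function(x, ...) {
  cat("<chec_pipeline>\n")
  cat("  peaks:", nrow(x$peaks), " (threshold ",
      signif(attr(x$peaks, "threshold"), 5), ")\n", sep = "")
  cat("  FDR vs control:", round(x$fdr_pct, 2), "%\n")
  counts <- attr(x$matches, "class_counts")
  cat("  motif classes: high", counts["high"], "/ low", counts["low"], "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits peaks (BED6, score = max value), kinetic classes, the Z-scored
#' time matrix (TSV, heatmap-viewer compatible), classified matches,
#' profiles and a JSON parameter manifest.
#'
#' @param res A `chec_pipeline` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pk <- res$peaks
  bed <- data.frame(pk$chrom, pk$start, pk$end, pk$peak_id,
                    signif(pk$max_value, 6), ".")
  utils::write.table(bed, file.path(dir, "peaks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(res$time_matrix),
                     file.path(dir, "time_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(tidy(res$kinetics)),
                     file.path(dir, "kinetic_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$matches[res$matches$matched,
                                               c("peak_id", "chrom",
                                                 "match_start", "strand",
                                                 "score", "pvalue",
                                                 "class")]),
                     file.path(dir, "motif_matches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cls in names(res$profiles)) {
    utils::write.table(as.data.frame(res$profiles[[cls]]$subtracted),
                       file.path(dir, paste0("profile_", cls, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- c(res$params,
                list(threshold = attr(res$peaks, "threshold"),
                     genome_mean = attr(res$peaks, "genome_mean"),
                     n_peaks = nrow(res$peaks), fdr_pct = res$fdr_pct))
  jsonlite::write_json(manifest, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Match called peaks to planted simulation sites
#'
#' A planted site is recovered when a peak midpoint lies within
#' `max_dist` bp of the site center; each site takes its nearest such peak.
#'
#' @param peaks Peak tibble.
#' @param manifest Simulation site manifest.
#' @param max_dist Maximum midpoint-to-center distance, bp (default 50).
#' @return The manifest with `recovered` (logical) and `peak_id` columns.
#' @export
match_planted_sites <- function(peaks, manifest, max_dist = 50) {
  out <- manifest
  out$recovered <- FALSE
  out$peak_id <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    same <- peaks$chrom == manifest$chrom[i]
    if (!any(same)) next
    d <- abs(peaks$midpoint[same] - manifest$center[i])
    if (min(d) <= max_dist) {
      out$recovered[i] <- TRUE
      out$peak_id[i] <- peaks$peak_id[same][which.min(d)]
    }
  }
  out
}

#' Heatmap of a Z-scored time-course matrix
#'
#' Rows ordered by time of maximal signal, mirroring clustered-heatmap
#' displays of cleavage kinetics.
#'
#' @param object A `time_course_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap (peaks x time points).
#' @exportS3Method ggplot2::autoplot
autoplot.time_course_matrix <- function(object, ...) {
  amax <- argmax_time(object)
  df <- object
  df$row <- rank(amax, ties.method = "first")
  long <- tidyr::pivot_longer(
    as_tibble(df)[, c("row", grep("^t_", names(df), value = TRUE))],
    dplyr::starts_with("t_"), names_to = "time", values_to = "z")
  long$time <- factor(long$time, levels = paste0(
    "t_", format(tcm_times(object), trim = TRUE, scientific = FALSE)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$row,
                                     fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black",
                                  high = "yellow") +
    ggplot2::labs(x = "time point (s)", y = "peak (by time of max)",
                  fill = "Z")
}
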