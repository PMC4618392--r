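# Synthetic ChEC-seq time courses: a random genome with planted motif
# instances, per-time-point fragment sets whose site-proximal cleavage is
# fast at consensus sites and delayed at degenerate sites, and an
# untargeted free-MNase control. Fragment ENDS carry the site signal (ChEC
# counts cut sites, not midpoints); slow kinetics are modeled as delayed
# onset, not reduced amplitude, so the time of maximal signal separates the
# classes.

#' Default planted motif count matrix
#'
#' A strong 8-bp motif (consensus TTACCCGG) with 85% consensus-base counts
#' per position — comparable in information content to yeast general
#' regulatory factor motifs.
#'
#' @return An 8 x 4 count matrix (A, C, G, T columns).
#' @export
default_motif_counts <- function() {
  consensus <- c("T", "T", "A", "C", "C", "C", "G", "G")
  m <- matrix(5, length(consensus), 4,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(consensus), match(consensus, DNA_BASES))] <- 85
  m
}

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' test suite: a 100-kb genome at yeast-like GC content, 200 fast
#' (exact-consensus) and 200 slow (2-mismatch) planted sites, and a 6-point
#' digestion time course from 10 s to 20 min. Fast sites saturate with a
#' ~15-s time constant; slow sites start cleaving only after ~2.5 min.
#'
#' @param genome_length Genome length, bp.
#' @param chrom Chromosome name.
#' @param gc GC fraction of the random genome.
#' @param motif_counts Motif count matrix (w x 4) to plant.
#' @param n_fast,n_slow Number of fast (exact consensus) and slow
#'   (mismatched) planted sites.
#' @param n_mismatch Mismatches introduced into slow-site instances.
#' @param time_points Digestion time points, seconds, increasing.
#' @param site_amplitude Expected fragments per site per time point at
#'   saturation (before per-site lognormal variation).
#' @param site_log_sd Lognormal sd of per-site amplitude factors.
#' @param fast_tau Saturation time constant of fast sites, s.
#' @param slow_onset,slow_tau Onset delay and time constant of slow sites, s.
#' @param cut_offset,cut_sd Mean and sd (bp) of the cut-site distance from
#'   the motif edge.
#' @param n_background Untargeted background fragments per sample.
#' @param frag_len_mean,frag_len_sd,frag_len_min,frag_len_max Fragment
#'   length distribution (normal, truncated).
#' @param n_hotspots Number of shared mass-action cleavage hotspots.
#' @param hotspot_amplitude Median expected fragments per hotspot.
#' @param hotspot_sd Sd (bp) of hotspot cut positions.
#' @param geometry `"symmetric"` (cuts flank both motif edges) or
#'   `"upstream_only"` (all cuts 5' of the motif, Reb1-like).
#' @param upstream_len_mean,upstream_len_sd Fragment length for
#'   upstream-only cleavage, bp.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(genome_length = 100000L, chrom = "chrS",
                              gc = 0.38,
                              motif_counts = default_motif_counts(),
                              n_fast = 200L, n_slow = 200L, n_mismatch = 2L,
                              time_points = c(10, 30, 60, 150, 600, 1200),
                              site_amplitude = 300, site_log_sd = 0.25,
                              fast_tau = 15, slow_onset = 150, slow_tau = 350,
                              cut_offset = 8, cut_sd = 2,
                              n_background = 20000L,
                              frag_len_mean = 120, frag_len_sd = 30,
                              frag_len_min = 30, frag_len_max = 250,
                              n_hotspots = 30L, hotspot_amplitude = 120,
                              hotspot_sd = 4,
                              geometry = c("symmetric", "upstream_only"),
                              upstream_len_mean = 60, upstream_len_sd = 15,
                              seed = 42L) {
  geometry <- match.arg(geometry)
  if (is.unsorted(time_points, strictly = TRUE)) {
    abort("time points must be strictly increasing")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# expected per-site fragment intensity at time t (before site factor)
class_intensity <- function(config, class, t) {
  A <- config$site_amplitude
  ifelse(class == "fast",
         A * (1 - exp(-t / config$fast_tau)),
         A * pmax(0, 1 - exp(-pmax(t - config$slow_onset, 0) /
                               config$slow_tau)))
}

#' Simulate a genome with planted motif sites
#'
#' Bases are drawn i.i.d. at the configured GC content; exact consensus
#' instances are written at fast sites and `n_mismatch`-mutated instances
#' at slow sites, on random strands, at non-overlapping positions recorded
#' in the manifest.
#'
#' @param config A [simulation_config()].
#' @return List: `seqs` (DNAStringSet), `genome` ([genome_index()]),
#'   `manifest` (tibble: `site_id`, `chrom`, `start`, `end`, `strand`,
#'   `class`, `center`, `planted_seq`), `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  w <- nrow(config$motif_counts)
  consensus <- DNA_BASES[apply(config$motif_counts, 1L, which.max)]
  n_sites <- config$n_fast + config$n_slow
  withr_seed(config$seed, {
    p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
           (1 - config$gc) / 2)
    bases <- sample(DNA_BASES, config$genome_length, replace = TRUE, prob = p)
    # non-overlapping site slots: jittered grid keeps >= 160 bp separation
    grid <- seq(150L, config$genome_length - 150L - w, by = 240L)
    if (length(grid) < n_sites) {
      abort("genome too short for requested number of sites")
    }
    starts <- sort(sample(grid, n_sites)) +
      sample(-40:40, n_sites, replace = TRUE)
    cls <- sample(rep(c("fast", "slow"), c(config$n_fast, config$n_slow)))
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    planted <- character(n_sites)
    for (i in seq_len(n_sites)) {
      inst <- consensus
      if (cls[i] == "slow" && config$n_mismatch > 0L) {
        pos <- sample.int(w, config$n_mismatch)
        for (q in pos) {
          inst[q] <- sample(setdiff(DNA_BASES, inst[q]), 1L)
        }
      }
      planted[i] <- paste(inst, collapse = "")
      genomic <- if (strand[i] == "+") inst else
        strsplit(reverse_complement(planted[i]), "")[[1]]
      bases[(starts[i] + 1L):(starts[i] + w)] <- genomic
    }
    seqs <- Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""),
                                              config$chrom))
    manifest <- tibble(site_id = paste0("site_", seq_len(n_sites)),
                       chrom = config$chrom, start = starts,
                       end = starts + w, strand = strand, class = cls,
                       center = starts + w %/% 2L, planted_seq = planted)
    list(seqs = seqs, genome = genome_index_from_fasta(seqs),
         manifest = manifest, config = config)
  })
}

clamp_fragments <- function(start, end, L) {
  start <- pmax(as.integer(round(start)), 0L)
  end <- pmin(as.integer(round(end)), L)
  keep <- start < end
  tibble(start = start[keep], end = end[keep])
}

rlen <- function(n, config) {
  pmin(pmax(round(rnorm(n, config$frag_len_mean, config$frag_len_sd)),
            config$frag_len_min), config$frag_len_max)
}

# fragments for one site given its fragment count
site_fragments <- function(n, site_start, site_end, strand, config) {
  if (n == 0L) return(tibble(start = integer(), end = integer()))
  d1 <- pmax(1, round(rnorm(n, config$cut_offset, config$cut_sd)))
  if (config$geometry == "symmetric") {
    d2 <- pmax(1, round(rnorm(n, config$cut_offset, config$cut_sd)))
    tibble(start = site_start - d1, end = site_end + d2)
  } else {
    len <- pmax(10, round(rnorm(n, config$upstream_len_mean,
                                config$upstream_len_sd)))
    if (strand == "+") {
      tibble(start = site_start - d1 - len, end = site_start - d1)
    } else {
      tibble(start = site_end + d1, end = site_end + d1 + len)
    }
  }
}

background_fragments <- function(n, config) {
  len <- rlen(n, config)
  start <- floor(runif(n, 0, config$genome_length - 1))
  tibble(start = start, end = start + len)
}

hotspot_fragments <- function(n, pos, config) {
  if (n == 0L) return(tibble(start = integer(), end = integer()))
  cut <- round(rnorm(n, pos, config$hotspot_sd))
  len <- rlen(n, config)
  left <- runif(n) < 0.5
  tibble(start = ifelse(left, cut - len, cut),
         end = ifelse(left, cut, cut + len))
}

#' Simulate a ChEC time course plus free-MNase control
#'
#' For each time point, site-proximal fragments are drawn with
#' class-dependent intensity (fast: saturating early; slow: delayed onset),
#' untargeted background fragments uniformly, and mass-action hotspot
#' fragments whose intensity grows over the digestion. The control sample
#' contains background and full-strength hotspot cleavage but no
#' site-targeted signal. Hotspots are shared between the TF samples and the
#' control and placed away from planted sites.
#'
#' @param sim Output of [simulate_genome()].
#' @param seed Integer seed; default derived from the master seed.
#' @return List: `fragments` (named list of fragment tibbles, one per time
#'   point, names = seconds), `control` (fragment tibble), `hotspots`
#'   (tibble: `pos`, `amplitude`), `site_factors` (per-site lognormal
#'   amplitude factors).
#' @export
simulate_timecourse <- function(sim, seed = sim$config$seed + 1L) {
  config <- sim$config
  man <- sim$manifest
  L <- config$genome_length
  withr_seed(seed, {
    site_factor <- exp(rnorm(nrow(man), 0, config$site_log_sd))
    # hotspots kept >= 150 bp from planted site centers
    hp <- numeric(0)
    while (length(hp) < config$n_hotspots) {
      cand <- floor(runif(config$n_hotspots, 300, L - 300))
      ok <- vapply(cand, function(x) all(abs(x - man$center) >= 150), TRUE)
      hp <- head(c(hp, cand[ok]), config$n_hotspots)
    }
    hot <- tibble(pos = hp,
                  amplitude = stats::rlnorm(config$n_hotspots,
                                            log(config$hotspot_amplitude),
                                            0.6))
    t_max <- max(config$time_points)
    frag_sets <- list()
    for (t in config$time_points) {
      mu <- class_intensity(config, man$class, t) * site_factor
      n_i <- rpois(nrow(man), mu)
      parts <- vector("list", nrow(man) + 2L)
      for (i in seq_len(nrow(man))) {
        parts[[i]] <- site_fragments(n_i[i], man$start[i], man$end[i],
                                     man$strand[i], config)
      }
      parts[[nrow(man) + 1L]] <- background_fragments(config$n_background,
                                                      config)
      nh <- rpois(nrow(hot), hot$amplitude * t / t_max)
      parts[[nrow(man) + 2L]] <- bind_rows(
        lapply(seq_len(nrow(hot)),
               function(h) hotspot_fragments(nh[h], hot$pos[h], config)))
      f <- bind_rows(parts)
      f <- clamp_fragments(f$start, f$end, L)
      f$chrom <- config$chrom
      f$sample <- "tf"
      f$time <- t
      frag_sets[[format(t, trim = TRUE, scientific = FALSE)]] <-
        f[, c("chrom", "start", "end", "sample", "time")]
    }
    nh <- rpois(nrow(hot), hot$amplitude)
    ctrl <- bind_rows(
      background_fragments(config$n_background, config),
      bind_rows(lapply(seq_len(nrow(hot)),
                       function(h) hotspot_fragments(nh[h], hot$pos[h],
                                                     config))))
    ctrl <- clamp_fragments(ctrl$start, ctrl$end, L)
    ctrl$chrom <- config$chrom
    ctrl$sample <- "free_mnase"
    ctrl$time <- NA_real_
    list(fragments = frag_sets,
         control = ctrl[, c("chrom", "start", "end", "sample", "time")],
         hotspots = hot, site_factors = site_factor)
  })
}

#' Write simulation outputs to a directory
#'
#' Emits FASTA, chrom.sizes, one BED per time point, the control BED and
#' the site manifest TSV.
#'
#' @param sim Output of [simulate_genome()].
#' @param tc Output of [simulate_timecourse()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, tc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$seqs, file.path(dir, "genome.fa"))
  utils::write.table(sim$genome[, c("chrom", "length")],
                     file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (t in names(tc$fragments)) {
    write_fragments(tc$fragments[[t]], file.path(dir, paste0("t", t, ".bed")))
  }
  write_fragments(tc$control, file.path(dir, "free_mnase.bed"))
  utils::write.table(sim$manifest, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
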