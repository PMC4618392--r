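# Shared fixtures, built in code. The default simulation and its pipeline
# run are computed once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# random sparse signal track on a small genome
random_track <- function(len = 500, n_nonzero = 40, max_val = 20, seed = 1) {
  set.seed(seed)
  g <- genome_index("chrT", len)
  v <- numeric(len)
  pos <- sample.int(len, min(n_nonzero, len))
  v[pos] <- sample.int(max_val, length(pos), replace = TRUE)
  signal_track(list(chrT = v), g)
}

# random fragment tibble on a given genome
random_fragments <- function(genome, n = 100, seed = 1) {
  set.seed(seed)
  len <- genome$length[1]
  start <- sample.int(len - 60L, n, replace = TRUE) - 1L
  tibble::tibble(chrom = genome$chrom[1], start = start,
                 end = start + sample(1:50, n, replace = TRUE),
                 sample = "x", time = 30)
}

# small shape table restricted helper: full symmetric synthetic table
test_shape_table <- function() memo("shape_table", symmetric_shape_table(7))

# the reference study conditions (simulator defaults)
default_sim <- function() memo("sim", simulate_genome(simulation_config()))
default_timecourse <- function() {
  memo("tc", simulate_timecourse(default_sim()))
}
default_run <- function() {
  memo("run", {
    sim <- default_sim()
    tc <- default_timecourse()
    suppressMessages(suppressWarnings(
      run_pipeline(tc$fragments, tc$control, sim$seqs,
                   motif_counts = sim$config$motif_counts,
                   shape_table = test_shape_table(), seed = 11)))
  })
}

# upstream-only (Reb1-like) geometry run, motif stage only
upstream_run <- function() {
  memo("upstream_run", {
    cfg <- simulation_config(geometry = "upstream_only")
    sim <- simulate_genome(cfg)
    tc <- simulate_timecourse(sim)
    res <- suppressMessages(suppressWarnings(
      run_pipeline(tc$fragments, tc$control, sim$seqs,
                   motif_counts = cfg$motif_counts, seed = 12)))
    list(sim = sim, tc = tc, res = res)
  })
}

# independent exhaustive threshold-and-merge peak caller (oracle)
naive_call_peaks <- function(track, fold = 10, merge_dist = 30) {
  mu <- track_mean(track)
  threshold <- fold * mu
  out <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (mu == 0) next
    qual <- which(v >= threshold) - 1L
    if (!length(qual)) next
    cur_start <- qual[1]
    cur_end <- qual[1]
    flush <- function(s, e) {
      out[[length(out) + 1L]] <<- tibble::tibble(chrom = chrom, start = s,
                                                 end = e + 1L)
    }
    if (length(qual) > 1L) {
      for (p in qual[-1]) {
        if (p - cur_end <= merge_dist) {
          cur_end <- p
        } else {
          flush(cur_start, cur_end)
          cur_start <- p
          cur_end <- p
        }
      }
    }
    flush(cur_start, cur_end)
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  dplyr::bind_rows(out)
}

# brute-force AUROC over all positive/negative pairs
pairwise_auroc <- function(pred, lab) {
  pos <- pred[lab == 1]
  neg <- pred[lab == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# random DNA strings
random_dna <- function(n, len, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}
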