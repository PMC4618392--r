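test_that("composite max is the positionwise maximum", {
  g <- genome_index("chrI", 50)
  mk <- function(v) signal_track(list(chrI = v), g)
  t1 <- mk(c(1, rep(0, 49)))
  t2 <- mk(c(2, rep(0, 49)))
  t3 <- mk(c(3, rep(0, 49)))
  expect_equal(composite_max(list(t1, t2, t3))$values$chrI[1], 3)
  expect_equal(composite_max(list(t1))$values$chrI, t1$values$chrI)

  # brute-force loop oracle on random tracks
  set.seed(5)
  vs <- replicate(4, runif(50), simplify = FALSE)
  comp <- composite_max(lapply(vs, mk))$values$chrI
  brute <- vapply(1:50, function(i) max(vapply(vs, `[`, 0, i)), 0)
  expect_equal(comp, brute)
})

test_that("threshold is fold times the zero-inclusive genome-wide mean", {
  g <- genome_index("chrI", 100)
  v <- numeric(100)
  v[41] <- 1000
  pk <- call_peaks(signal_track(list(chrI = v), g))
  expect_equal(attr(pk, "genome_mean"), 10)
  expect_equal(attr(pk, "threshold"), 100)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$start, pk$end), c(40L, 41L))

  # uniform track: no position reaches 10x the mean
  u <- signal_track(list(chrI = rep(4, 100)), g)
  expect_equal(nrow(call_peaks(u)), 0L)

  # all-zero track: zero peaks with a warning
  expect_warning(pk0 <- call_peaks(signal_track(NULL, g)), "all-zero")
  expect_equal(nrow(pk0), 0L)
})

test_that("qualifying positions merge at gaps up to the merge distance", {
  g <- genome_index("chrI", 100)
  mk <- function(coords) {
    v <- numeric(100)
    v[coords + 1] <- 1000
    signal_track(list(chrI = v), g)
  }
  expect_equal(nrow(call_peaks(mk(c(0, 30)))), 1L)   # gap 30: merged
  pk <- call_peaks(mk(c(0, 31)))                     # gap 31: separate
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$midpoint, c(0L, 31L))
})

test_that("peak caller agrees with the exhaustive oracle and its invariants", {
  for (s in 1:25) {
    tr <- random_track(len = 200 + 37 * s, n_nonzero = 5 + 3 * s,
                       max_val = 400, seed = s)
    pk <- call_peaks(tr, fold = 10, merge_dist = 30)
    oracle <- naive_call_peaks(tr, fold = 10, merge_dist = 30)
    expect_equal(pk[, c("chrom", "start", "end")],
                 oracle, ignore_attr = TRUE)
    # every qualifying position is inside a peak; every peak holds >= 1
    thr <- attr(pk, "threshold")
    qual <- which(tr$values$chrT >= thr) - 1L
    inside <- rep(FALSE, length(qual))
    for (i in seq_len(nrow(pk))) {
      inside <- inside | (qual >= pk$start[i] & qual < pk$end[i])
      expect_gte(max(tr$values$chrT[(pk$start[i] + 1):pk$end[i]]), thr)
    }
    if (length(qual)) expect_true(all(inside))
  }
})

test_that("window sums match brute-force slice sums and clip at edges", {
  g <- genome_index("chrI", 300)
  v <- numeric(300)
  v[151] <- 5
  tr <- signal_track(list(chrI = v), g)
  mid <- tibble::tibble(chrom = "chrI", midpoint = 150L)
  expect_equal(window_sum(tr, mid, 50), 5)

  u <- signal_track(list(chrI = rep(1, 300)), g)
  expect_equal(window_sum(u, mid, 50), 50)
  # clipped at the left edge: only in-bounds positions counted
  expect_equal(window_sum(u, tibble::tibble(chrom = "chrI", midpoint = 10L),
                          50), 35)

  rt <- random_track(300, 100, seed = 3)
  set.seed(8)
  mids <- tibble::tibble(chrom = "chrT", midpoint = sample(30:270, 20))
  got <- window_sum(rt, mids, 50)
  brute <- vapply(mids$midpoint, function(m) {
    sum(rt$values$chrT[max(m - 25, 0):min(m + 24, 299) + 1])
  }, 0)
  expect_equal(got, brute)
})

test_that("control-overlap FDR reproduces printed count/total arithmetic", {
  # 269 of 7,260 TF peaks overlapping control peaks -> 3.71%
  tf <- tibble::tibble(chrom = "chrI",
                       start = seq(0L, by = 200L, length.out = 7260L))
  tf$end <- tf$start + 10L
  ctrl <- tf[1:269, ]
  expect_equal(round(overlap_fdr(tf, ctrl), 2), 3.71)

  far <- dplyr::mutate(ctrl, start = start + 50L, end = end + 50L)
  expect_equal(overlap_fdr(tf, far), 0)
  expect_equal(overlap_fdr(tf, tf), 100)
  expect_error(overlap_fdr(tf[0, ], ctrl), "empty")

  # monotone nondecreasing as control peaks are added
  expect_lte(overlap_fdr(tf, ctrl[1:100, ]), overlap_fdr(tf, ctrl))
})

test_that("window-set intersection uses half-open 100-bp midpoint windows", {
  # 929 of 1,277 reference peaks hit -> 72.7%
  ref <- tibble::tibble(chrom = "chrI",
                        midpoint = seq(200L, by = 300L, length.out = 1277L))
  qry <- tibble::tibble(chrom = "chrI", midpoint = ref$midpoint[1:929] + 30L)
  out <- intersect_window_sets(qry, ref, width = 100)
  expect_equal(out$n_overlap, 929L)
  expect_equal(round(out$pct, 1), 72.7)

  # abutting windows (gap 0) share no base under half-open convention
  a <- tibble::tibble(chrom = "chrI", midpoint = 500L)
  b <- tibble::tibble(chrom = "chrI", midpoint = 600L)  # windows [450,550) [550,650)
  expect_equal(intersect_window_sets(a, b, 100)$n_overlap, 0L)

  # symmetric counts under a 1-1 mapping
  expect_equal(intersect_window_sets(qry, ref[1:929, ], 100)$n_overlap,
               intersect_window_sets(ref[1:929, ], qry, 100)$n_overlap)
})

test_that("slow-site uniqueness reproduces the printed percentages", {
  mk_sites <- function(n) {
    tibble::tibble(chrom = "chrI",
                   midpoint = seq(200L, by = 300L, length.out = n))
  }
  # (total, shared) pairs: 8,649/1,099; 5,286/1,171; 5,557/583
  cases <- list(c(8649, 1099, 87.3), c(5286, 1171, 77.8), c(5557, 583, 89.5))
  for (cs in cases) {
    sites <- mk_sites(cs[1])
    other <- sites[seq_len(cs[2]), ]
    out <- fraction_unique(sites, list(other), width = 100)
    expect_equal(out$n_unique, cs[1] - cs[2])
    expect_equal(round(out$pct, 1), cs[3])
  }
})

test_that("replicate reproducibility is Spearman rank correlation", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_reproducibility(x, x), 1)
  expect_equal(spearman_reproducibility(x, -x), -1)

  set.seed(11)
  a <- rnorm(50)
  b <- rnorm(50)
  expect_equal(spearman_reproducibility(a, b),
               cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_error(spearman_reproducibility(rep(1, 5), a[1:5]), "constant")
  expect_error(spearman_reproducibility(a[1:2], b[1:2]), "at least 3")
})
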