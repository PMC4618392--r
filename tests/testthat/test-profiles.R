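test_that("oriented profiles reflect minus-strand sites", {
  g <- genome_index("chrI", 400)
  v <- numeric(400)
  v[201 - 3] <- 7          # position 197 = center 200 offset -3
  tr <- signal_track(list(chrI = v), g)
  plus <- tibble::tibble(chrom = "chrI", center = 200L, strand = "+")
  prof <- oriented_end_profile(tr, plus, flank = 50)
  expect_equal(prof$mean[prof$offset == -3], 7)
  expect_equal(sum(prof$mean), 7)

  minus <- dplyr::mutate(plus, strand = "-")
  prof_m <- oriented_end_profile(tr, minus, flank = 50)
  expect_equal(prof_m$mean[prof_m$offset == 2], 7)  # reflected: -3 -> f-1-(f-3)

  # reflection oracle: minus profile is the reverse of the plus profile
  rt <- random_track(400, 150, seed = 12)
  sites <- tibble::tibble(chrom = "chrT", center = c(120L, 250L, 300L),
                          strand = "+")
  p_plus <- oriented_end_profile(rt, sites, flank = 40)
  p_minus <- oriented_end_profile(rt, dplyr::mutate(sites, strand = "-"),
                                  flank = 40)
  expect_equal(p_minus$mean, rev(p_plus$mean))

  # sites too close to the edge are skipped with a message
  edge <- tibble::tibble(chrom = "chrT", center = c(10L, 250L),
                         strand = "+")
  expect_message(pe <- oriented_end_profile(rt, edge, flank = 40), "clipped")
  expect_equal(attr(pe, "n_sites"), 1L)
})

test_that("profile normalization and control subtraction compose linearly", {
  g <- genome_index("chrI", 400)
  rt <- random_track(400, 80, seed = 5)
  sites <- tibble::tibble(chrom = "chrT", center = c(150L, 250L),
                          strand = "+")
  tf <- oriented_end_profile(rt, sites, flank = 30)
  ctrl <- oriented_end_profile(rt, sites, flank = 30)
  # tf == control: zero profile
  zero <- normalize_and_subtract(tf, ctrl, 1000, 1000, genome_size = 12495000)
  expect_equal(zero$mean, rep(0, 60))

  # zero control leaves the genome-scaled tf profile
  ctrl0 <- ctrl
  ctrl0$mean <- rep(0, 60)
  ns <- normalize_and_subtract(tf, ctrl0, 1000, 500, genome_size = 12495000)
  expect_equal(ns$mean, tf$mean * 12495000 / 1000)

  # scale invariance: doubling raw profiles and fragment counts together
  tf2 <- tf
  tf2$mean <- tf$mean * 2
  ctrl2 <- ctrl
  ctrl2$mean <- ctrl$mean * 2
  a <- normalize_and_subtract(tf, ctrl, 1000, 800, genome_size = 12495000)
  b <- normalize_and_subtract(tf2, ctrl2, 2000, 1600, genome_size = 12495000)
  expect_equal(a$mean, b$mean)

  expect_error(normalize_and_subtract(tf, ctrl), "required")
})

test_that("bootstrap band behaves sensibly and covers the truth", {
  g <- genome_index("chrI", 1000)
  v <- rep(2, 1000)
  tr <- signal_track(list(chrI = v), g)
  sites <- tibble::tibble(chrom = "chrI",
                          center = seq(100L, 900L, length.out = 10))
  ci <- average_signal_ci(tr, sites, flank = 10, n_boot = 50, seed = 2)
  expect_equal(ci$lo, ci$mean)             # identical sites: zero width
  expect_equal(ci$hi, ci$mean)

  rt <- random_track(1000, 400, seed = 3)
  sites_t <- dplyr::mutate(sites, chrom = "chrT")
  ci2 <- average_signal_ci(rt, sites_t, flank = 10, n_boot = 100, seed = 2)
  expect_true(all(ci2$lo <= ci2$mean + 1e-12 & ci2$mean <= ci2$hi + 1e-12))

  expect_warning(one <- average_signal_ci(rt, sites_t[1, ], flank = 10),
                 "fewer than 2")
  expect_true(all(is.na(one$lo)))

  # calibration: ~95% coverage for the mean of Gaussian site signals
  set.seed(99)
  truth <- 5
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    m <- matrix(rnorm(20 * 4, truth, 2), 20, 4)  # 20 sites, 4 offsets
    gsim <- genome_index("chrI", 20 * 10)
    vv <- as.vector(t(cbind(m, matrix(0, 20, 6))))
    trs <- signal_track(list(chrI = vv), gsim)
    ss <- tibble::tibble(chrom = "chrI", center = seq(2L, by = 10L,
                                                      length.out = 20))
    cc <- average_signal_ci(trs, ss, flank = 2, n_boot = 200, seed = r)
    hits <- hits + (cc$lo[1] <= truth && truth <= cc$hi[1])
  }
  expect_gt(hits / n_rep, 0.85)
  expect_lte(hits / n_rep, 1)
})

test_that("asymmetry index quantifies upstream excess and reflects exactly", {
  prof <- function(means) {
    structure(tibble::tibble(offset = seq.int(-10L, 9L), mean = means),
              class = c("chec_profile", "tbl_df", "tbl", "data.frame"))
  }
  up <- c(rep(1, 7), rep(0, 13))          # all signal at offsets < -3
  expect_equal(asymmetry_index(prof(up), 4), 1)
  sym <- rep(1, 20)
  expect_equal(asymmetry_index(prof(sym), 4), 0)
  expect_true(is.na(asymmetry_index(prof(rep(0, 20)), 4)))

  # oracle: direct sums on random profiles; reflection negates (even width)
  set.seed(41)
  for (i in 1:10) {
    m <- runif(20)
    p <- prof(m)
    u <- sum(m[1:8])        # offsets -10..-3
    d <- sum(m[13:20])      # offsets 2..9
    expect_equal(asymmetry_index(p, 4), (u - d) / (u + d))
    expect_equal(asymmetry_index(prof(rev(m)), 4),
                 -asymmetry_index(p, 4))
  }
})
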