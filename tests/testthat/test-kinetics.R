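mk_tracks <- function(genome, vals_by_time) {
  lapply(vals_by_time, function(v) signal_track(list(chrI = v), genome))
}

test_that("time-course matrix entries are per-peak window sums", {
  g <- genome_index("chrI", 200)
  v <- function(x) {
    out <- numeric(200)
    out[101] <- x
    out
  }
  tracks <- mk_tracks(g, list(`10` = v(2), `30` = v(8), `60` = v(4)))
  peaks <- tibble::tibble(peak_id = "peak_1", chrom = "chrI",
                          midpoint = 100L)
  tcm <- build_time_matrix(tracks, peaks, width = 50)
  expect_equal(unname(tcm_values(tcm)[1, ]), c(2, 8, 4))
  expect_equal(tcm_times(tcm), c(10, 30, 60))

  # columns ordered by time even when tracks arrive shuffled
  tcm2 <- build_time_matrix(tracks[c(2, 3, 1)], peaks, width = 50)
  expect_equal(unname(tcm_values(tcm2)[1, ]), c(2, 8, 4))

  empty <- build_time_matrix(tracks, peaks[0, ], width = 50)
  expect_equal(nrow(empty), 0L)
  expect_error(build_time_matrix(tracks[1], peaks), "at least two")

  # oracle: manual slice sums on random tracks
  set.seed(6)
  rtr <- lapply(setNames(1:3 * 10, 1:3 * 10), function(t) {
    signal_track(list(chrI = runif(200)), g)
  })
  pk <- tibble::tibble(peak_id = paste0("p", 1:5), chrom = "chrI",
                       midpoint = sample(40:160, 5))
  tm <- tcm_values(build_time_matrix(rtr, pk, width = 50))
  for (j in 1:3) {
    manual <- vapply(pk$midpoint, function(m) {
      sum(rtr[[j]]$values$chrI[(m - 25 + 1):(m + 25)])
    }, 0)
    expect_equal(unname(tm[, j]), manual)
  }
})

test_that("row Z-scoring uses population sd and flags constant rows", {
  g <- genome_index("chrI", 200)
  v <- function(x) {
    out <- numeric(200)
    out[101] <- x
    out
  }
  tracks <- mk_tracks(g, list(`10` = v(2), `30` = v(8), `60` = v(4)))
  peaks <- tibble::tibble(peak_id = "peak_1", chrom = "chrI", midpoint = 100L)
  z <- zscore_rows(build_time_matrix(tracks, peaks, width = 50))
  x <- c(2, 8, 4)
  expected <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(unname(tcm_values(z)[1, ]), expected)
  expect_false(z$degenerate[1])

  # constant row maps to zeros with the degenerate flag
  tracks_c <- mk_tracks(g, list(`10` = v(5), `30` = v(5), `60` = v(5)))
  zc <- zscore_rows(build_time_matrix(tracks_c, peaks, width = 50))
  expect_equal(unname(tcm_values(zc)[1, ]), c(0, 0, 0))
  expect_true(zc$degenerate[1])

  # non-constant rows: mean 0, sd 1 within 1e-9; idempotent
  set.seed(13)
  rtr <- lapply(setNames(c(10, 30, 60, 120), c(10, 30, 60, 120)),
                function(t) signal_track(list(chrI = runif(200)), g))
  pk <- tibble::tibble(peak_id = paste0("p", 1:8), chrom = "chrI",
                       midpoint = sample(40:160, 8))
  z1 <- zscore_rows(build_time_matrix(rtr, pk, width = 50))
  m <- tcm_values(z1)
  expect_lt(max(abs(rowMeans(m))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans((m - rowMeans(m))^2)) - 1)), 1e-9)
  z2 <- zscore_rows(z1)
  expect_equal(tcm_values(z2), m)
})

test_that("argmax time takes the earliest maximal time point", {
  g <- genome_index("chrI", 200)
  v <- function(x) {
    out <- numeric(200)
    out[101] <- x
    out
  }
  peaks <- tibble::tibble(peak_id = "peak_1", chrom = "chrI", midpoint = 100L)
  tie <- build_time_matrix(mk_tracks(g, list(`10` = v(0), `30` = v(1),
                                             `60` = v(1))), peaks, 50)
  expect_equal(argmax_time(tie), 30)
  inc <- build_time_matrix(mk_tracks(g, list(`10` = v(1), `30` = v(2),
                                             `60` = v(3))), peaks, 50)
  expect_equal(argmax_time(inc), 60)

  # naive scan oracle on random rows
  set.seed(21)
  rtr <- lapply(setNames(c(10, 30, 60), c(10, 30, 60)),
                function(t) signal_track(list(chrI = runif(200)), g))
  pk <- tibble::tibble(peak_id = paste0("p", 1:10), chrom = "chrI",
                       midpoint = sample(40:160, 10))
  tm <- build_time_matrix(rtr, pk, 50)
  x <- tcm_values(tm)
  naive <- vapply(seq_len(nrow(x)), function(i) {
    best <- which(x[i, ] == max(x[i, ]))[1]
    tcm_times(tm)[best]
  }, 0)
  expect_equal(argmax_time(tm), naive)
})

test_that("k-means recovers planted kinetic families and labels them by time", {
  # two well-separated synthetic row families: max at t1 vs max at t_last
  set.seed(31)
  n <- 60
  times <- c(10, 30, 60, 150, 600, 1200)
  fast_rows <- t(replicate(n, c(5, 4.5, 4, 3, 2, 1) + rnorm(6, 0, 0.2)))
  slow_rows <- t(replicate(n, c(0.5, 0.6, 0.8, 1.5, 4, 5) + rnorm(6, 0, 0.2)))
  tcm <- tibble::tibble(peak_id = paste0("p", 1:(2 * n)), chrom = "chrI",
                        midpoint = 1:(2 * n))
  mat <- rbind(fast_rows, slow_rows)
  for (j in seq_along(times)) tcm[[paste0("t_", times[j])]] <- mat[, j]
  attr(tcm, "times") <- times
  attr(tcm, "zscored") <- FALSE
  class(tcm) <- c("time_course_matrix", class(tcm))

  z <- zscore_rows(tcm)
  kin <- cluster_kinetics(z, k = 2, seed = 3)
  planted <- rep(c("fast", "slow"), each = n)
  expect_equal(tidy(kin)$class, planted)

  gl <- glance(kin)
  expect_lt(gl$mean_argmax[gl$class == "fast"],
            gl$mean_argmax[gl$class == "slow"])

  # partition invariant under row permutation
  set.seed(77)
  perm <- sample(2 * n)
  zp <- z[perm, ]
  attr(zp, "times") <- times
  attr(zp, "zscored") <- TRUE
  class(zp) <- c("time_course_matrix", class(zp))
  kin_p <- cluster_kinetics(zp, k = 2, seed = 3)
  expect_equal(tidy(kin_p)$class, planted[perm])

  expect_warning(k1 <- cluster_kinetics(z, k = 1, seed = 3), "single class")
  expect_equal(unique(tidy(k1)$class), "fast")
  expect_error(cluster_kinetics(z, k = 2 * n + 1), "fewer rows")
  expect_error(cluster_kinetics(tcm, k = 2), "Z-scored")
})
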