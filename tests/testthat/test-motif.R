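test_that("motif probabilities and log-odds follow the pseudocount model", {
  # counts proportional to background: all log-odds are 0
  bg <- c(0.3, 0.2, 0.2, 0.3)
  counts <- matrix(rep(bg * 100, 3), 3, 4, byrow = TRUE)
  m <- build_motif(counts, background = bg, pseudocount = 0.1)
  expect_equal(m$log_odds, matrix(0, 3, 4), ignore_attr = TRUE)

  # deterministic single-position motif, uniform background, no pseudocount
  m1 <- build_motif(matrix(c(1, 0, 0, 0), 1, 4), pseudocount = 0)
  expect_equal(m1$log_odds[1, 1], 2)   # log2(1 / 0.25) = 2 bits

  # probabilities renormalize to 1 per position
  set.seed(14)
  cm <- matrix(rpois(40, 6), 10, 4)
  mr <- build_motif(cm, background = c(0.31, 0.19, 0.19, 0.31))
  expect_equal(rowSums(mr$prob), rep(1, 10))

  expect_error(build_motif(matrix(0, 2, 4), pseudocount = 0), "zero column")
})

test_that("exact p-values match brute-force enumeration and are monotone", {
  # uniform-background w=3 motif with one optimal letter per position:
  # only the consensus word attains the maximum, p = 0.25^3
  cm <- matrix(1, 3, 4)
  cm[cbind(1:3, c(1, 3, 2))] <- 50
  m <- build_motif(cm, pseudocount = 0)
  max_score <- sum(apply(m$log_odds, 1, max))
  expect_equal(match_pvalue(m, max_score), 0.25^3)
  min_score <- sum(apply(m$log_odds, 1, min))
  expect_equal(match_pvalue(m, min_score), 1)

  # w=4 random motif: DP equals exhaustive enumeration over all 256 words
  set.seed(19)
  cm4 <- matrix(rpois(16, 5) + 1, 4, 4)
  bg <- c(0.28, 0.22, 0.22, 0.28)
  m4 <- build_motif(cm4, background = bg)
  words <- as.matrix(expand.grid(rep(list(1:4), 4)))
  ints <- apply(words, 1, function(w) sum(m4$int_scores[cbind(1:4, w)]))
  probs <- apply(words, 1, function(w) prod(bg[w]))
  for (s in seq(0, m4$max_int, by = 97)) {
    expect_equal(checseq:::int_pvalue(m4, s), sum(probs[ints >= s]),
                 tolerance = 1e-12)
  }

  # monotonicity: higher score -> smaller or equal p
  pv <- checseq:::int_pvalue(m4, 0:m4$max_int)
  expect_true(all(diff(pv) <= 0))
})

test_that("best match scans both strands with leftmost/+ tie-breaking", {
  cm <- matrix(1, 5, 4)
  cm[cbind(1:5, c(4, 4, 1, 2, 3))] <- 60   # consensus TTACG
  m <- build_motif(cm, pseudocount = 0.1)
  win <- paste0("AAAAA", "TTACG", "AAAAA")
  bm <- best_match(m, win)
  expect_equal(bm$offset, 5L)
  expect_equal(bm$strand, "+")
  expect_true(bm$matched)

  # reverse-complemented window: same score on the minus strand
  bm_rc <- best_match(m, reverse_complement(win))
  expect_equal(bm_rc$score, bm$score)
  expect_equal(bm_rc$strand, "-")
  expect_equal(bm_rc$offset, 15L - 5L - 5L)

  expect_false(best_match(m, strrep("N", 20))$matched)
  expect_false(best_match(m, "ACG")$matched)   # shorter than motif

  # strand-flip score invariance on random windows
  for (wseq in random_dna(10, 30, seed = 23)) {
    expect_equal(best_match(m, wseq)$score,
                 best_match(m, reverse_complement(wseq))$score)
  }
})

test_that("site classification splits strictly at the alpha threshold", {
  matches <- tibble::tibble(pvalue = c(0.0009, 0.001, 0.5, NA))
  cls <- classify_sites(matches, alpha = 0.001)
  expect_equal(cls$class, c("high", "low", "low", "low"))
  counts <- attr(cls, "class_counts")
  expect_equal(unname(counts["high"] + counts["low"]), nrow(matches))
  expect_equal(nrow(classify_sites(matches[0, ])), 0L)
})

test_that("random site generation respects exclusions and the seed", {
  g <- genome_index(c("chrI", "chrII"), c(5000, 3000))
  r1 <- generate_random_sites(g, n = 5, width = 100, seed = 4)
  r2 <- generate_random_sites(g, n = 5, width = 100, seed = 4)
  expect_equal(r1, r2)
  expect_equal(nrow(r1), 5L)
  expect_true(all(r1$end - r1$start == 100L))

  excl <- tibble::tibble(chrom = c("chrI", "chrII"), start = c(0L, 0L),
                         end = c(5000L, 3000L))
  expect_error(generate_random_sites(g, 3, 100, exclude = excl, seed = 1,
                                     max_tries = 1000), "could only place")

  half <- tibble::tibble(chrom = "chrI", start = 0L, end = 5000L)
  r3 <- generate_random_sites(g, n = 50, width = 100, exclude = half,
                              seed = 9)
  # exhaustive post-hoc check: no returned window overlaps the exclusion
  expect_true(all(r3$chrom == "chrII"))
})

test_that("motif matrix reader handles MEME, labeled and plain dialects", {
  p <- withr::local_tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "letter-probability matrix: alength= 4 w= 2 nsites= 20",
               " 0.10 0.20 0.30 0.40", " 0.70 0.10 0.10 0.10"), p)
  m <- read_motif_matrix(p)
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(m[1, ], c(0.1, 0.2, 0.3, 0.4))

  writeLines(c("A | 1 2 3", "C | 4 5 6", "G | 7 8 9", "T | 10 11 12"), p)
  m2 <- read_motif_matrix(p)
  expect_equal(dim(m2), c(3L, 4L))
  expect_equal(m2[2, ], c(2, 5, 8, 11))

  writeLines(c("A C G T", "1 2 3 4", "5 6 7 8"), p)
  m3 <- read_motif_matrix(p)
  expect_equal(m3[2, ], c(5, 6, 7, 8))

  writeLines("not a matrix at all", p)
  expect_error(read_motif_matrix(p), "unrecognized")
})
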