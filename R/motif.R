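# PSSM scanning with exact p-values. Log-odds scores are discretized to an
# integer grid; the null score distribution of a background-generated w-mer
# is obtained by convolving the per-position integer score distributions,
# and the p-value of a score is the tail mass at or above it. Sequences are
# scored on the same integer grid, so scan p-values agree exactly with the
# DP distribution.

DNA_BASES <- c("A", "C", "G", "T")

#' Estimate zero-order background base composition from a genome
#'
#' @param seqs A `DNAStringSet` (e.g. from [read_genome_fasta()]).
#' @return Named numeric vector of A/C/G/T frequencies summing to 1
#'   (N and other codes are ignored).
#' @export
background_from_genome <- function(seqs) {
  counts <- colSums(Biostrings::alphabetFrequency(seqs)[, DNA_BASES,
                                                        drop = FALSE])
  counts / sum(counts)
}

#' Build a motif model from a position count matrix
#'
#' Counts are converted to probabilities with a background-distributed
#' pseudocount, `p = (count + pseudocount * bg) / (total + pseudocount)`,
#' then to log2 odds against the background. Scores are discretized to
#' `n_bins` integer bins across the attainable range and the exact null
#' score distribution is computed by dynamic programming, giving a
#' score-to-p-value map where p is the probability that a background w-mer
#' scores at least as high.
#'
#' @param counts Numeric matrix, w rows x 4 columns (A, C, G, T order), of
#'   observed base counts (or probabilities) per motif position.
#' @param background Length-4 A/C/G/T background probabilities (default
#'   uniform).
#' @param pseudocount Total pseudocount per position, distributed by
#'   background (default 0.1).
#' @param n_bins Number of integer score bins across the attainable score
#'   range (default 1000).
#' @return A `motif_model`: list with `width`, `prob` (w x 4), `background`,
#'   `log_odds` (w x 4, bits), `int_scores` (w x 4 integer grid), `scale`,
#'   `offset`, `null_tail` (tail probability per integer score 0..max).
#' @export
build_motif <- function(counts, background = rep(0.25, 4), pseudocount = 0.1,
                        n_bins = 1000L) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) abort("count matrix must have 4 columns (A,C,G,T)")
  if (nrow(counts) < 1L) abort("motif width must be >= 1")
  if (any(counts < 0)) abort("counts must be non-negative")
  background <- background / sum(background)
  if (any(background <= 0)) abort("background probabilities must be positive")
  tot <- rowSums(counts)
  if (any(tot == 0) && pseudocount == 0) {
    abort("zero column sum with zero pseudocount")
  }
  prob <- (counts + pseudocount * matrix(background, nrow(counts), 4,
                                         byrow = TRUE)) / (tot + pseudocount)
  log_odds <- log2(prob / matrix(background, nrow(prob), 4, byrow = TRUE))
  w <- nrow(prob)

  # a zero-probability letter (zero count, zero pseudocount) has -Inf
  # log-odds: its cells are excluded from the integer grid and its null
  # mass falls below every finite score
  finite <- is.finite(log_odds)
  row_min <- apply(ifelse(finite, log_odds, Inf), 1L, min)
  row_max <- apply(ifelse(finite, log_odds, -Inf), 1L, max)
  total_range <- sum(row_max - row_min)
  scale <- if (total_range > 0) n_bins / total_range else 0
  int_scores <- round((log_odds - row_min) * scale)
  int_scores[!finite] <- NA_real_
  storage.mode(int_scores) <- "integer"
  offset <- sum(row_min)    # raw score = int/scale + offset (up to rounding)

  max_int <- sum(apply(int_scores, 1L, max, na.rm = TRUE))
  dist <- c(1, numeric(max_int))          # P(int sum = s), s = 0..max_int
  for (i in seq_len(w)) {
    nxt <- numeric(max_int + 1L)
    for (j in 1:4) {
      s <- int_scores[i, j]
      if (is.na(s)) next                  # impossible letter: mass drops out
      nxt[(s + 1L):(max_int + 1L)] <-
        nxt[(s + 1L):(max_int + 1L)] +
        background[j] * dist[1:(max_int + 1L - s)]
    }
    dist <- nxt
  }
  null_tail <- rev(cumsum(rev(dist)))     # P(int sum >= s), finite words only
  null_tail <- pmin(pmax(null_tail, 0), 1)

  structure(list(width = w, prob = prob, background = background,
                 log_odds = log_odds, int_scores = int_scores,
                 scale = scale, offset = offset, null_tail = null_tail,
                 max_int = max_int),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> width", x$width, "| consensus", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a motif model
#' @param model A `motif_model`.
#' @return Character string of the most probable base per position.
#' @export
motif_consensus <- function(model) {
  paste(DNA_BASES[apply(model$prob, 1L, which.max)], collapse = "")
}

#' Exact p-value of a motif score
#'
#' The p-value is the probability that a background-generated sequence of
#' motif width scores at least as high as `score`. Scores above the maximum
#' attainable return the probability of the top bin (never 0); scores at or
#' below the minimum return 1.
#'
#' @param model A `motif_model`.
#' @param score Raw log2-odds score(s).
#' @return P-value(s) in (0, 1].
#' @export
match_pvalue <- function(model, score) {
  int <- round((score - model$offset) * model$scale)
  int[!is.finite(score)] <- -1L    # -Inf score: below everything, p = 1
  int_pvalue(model, int)
}

int_pvalue <- function(model, int) {
  out <- model$null_tail[pmin(pmax(int, 0L), model$max_int) + 1L]
  out[int < 0L] <- 1
  out
}

# encode ACGTN string to integer codes 1..4, N/other -> NA
encode_bases <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  m
}

# score every valid offset of one encoded sequence; returns int scores with
# NA at offsets covering an undefined base
scan_int_scores <- function(model, code) {
  w <- model$width
  L <- length(code)
  if (L < w) return(integer(0))
  n_off <- L - w + 1L
  out <- integer(n_off)
  ok <- rep(TRUE, n_off)
  for (i in seq_len(w)) {
    idx <- code[i:(i + n_off - 1L)]
    bad <- is.na(idx)
    ok <- ok & !bad
    idx[bad] <- 1L
    cell <- model$int_scores[i, idx]
    ok <- ok & !is.na(cell)      # impossible (zero-probability) letter
    cell[is.na(cell)] <- 0L
    out <- out + cell
  }
  out[!ok] <- NA_integer_
  out
}

#' Best motif match in each sequence window
#'
#' Scans both strands at every offset and reports the match with the
#' smallest p-value (highest score) per window; ties are broken by leftmost
#' position on the forward coordinates, then by the + strand. Offsets whose
#' w-mer contains an undefined base (N) are skipped; a window with no valid
#' offset yields a row with `matched = FALSE`.
#'
#' @param model A `motif_model`.
#' @param windows Character vector of window sequences (forward-strand
#'   genomic sequence), each at least motif-width long (shorter windows
#'   yield no match).
#' @return Tibble, one row per window: `window`, `offset` (0-based start of
#'   the match within the window, forward-strand coordinates), `strand`,
#'   `score` (log2 odds), `pvalue`, `matched`.
#' @export
best_match <- function(model, windows) {
  w <- model$width
  out <- vector("list", length(windows))
  for (k in seq_along(windows)) {
    code <- encode_bases(windows[k])
    L <- length(code)
    fwd <- scan_int_scores(model, code)
    rc_code <- rev(5L - code)            # A<->T, C<->G on reversed sequence
    rev_ <- scan_int_scores(model, rc_code)
    # rc offset o (1-based) covers forward positions (L-w-o+1)..(L-o) 0-based
    cand <- tibble(
      int = c(fwd, rev_),
      offset = c(seq_along(fwd) - 1L,
                 if (length(rev_)) L - w - (seq_along(rev_) - 1L) else integer()),
      strand = rep(c("+", "-"), c(length(fwd), length(rev_))))
    cand <- cand[!is.na(cand$int), , drop = FALSE]
    if (nrow(cand) == 0L) {
      out[[k]] <- tibble(window = k, offset = NA_integer_,
                         strand = NA_character_, score = NA_real_,
                         pvalue = NA_real_, matched = FALSE)
      next
    }
    best <- cand[order(-cand$int, cand$offset, cand$strand), ][1, ]
    raw <- if (model$scale > 0) best$int / model$scale + model$offset else
      model$offset
    out[[k]] <- tibble(window = k, offset = as.integer(best$offset),
                       strand = best$strand, score = raw,
                       pvalue = int_pvalue(model, best$int), matched = TRUE)
  }
  bind_rows(out)
}

#' Classify motif matches into high- and low-scoring sites
#'
#' High-scoring sites have best-match p-value strictly below `alpha`
#' (default 0.001); matches with p at or above `alpha` — and windows with no
#' valid match — are low-scoring.
#'
#' @param matches Tibble from [best_match()] (or any tibble with a `pvalue`
#'   column).
#' @param alpha Classification threshold (default 0.001, strict `<`).
#' @return The input with a `class` column (`"high"`/`"low"`), and
#'   attribute `class_counts`.
#' @export
classify_sites <- function(matches, alpha = 0.001) {
  cls <- ifelse(!is.na(matches$pvalue) & matches$pvalue < alpha,
                "high", "low")
  matches$class <- cls
  attr(matches, "class_counts") <- c(high = sum(cls == "high"),
                                     low = sum(cls == "low"))
  matches
}

#' Generate random genomic windows avoiding excluded sites
#'
#' Draws fixed-width windows uniformly over the genome (chromosomes weighted
#' by placeable length) and rejection-samples against >= 1 bp overlap with
#' any excluded interval. Used to build random control site sets matched in
#' number to a peak class.
#'
#' @param genome A [genome_index()].
#' @param n Number of windows.
#' @param width Window width in bp.
#' @param exclude Optional tibble of intervals (`chrom`, `start`, `end`) the
#'   windows must not overlap.
#' @param seed Integer seed.
#' @param max_tries Sampling attempts before giving up (default `200 * n`).
#' @return Tibble of `n` windows: `chrom`, `start`, `end`, `midpoint`.
#' @export
generate_random_sites <- function(genome, n, width, exclude = NULL,
                                  seed = 1L, max_tries = 200L * n) {
  placeable <- pmax(genome$length - width + 1L, 0L)
  if (sum(placeable) == 0L) abort("genome too small for requested width")
  withr_seed(seed, {
    got <- list()
    n_got <- 0L
    tries <- 0L
    while (n_got < n && tries < max_tries) {
      m <- min(max(n - n_got, 64L), 4096L)
      tries <- tries + m
      ci <- sample.int(nrow(genome), m, replace = TRUE,
                       prob = placeable / sum(placeable))
      start <- floor(runif(m, 0, placeable[ci]))
      cand <- tibble(chrom = genome$chrom[ci], start = as.integer(start),
                     end = as.integer(start + width))
      if (!is.null(exclude) && nrow(exclude)) {
        cand <- cand[!overlaps_any(cand, exclude), , drop = FALSE]
      }
      if (nrow(cand)) {
        got[[length(got) + 1L]] <- cand
        n_got <- n_got + nrow(cand)
      }
    }
    if (n_got < n) {
      abort(paste0("could only place ", n_got, " of ", n,
                   " non-excluded windows"))
    }
    out <- head(bind_rows(got), n)
    mutate(out, midpoint = as.integer(floor((.data$start + .data$end) / 2)))
  })
}

## ---- motif file parsing --------------------------------------------------

#' Read a position count/frequency matrix from text
#'
#' Auto-detects three dialects: MEME minimal format (a
#' `letter-probability matrix` block), a transposed 4-row layout with base
#' labels (`A | 1 2 3 ...`, ScerTF style), and a plain numeric table of w
#' rows by 4 columns (optional `A C G T` header).
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix, w rows x 4 columns (A, C, G, T), suitable for
#'   [build_motif()].
#' @export
read_motif_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lp <- grep("letter-probability matrix", lines)
  if (length(lp)) {
    rows <- list()
    for (ln in lines[-seq_len(lp[1])]) {
      nums <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(nums) == 4L && !anyNA(nums)) rows[[length(rows) + 1L]] <- nums
      else if (length(rows)) break
    }
    if (!length(rows)) abort("no matrix rows after letter-probability header")
    return(do.call(rbind, rows))
  }
  lab <- grepl("^\\s*[ACGT]\\s*[|:]", lines)
  if (sum(lab) == 4L) {
    vals <- lapply(lines[lab], function(ln) {
      as.numeric(strsplit(trimws(sub("^\\s*[ACGT]\\s*[|:]", "", ln)),
                          "\\s+")[[1]])
    })
    names(vals) <- sub("^\\s*([ACGT]).*$", "\\1", lines[lab])
    m <- do.call(cbind, vals[DNA_BASES])
    if (anyNA(m)) abort("non-numeric value in labeled motif matrix")
    dimnames(m) <- NULL
    return(m)
  }
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (all(toupper(first) %in% DNA_BASES) && length(first) == 4L) {
    lines <- lines[-1]
  }
  rows <- lapply(lines, function(ln) {
    suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  })
  m <- do.call(rbind, rows)
  if (anyNA(m) || ncol(m) != 4L) abort("unrecognized motif matrix format")
  m
}
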