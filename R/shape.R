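# Pentamer-based DNA shape prediction. A sliding 5-bp window assigns the
# base-centered features MGW (minor groove width, Angstrom) and ProT
# (propeller twist, degrees) to the pentamer's center base, and the
# step-centered features Roll and HelT (degrees) to the two dinucleotide
# steps flanking the center base; step values from the pentamers sharing a
# step are averaged. The pentamer value table is consumed as data.

SHAPE_FEATURES <- c("MGW", "ProT", "Roll", "HelT")

#' Read a pentamer shape table
#'
#' Expected TSV columns: `pentamer`, `MGW`, `ProT`, `Roll1`, `Roll2`,
#' `HelT1`, `HelT2` — base-centered MGW/ProT, and Roll/HelT for the steps
#' left and right of the center base.
#'
#' @param path TSV path (with header).
#' @return A `shape_table` tibble.
#' @export
read_shape_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("pentamer", "MGW", "ProT", "Roll1", "Roll2", "HelT1", "HelT2")
  if (!all(need %in% names(df))) {
    abort(paste0("shape table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  as_shape_table(as_tibble(df[, need]))
}

as_shape_table <- function(df) {
  df$pentamer <- toupper(df$pentamer)
  if (anyDuplicated(df$pentamer)) abort("duplicate pentamer in shape table")
  class(df) <- c("shape_table", class(df))
  df
}

#' Synthetic reverse-complement-symmetric pentamer shape table
#'
#' Generates values for all 1,024 pentamers satisfying the physical
#' symmetry a real table must obey: MGW and ProT are equal for a pentamer
#' and its reverse complement, while the Roll/HelT step values swap. Values
#' are drawn in realistic ranges (MGW ~ 3-6.5 Angstrom, ProT ~ -15-0,
#' Roll ~ -8-8, HelT ~ 30-40 degrees). Synthetic: for testing and
#' simulation, not a physical prediction table.
#'
#' @param seed Integer seed.
#' @return A `shape_table` covering all pentamers.
#' @export
symmetric_shape_table <- function(seed = 1L) {
  pents <- apply(expand.grid(rep(list(DNA_BASES), 5))[, 5:1], 1L,
                 paste, collapse = "")
  rc <- reverse_complement(pents)
  withr_seed(seed, {
    vals <- tibble(pentamer = pents,
                   MGW = runif(1024, 3, 6.5),
                   ProT = runif(1024, -15, 0),
                   Roll1 = runif(1024, -8, 8),
                   Roll2 = runif(1024, -8, 8),
                   HelT1 = runif(1024, 30, 40),
                   HelT2 = runif(1024, 30, 40))
    # impose symmetry: canonical member of each {pent, rc} pair wins
    canon <- pmin(pents, rc)
    idx <- match(canon, pents)
    out <- vals
    out$MGW <- vals$MGW[idx]
    out$ProT <- vals$ProT[idx]
    flip <- pents != canon
    out$Roll1[flip] <- vals$Roll2[idx][flip]
    out$Roll2[flip] <- vals$Roll1[idx][flip]
    out$HelT1[flip] <- vals$HelT2[idx][flip]
    out$HelT2[flip] <- vals$HelT1[idx][flip]
    out$Roll1[!flip] <- vals$Roll1[idx][!flip]
    as_shape_table(out)
  })
}

#' Predict DNA shape features along a sequence
#'
#' @param sequence DNA string (length >= 5). Positions whose covering
#'   pentamer contains N — or a pentamer absent from a partial table — get
#'   `NA`.
#' @param table A `shape_table`.
#' @return Tibble with `position` (0-based), `MGW`, `ProT` (per base;
#'   defined for positions 2..L-3) and `Roll`, `HelT` (per step, value at
#'   `position` describing the step between `position` and `position + 1`,
#'   averaged over the flanking pentamers that cover it).
#' @export
predict_shape <- function(sequence, table) {
  seq_up <- toupper(sequence)
  L <- nchar(seq_up)
  if (L < 5L) abort("sequence must be at least 5 bp")
  centers <- 2:(L - 3L)                       # 0-based center positions
  pent <- substring(seq_up, centers - 1L, centers + 3L)
  idx <- match(pent, table$pentamer)
  mgw <- prot <- rep(NA_real_, L)
  mgw[centers + 1L] <- table$MGW[idx]
  prot[centers + 1L] <- table$ProT[idx]
  # step s (between bases s and s+1, 0-based) takes Roll2/HelT2 from the
  # pentamer centered at s and Roll1/HelT1 from the one centered at s+1
  roll_s <- helt_s <- rep(NA_real_, L - 1L)
  r2 <- h2 <- rep(NA_real_, L)   # right-step value of pentamer centered here
  r1 <- h1 <- rep(NA_real_, L)   # left-step value
  r2[centers + 1L] <- table$Roll2[idx]
  h2[centers + 1L] <- table$HelT2[idx]
  r1[centers + 1L] <- table$Roll1[idx]
  h1[centers + 1L] <- table$HelT1[idx]
  for (s in seq_len(L - 1L)) {    # s is 1-based step index = 0-based step s-1
    contrib_r <- c(r2[s], r1[s + 1L])
    contrib_h <- c(h2[s], h1[s + 1L])
    if (!all(is.na(contrib_r))) roll_s[s] <- mean(contrib_r, na.rm = TRUE)
    if (!all(is.na(contrib_h))) helt_s[s] <- mean(contrib_h, na.rm = TRUE)
  }
  tibble(position = 0:(L - 1L), MGW = mgw, ProT = prot,
         Roll = c(roll_s, NA_real_), HelT = c(helt_s, NA_real_))
}

#' Average shape profile over a set of oriented site sequences
#'
#' @param sequences Character vector of equal-length site window sequences
#'   (oriented 5' to 3' along the motif).
#' @param table A `shape_table`.
#' @return A `shape_profile`: tibble with `offset` (0-based window
#'   position), per-feature means (`MGW`, `ProT`, `Roll`, `HelT`) and
#'   per-feature site counts (`n_MGW`, ...); missing values excluded.
#' @export
class_average_shape <- function(sequences, table) {
  if (!length(sequences)) abort("no sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) abort("sequences must have equal length")
  preds <- lapply(sequences, predict_shape, table = table)
  out <- tibble(offset = 0:(L - 1L))
  for (f in SHAPE_FEATURES) {
    m <- vapply(preds, function(p) p[[f]], numeric(L))
    out[[f]] <- rowMeans(m, na.rm = TRUE)
    out[[f]][is.nan(out[[f]])] <- NA_real_
    out[[paste0("n_", f)]] <- rowSums(!is.na(m))
  }
  class(out) <- c("shape_profile", class(out))
  attr(out, "n_sites") <- length(sequences)
  out
}

#' Compare two average shape profiles
#'
#' For each feature, the Pearson correlation of the two mean-profile
#' vectors and a two-sample Kolmogorov-Smirnov test treating the vectors as
#' value samples. PCC near 1 and a large KS p-value indicate similar
#' profiles.
#'
#' @param a,b `shape_profile` objects on aligned offsets.
#' @param features Features to compare (default all four).
#' @return Tibble: `feature`, `pcc`, `ks_stat`, `ks_p`, `n` (shared
#'   non-missing offsets). `pcc` is `NA` for a constant profile.
#' @export
compare_shape_profiles <- function(a, b, features = SHAPE_FEATURES) {
  rows <- lapply(features, function(f) {
    ok <- !is.na(a[[f]]) & !is.na(b[[f]])
    x <- a[[f]][ok]
    y <- b[[f]][ok]
    if (length(x) < 3L) abort("fewer than 3 shared offsets")
    pcc <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    ks <- suppressWarnings(ks.test(x, y))
    tibble(feature = f, pcc = pcc, ks_stat = unname(ks$statistic),
           ks_p = ks$p.value, n = length(x))
  })
  bind_rows(rows)
}

#' Plot an average shape profile
#'
#' @param object A `shape_profile`.
#' @param ... Unused.
#' @return A ggplot faceted by shape feature.
#' @exportS3Method ggplot2::autoplot
autoplot.shape_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("offset", SHAPE_FEATURES)],
                              dplyr::all_of(SHAPE_FEATURES),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "window position (bp)", y = "predicted value")
}
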