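# Coordinate conventions: 0-based, half-open [start, end) everywhere,
# matching BED/bedgraph. 1-based closed coordinates appear only when
# indexing R vectors internally (position p maps to index p + 1).

#' Construct a genome index
#'
#' A genome index records the ordered chromosome names and lengths that every
#' track, fragment set and interval in the package is validated against.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return A `genome_index`: a tibble with columns `chrom` and `length`, and
#'   attribute `total` (sum of lengths).
#' @export
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) abort("no chromosomes")
  if (anyDuplicated(chrom)) {
    abort(paste0("duplicate chromosome name: ", chrom[duplicated(chrom)][1]))
  }
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    abort("chromosome lengths must be positive integers")
  }
  out <- tibble(chrom = chrom, length = as.integer(length))
  attr(out, "total") <- sum(out$length)
  class(out) <- c("genome_index", class(out))
  out
}

#' Total genome length of a genome index
#' @param genome A `genome_index`.
#' @return Total length in bp.
#' @export
genome_total <- function(genome) {
  stopifnot(inherits(genome, "genome_index"))
  sum(genome$length)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) abort(paste0("unknown chromosome: ", chrom[which(is.na(i))[1]]))
  genome$length[i]
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a whitespace-delimited file with lines
#'   `name<TAB>length`.
#' @return A [genome_index()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("no chromosomes")
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) abort(paste0("malformed chrom.sizes line ", bad[1]))
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len)) {
    abort(paste0("non-numeric length on chrom.sizes line ", which(is.na(len))[1]))
  }
  genome_index(nm, len)
}

#' Read paired-end cleavage fragments from a BED3+ file
#'
#' Each record is one sequenced fragment; both fragment termini are MNase cut
#' sites. Coordinates are validated against the genome index.
#'
#' @param path BED3+ file (chrom, start, end in the first three columns).
#' @param genome A [genome_index()].
#' @param sample Optional sample label.
#' @param time Optional digestion time point in seconds.
#' @return A fragment tibble with columns `chrom`, `start`, `end`, `sample`,
#'   `time` (0-based half-open coordinates).
#' @export
read_fragments <- function(path, genome, sample = NA_character_, time = NA_real_) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    frags <- tibble(chrom = character(), start = integer(), end = integer(),
                    sample = character(), time = numeric())
    return(frags)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "")
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start) || anyNA(end)) {
    abort(paste0("non-numeric BED coordinate at record ",
                 which(is.na(start) | is.na(end))[1]))
  }
  frags <- tibble(chrom = as.character(df[[1]]), start = as.integer(start),
                  end = as.integer(end),
                  sample = sample, time = time)
  validate_fragments(frags, genome)
}

#' Validate a fragment tibble against a genome index
#'
#' @param frags Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome A [genome_index()].
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_fragments <- function(frags, genome) {
  if (nrow(frags) == 0L) return(frags)
  i <- match(frags$chrom, genome$chrom)
  if (anyNA(i)) {
    abort(paste0("fragment record ", which(is.na(i))[1],
                 ": unknown chromosome ", frags$chrom[which(is.na(i))[1]]))
  }
  bad <- which(frags$start >= frags$end)
  if (length(bad)) abort(paste0("fragment record ", bad[1], ": start >= end"))
  bad <- which(frags$start < 0 | frags$end > genome$length[i])
  if (length(bad)) {
    abort(paste0("fragment record ", bad[1], ": outside chromosome bounds"))
  }
  frags
}

#' Summary totals for a fragment set
#'
#' @param frags Fragment tibble.
#' @return One-row tibble: `n_fragments`, `n_ends` (2 per fragment),
#'   `mapped_bases` (sum of fragment lengths).
#' @export
fragment_stats <- function(frags) {
  tibble(n_fragments = nrow(frags),
         n_ends = 2L * nrow(frags),
         mapped_bases = if (nrow(frags)) sum(frags$end - frags$start) else 0L)
}

#' Write a fragment tibble as BED3
#' @param frags Fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  utils::write.table(frags[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- signal tracks -------------------------------------------------------

#' Construct a per-base signal track
#'
#' A signal track holds one numeric value per base position per chromosome.
#'
#' @param values Named list of numeric vectors, one per chromosome, each of
#'   the chromosome's length. If omitted, an all-zero track is created.
#' @param genome A [genome_index()].
#' @param units Character tag describing the value units
#'   (`"raw_ends"`, `"depth_scaled"`, `"genome_scaled"`, ...).
#' @return A `signal_track` object.
#' @export
signal_track <- function(values = NULL, genome, units = "raw_ends") {
  stopifnot(inherits(genome, "genome_index"))
  if (is.null(values)) {
    values <- lapply(setNames(genome$length, genome$chrom), numeric)
  }
  if (!setequal(names(values), genome$chrom)) {
    abort("track chromosomes do not match genome index")
  }
  values <- values[genome$chrom]
  lens <- vapply(values, length, 1L)
  if (!all(lens == genome$length)) abort("track vector length mismatch")
  if (!all(vapply(values, function(v) all(is.finite(v)), TRUE))) {
    abort("track values must be finite")
  }
  structure(list(values = values, genome = genome, units = units),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", length(x$values), " chromosome(s), ",
      format(genome_total(x$genome), big.mark = ","), " bp, units: ",
      x$units, "\n", sep = "")
  invisible(x)
}

#' Sum of all values in a signal track
#' @param track A `signal_track`.
#' @return Numeric scalar.
#' @export
track_sum <- function(track) sum(vapply(track$values, sum, 0))

#' Genome-wide mean of a signal track (zeros included)
#' @param track A `signal_track`.
#' @return Mean value over every base of every chromosome.
#' @export
track_mean <- function(track) track_sum(track) / genome_total(track$genome)

same_genome <- function(a, b) {
  identical(a$genome$chrom, b$genome$chrom) &&
    identical(a$genome$length, b$genome$length)
}

#' Write a signal track as bedgraph
#'
#' Runs of equal value are merged into single intervals; zero runs are
#' omitted. Coordinates are 0-based half-open.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      vals <- vapply(r$values[keep], format, "", trim = TRUE,
                     scientific = FALSE, digits = 15)
      writeLines(paste(chrom, starts[keep], ends[keep], vals), con)
    }
  }
  invisible(path)
}

#' Read a bedgraph file into a signal track
#'
#' Accepts both run-merged and per-base records; positions not covered by any
#' record are restored as 0.
#'
#' @param path Bedgraph path (4 columns: chrom, start, end, value).
#' @param genome A [genome_index()].
#' @param units Units tag to attach.
#' @return A `signal_track`.
#' @export
read_bedgraph <- function(path, genome, units = "raw_ends") {
  track <- signal_track(NULL, genome, units = units)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(track)
  fields <- strsplit(lines, "[ \t]+")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  val <- as.numeric(vapply(fields, `[[`, "", 4L))
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) abort(paste0("bedgraph chromosome not in genome: ",
                             chrom[which(is.na(i))[1]]))
  if (any(start < 0) || any(end > genome$length[i]) || any(start >= end)) {
    abort("bedgraph interval outside genome bounds")
  }
  for (k in seq_along(lines)) {
    track$values[[chrom[k]]][(start[k] + 1):end[k]] <- val[k]
  }
  track
}

## ---- sequence access -----------------------------------------------------

#' Read a genome FASTA into a DNAStringSet
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by chromosome (first word of
#'   each header).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Genome index from a loaded FASTA
#' @param seqs A `DNAStringSet` as returned by [read_genome_fasta()].
#' @return A [genome_index()].
#' @export
genome_index_from_fasta <- function(seqs) {
  genome_index(names(seqs), Biostrings::width(seqs))
}

#' Fetch genomic sequences for intervals
#'
#' Minus-strand intervals return the reverse complement, so returned
#' sequences always read 5' to 3' in the requested orientation. Characters
#' outside ACGTN are mapped to N with a warning.
#'
#' @param seqs A `DNAStringSet` (chromosome sequences).
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `strand` (`"+"`/`"-"`, default `"+"`).
#' @return Character vector of uppercase sequences, one per interval.
#' @export
fetch_sequence <- function(seqs, intervals) {
  if (nrow(intervals) == 0L) return(character())
  strand <- if ("strand" %in% names(intervals)) intervals$strand else
    rep("+", nrow(intervals))
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  i <- match(intervals$chrom, names(seqs))
  if (anyNA(i)) abort(paste0("unknown chromosome: ",
                             intervals$chrom[which(is.na(i))[1]]))
  lens <- Biostrings::width(seqs)[i]
  if (any(intervals$start < 0) || any(intervals$end > lens) ||
      any(intervals$start >= intervals$end)) {
    abort("interval outside chromosome bounds")
  }
  out <- character(nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    s <- Biostrings::subseq(seqs[[i[k]]], intervals$start[k] + 1L,
                            intervals$end[k])
    if (strand[k] == "-") s <- Biostrings::reverseComplement(s)
    out[k] <- toupper(as.character(s))
  }
  if (any(grepl("[^ACGTN]", out))) {
    warn("non-ACGTN characters mapped to N")
    out <- gsub("[^ACGTN]", "N", out)
  }
  out
}

#' Reverse complement of DNA strings
#' @param x Character vector of ACGTN sequences.
#' @return Reverse-complemented character vector.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
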