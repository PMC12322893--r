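#' Genomic intervals and locus strings
#'
#' All coordinates inside chromlink are 0-based half-open (BED convention):
#' an interval covers bases `start, start+1, ..., end-1`. Display strings
#' ("chr13:21045572-21046978") are 1-based inclusive, as shown by genome
#' browsers; [parse_locus()] and [format_locus()] convert between the two
#' conventions and are exact inverses.
#'
#' @param chrom chromosome name(s), non-empty character.
#' @param start 0-based inclusive start(s), integer-like, `>= 0`.
#' @param end exclusive end(s), integer-like, `> start`.
#' @return `genomic_interval()` returns a data.frame with columns
#'   `chrom`, `start`, `end` (one row per interval).
#' @examples
#' genomic_interval("chr13", 21045571, 21046978)
#' parse_locus("chrX:23456-24253566")
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty", call. = FALSE)
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be numeric", call. = FALSE)
  if (any(start < 0)) stop("start must be >= 0", call. = FALSE)
  if (any(end <= start))
    stop("end must be greater than start (half-open intervals)", call. = FALSE)
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Parse a browser-style locus string
#'
#' Accepts `"<chrom>:<start>-<end>"` in 1-based inclusive display
#' coordinates (thousands separators allowed) and returns the interval in
#' the internal 0-based half-open convention.
#'
#' @param text character vector of locus strings, e.g. `"chrX:23456-24253566"`.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @seealso [format_locus()] for the inverse.
#' @export
parse_locus <- function(text) {
  text <- as.character(text)
  clean <- gsub(",", "", text, fixed = TRUE)
  m <- regmatches(clean, regexec("^([^: \t]+):([0-9]+)-([0-9]+)$", clean))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed locus string: ", paste(sQuote(text[bad]), collapse = ", "),
         call. = FALSE)
  chrom <- vapply(m, `[`, "", 2L)
  first <- as.numeric(vapply(m, `[`, "", 3L))
  second <- as.numeric(vapply(m, `[`, "", 4L))
  rev <- first > second | first < 1
  if (any(rev))
    stop("invalid locus coordinates in: ",
         paste(sQuote(text[rev]), collapse = ", "), call. = FALSE)
  genomic_interval(chrom, first - 1, second)
}

#' Format intervals as display locus strings
#'
#' Inverse of [parse_locus()]: internal 0-based half-open coordinates are
#' rendered 1-based inclusive.
#'
#' @param iv data.frame with columns `chrom`, `start`, `end`.
#' @return character vector of `"<chrom>:<start>-<end>"` strings.
#' @export
format_locus <- function(iv) {
  sprintf("%s:%d-%d", iv$chrom, as.integer(iv$start) + 1L, as.integer(iv$end))
}

#' Extend intervals symmetrically
#'
#' Widens each interval by `w` bases on both sides, clamping the start at 0.
#' No right clamp is applied unless chromosome sizes are supplied.
#'
#' @param iv data.frame with columns `chrom`, `start`, `end`.
#' @param w non-negative extension in bases.
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   clamp the extended end.
#' @return data.frame of the same shape with widened coordinates.
#' @export
extend_interval <- function(iv, w, chrom_sizes = NULL) {
  stopifnot(length(w) == 1L, w >= 0)
  out <- iv
  out$start <- pmax(0, iv$start - w)
  out$end <- iv$end + w
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[out$chrom])
    has <- !is.na(lim)
    out$end[has] <- pmin(out$end[has], lim[has])
  }
  out
}

#' Jaccard index of two genomic intervals
#'
#' Overlap length divided by union length, in half-open arithmetic.
#' Intervals on different chromosomes, or without a shared base, score 0.
#' Vectorised over rows; symmetric in its arguments.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end` (recycled to
#'   a common number of rows).
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' jaccard_index(genomic_interval("chr1", 0, 100), genomic_interval("chr1", 50, 150))
#' @export
jaccard_index <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov <- pmax(0, ov)
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  un <- (a$end[ai] - a$start[ai]) + (b$end[bi] - b$start[bi]) - ov
  ifelse(ov > 0, ov / un, 0)
}

# GRanges from an internal 0-based half-open table; seqnames may carry a
# composite key (e.g. "lncRNA|chrom") so that findOverlaps respects attribution.
.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = "*"
  )
}
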