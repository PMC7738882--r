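#' Construct a set of genomic intervals
#'
#' All coordinates in this package follow the BED convention: 0-based,
#' half-open `[start, end)`. Strand affects only TSS/TTS orientation and
#' profile flipping, never interval arithmetic.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued vectors; `0 <= start < end` per interval.
#' @param strand Optional strand vector, each element one of `"+"`, `"-"`,
#'   `"."`. Recycled if length 1.
#' @param name Optional character vector of interval names.
#' @param score Optional numeric score vector.
#' @return A data frame with columns `chrom`, `start`, `end` and any of
#'   `name`, `score`, `strand` that were supplied.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, name = NULL,
                              score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- rep_len(as.character(strand), nrow(df))
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chromosome names must be non-empty")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("%s %d: requires 0 <= start < end (got start=%s, end=%s)",
                 what, bad[1], format(df$start[bad[1]]), format(df$end[bad[1]])))
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  invisible(df)
}

# Convert BED-convention intervals to GRanges (1-based closed) for interval
# algebra. Strand is deliberately dropped: it never participates in overlaps.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Pairwise interval overlap test
#'
#' Tests whether paired intervals overlap by at least `min_bp` under half-open
#' semantics: overlap length is `max(0, min(end) - max(start))` on the same
#' chromosome. Vectorized elementwise over two equal-length interval frames
#' (or one interval against many).
#'
#' @param a,b Interval data frames (see [genomic_intervals()]); the shorter is
#'   recycled if it has one row.
#' @param min_bp Minimum overlap in bp (>= 1).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  len <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  a$chrom[ai] == b$chrom[bi] & len >= min_bp
}

#' Which query intervals overlap any subject interval
#'
#' @inheritParams interval_overlaps
#' @param query,subject Interval data frames.
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subject, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  suppressWarnings(
    IRanges::overlapsAny(as_granges0(query), as_granges0(subject),
                         minoverlap = min_bp))
}

#' Merge overlapping intervals
#'
#' Reduces a set of intervals to its union of maximal non-overlapping runs
#' (abutting intervals are merged as well).
#'
#' @param df Interval data frame.
#' @return Interval data frame sorted by chromosome then start.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  granges_to_intervals(GenomicRanges::reduce(as_granges0(df)))
}

#' Jaccard index between paired intervals
#'
#' `|a intersect b| / |a union b|` in bp; 0 for intervals on different
#' chromosomes.
#'
#' @inheritParams interval_overlaps
#' @return Numeric vector.
#' @export
interval_jaccard <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  inter <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  inter[a$chrom[ai] != b$chrom[bi]] <- 0
  uni <- (a$end[ai] - a$start[ai]) + (b$end[bi] - b$start[bi]) - inter
  inter / uni
}
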