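#' Call enriched peaks on a binned signal track
#'
#' A deliberately simple, fully documented enrichment caller: each bin is
#' tested against a Poisson background whose rate is the larger of the
#' genome-wide mean bin count and the local mean in a centred window
#' (default 10 kb), in the spirit of local-lambda peak callers. Per-bin
#' upper-tail p-values are Benjamini-Hochberg corrected genome-wide;
#' significant bins closer than `merge_gap` are merged and peaks shorter
#' than `min_len` are dropped.
#'
#' @param track A [signal_track()] of (approximately Poisson) bin counts.
#' @param fdr Benjamini-Hochberg false discovery rate for bins (default 0.05).
#' @param min_len Minimum peak length in bp (default 200).
#' @param merge_gap Maximum gap in bp between significant bins to merge
#'   (default 100).
#' @param local_window Width in bp of the local background window
#'   (default 10000).
#' @return A data frame of peaks: `chrom`, `start`, `end`, `name`, `summit`
#'   (bp, centre of the highest bin), `raw_density` (reads per kb),
#'   `pvalue` (smallest per-bin Poisson p inside the peak). Empty for an
#'   all-zero track.
#' @export
call_peaks <- function(track, fdr = 0.05, min_len = 200L, merge_gap = 100L,
                       local_window = 10000L) {
  stopifnot(inherits(track, "signal_track"), fdr > 0, fdr < 1)
  bs <- track$bin_size
  nbin <- vapply(track$values, length, numeric(1))
  total <- sum(vapply(track$values, sum, numeric(1)))
  if (total == 0) return(empty_peaks())
  genome_mean <- total / sum(nbin)
  w <- max(1L, round(local_window / bs))
  pvals <- lapply(track$values, function(v) {
    lam <- pmax(genome_mean, running_mean(v, w))
    stats::ppois(ceiling(v) - 1, lam, lower.tail = FALSE)
  })
  padj <- stats::p.adjust(unlist(pvals, use.names = FALSE), method = "BH")
  padj <- split_like(padj, pvals)
  out <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    sig <- which(padj[[ch]] <= fdr & v > 0)
    if (!length(sig)) next
    runs <- merge_bin_runs(sig, max(0L, floor(merge_gap / bs)))
    for (k in seq_len(nrow(runs))) {
      b0 <- runs$from[k]; b1 <- runs$to[k]
      s <- (b0 - 1) * bs
      e <- min(b1 * bs, track$chrom_sizes[[ch]])
      if (e - s < min_len) next
      seg <- v[b0:b1]
      imax <- b0 - 1 + which.max(seg)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        summit = (imax - 1) * bs + bs / 2,
        raw_density = sum(seg) / ((e - s) / 1000),
        pvalue = min(pvals[[ch]][b0:b1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_peaks())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$name <- sprintf("peak_%05d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "name", "summit", "raw_density", "pvalue")]
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), summit = numeric(), raw_density = numeric(),
             pvalue = numeric(), stringsAsFactors = FALSE)
}

# Centred running mean with shrinking windows at the edges.
running_mean <- function(v, w) {
  n <- length(v)
  half <- floor(w / 2)
  C <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (C[hi + 1L] - C[lo + 1L]) / (hi - lo)
}

split_like <- function(x, template) {
  lens <- vapply(template, length, integer(1))
  stats::setNames(split(x, rep(seq_along(lens), lens)), names(template))
}

# Group sorted bin indices into runs allowing gaps of up to gap_bins bins.
merge_bin_runs <- function(idx, gap_bins) {
  brk <- c(TRUE, diff(idx) > gap_bins + 1L)
  grp <- cumsum(brk)
  data.frame(from = tapply(idx, grp, min), to = tapply(idx, grp, max))
}

#' Partition two peak sets into common and unique peaks
#'
#' A peak is common if it overlaps any peak of the other sample by at least
#' `min_bp`. The partition of each sample's list is exhaustive and disjoint.
#'
#' @param peaks1,peaks2 Peak data frames (see [call_peaks()]).
#' @param min_bp Minimum overlap in bp (default 1).
#' @return A list with `common1`, `common2`, `unique1`, `unique2` and
#'   `pairs`, a two-column matrix pairing each common peak of sample 1 with
#'   its maximum-overlap partner in sample 2.
#' @export
classify_common_unique <- function(peaks1, peaks2, min_bp = 1L) {
  c1 <- overlaps_any(peaks1, peaks2, min_bp)
  c2 <- overlaps_any(peaks2, peaks1, min_bp)
  pairs <- max_overlap_pairs(peaks1, peaks2, min_bp)
  list(common1 = peaks1[c1, , drop = FALSE],
       common2 = peaks2[c2, , drop = FALSE],
       unique1 = peaks1[!c1, , drop = FALSE],
       unique2 = peaks2[!c2, , drop = FALSE],
       pairs = pairs)
}

# For every peak in a overlapping b, the index pair (ia, ib) with the
# largest overlap (ties: first).
max_overlap_pairs <- function(a, b, min_bp = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(cbind(ia = integer(0), ib = integer(0)))
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                minoverlap = min_bp))
  ia <- S4Vectors::queryHits(h); ib <- S4Vectors::subjectHits(h)
  if (!length(ia)) return(cbind(ia = integer(0), ib = integer(0)))
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  best <- tapply(seq_along(ia), ia, function(i) i[which.max(ov[i])])
  cbind(ia = ia[best], ib = ib[best])
}
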