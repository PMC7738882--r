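#' Binned signal track
#'
#' A `signal_track` stores per-chromosome signal in fixed-width bins. The
#' value of a bin is interpreted as the signal level over the whole bin span
#' (bedGraph semantics), so for count tracks built at one read per base of
#' coverage the bin value is the read count falling in the bin.
#'
#' @param values Named list of numeric vectors, one per chromosome, all
#'   values >= 0.
#' @param bin_size Bin width in bp (>= 1).
#' @param chrom_sizes Optional named vector of chromosome lengths in bp;
#'   defaults to `length(values[[c]]) * bin_size`.
#' @param library_size Optional total signal; defaults to the sum of all bin
#'   values (the read count when bins hold counts).
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_sizes = NULL,
                         library_size = NULL) {
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)),
            bin_size >= 1)
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(v < 0 | is.na(v)), logical(1))))
    stop("signal_track: all bin values must be finite and >= 0")
  if (is.null(chrom_sizes))
    chrom_sizes <- vapply(values, length, numeric(1)) * bin_size
  chrom_sizes <- chrom_sizes[names(values)]
  if (is.null(library_size))
    library_size <- sum(vapply(values, sum, numeric(1)))
  structure(list(values = values, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes, library_size = library_size),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin %d bp, library size %.4g\n",
              length(x$values), x$bin_size, x$library_size))
  for (ch in names(x$values))
    cat(sprintf("  %s: %d bins (%.4g bp)\n", ch, length(x$values[[ch]]),
                x$chrom_sizes[[ch]]))
  invisible(x)
}

#' Depth-normalize a track to reads (signal) per million
#'
#' @param track A [signal_track()].
#' @return A `signal_track` with values scaled by `1e6 / library_size`.
#' @export
track_rpm <- function(track) {
  stopifnot(inherits(track, "signal_track"), track$library_size > 0)
  k <- 1e6 / track$library_size
  signal_track(lapply(track$values, function(v) v * k), track$bin_size,
               track$chrom_sizes, library_size = 1e6)
}

#' Scale a track's values by a constant
#' @param track A [signal_track()].
#' @param k Positive scale factor.
#' @export
track_scale <- function(track, k) {
  stopifnot(k >= 0)
  signal_track(lapply(track$values, function(v) v * k), track$bin_size,
               track$chrom_sizes, library_size = track$library_size * k)
}

# Per-chromosome prefix sums of bin values, cached computation helper.
track_cumsum <- function(track) lapply(track$values, cumsum)

#' Mean signal over arbitrary intervals
#'
#' Computes the base-pair-weighted mean bin value over each (possibly
#' fractional) interval `[start, end)`: each base carries its bin's value.
#' Intervals are clipped to the chromosome; an interval entirely outside its
#' chromosome (or on an unknown chromosome) yields `NA`.
#'
#' @param track A [signal_track()].
#' @param chrom,start,end Parallel vectors describing intervals (0-based
#'   half-open; `start`/`end` may be fractional, as for scaled gene-body
#'   segments).
#' @return Numeric vector of means, `NA` where no covered base exists.
#' @export
track_means <- function(track, chrom, start, end) {
  bs <- track$bin_size
  out <- rep(NA_real_, length(chrom))
  cs <- track_cumsum(track)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(track$values)) next
    v <- track$values[[ch]]
    C <- cs[[ch]]
    size <- min(track$chrom_sizes[[ch]], length(v) * bs)
    s <- pmax(0, start[idx]); e <- pmin(size, end[idx])
    ok <- which(e > s)
    if (!length(ok)) next
    s <- s[ok]; e <- e[ok]
    i0 <- pmin(floor(s / bs), length(v) - 1)
    i1 <- pmin(ceiling(e / bs) - 1, length(v) - 1)  # last bin touched
    # integral = full bins strictly inside + partial first/last bins
    first_v <- v[i0 + 1]; last_v <- v[i1 + 1]
    single <- i0 == i1
    tot <- numeric(length(s))
    tot[single] <- first_v[single] * (e[single] - s[single])
    if (any(!single)) {
      m <- !single
      full <- ifelse(i1[m] - 1 >= i0[m] + 1,
                     C[i1[m]] - C[i0[m] + 1], 0) * bs
      tot[m] <- first_v[m] * ((i0[m] + 1) * bs - s[m]) + full +
        last_v[m] * (e[m] - i1[m] * bs)
    }
    out[idx[ok]] <- tot / (e - s)
  }
  out
}

#' Total signal over whole-bin intervals
#'
#' Sum of bin values fully or partly inside each interval, weighted by the
#' covered fraction of each bin. For bin-aligned intervals on a count track
#' this is the read count in the interval.
#'
#' @inheritParams track_means
#' @return Numeric vector of sums (0 for out-of-range intervals).
#' @export
track_sums <- function(track, chrom, start, end) {
  m <- track_means(track, chrom, start, end)
  w <- pmin(unname(track$chrom_sizes[chrom]), end) - pmax(0, start)
  s <- m * pmax(w, 0)
  s[is.na(s)] <- 0
  s
}
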