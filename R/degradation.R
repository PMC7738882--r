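#' Call degraded regions from 0 h vs 4 h peak sets
#'
#' The core of the genome-wide histone degradation analysis. Degraded
#' regions are the union of
#' \itemize{
#'   \item peaks unique to 0 h (no 4 h peak overlapping by >= `min_bp`), and
#'   \item common peaks whose normalized M (`log2` 0 h over rescaled 4 h
#'     density) is at least `min_m` and whose one-sided Audic-Claverie
#'     p-value is below `alpha`.
#' }
#' Overlapping results are merged; a merged region containing any
#' differential-common parent is labelled `differential_common`, otherwise
#' `unique_0h`.
#'
#' @param peaks_0h,peaks_4h Peak data frames from [call_peaks()] for the
#'   0 h and 4 h chase samples.
#' @param model A [fit_manorm()] model fitted on these samples' common peaks
#'   (`x1` = 0 h, `x2` = 4 h densities). May be `NULL` when there are no
#'   common peaks.
#' @param alpha Significance level for the differential test (default 0.01).
#' @param min_m Minimum normalized M, i.e. log2 fold loss (default 1 = 2-fold).
#' @param min_bp Minimum overlap defining "present at 4 h" (default 1).
#' @param track_0h Optional 0 h [signal_track()]; when given, each merged
#'   region's density is re-measured from this track.
#' @param genotype Label stored on the result (e.g. `"WT"`).
#' @return A data frame of class `degradation_regions` with columns `chrom`,
#'   `start`, `end`, `provenance`, `M`, `pvalue` (`NA` for pure unique-0h
#'   regions) and, with `track_0h`, `density_0h`; attribute `genotype`.
#' @export
call_degraded_regions <- function(peaks_0h, peaks_4h, model = NULL,
                                  alpha = 0.01, min_m = 1.0, min_bp = 1L,
                                  track_0h = NULL, genotype = "sample") {
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(peaks_0h) == 0L) return(empty_degradation(genotype))
  parts <- classify_common_unique(peaks_0h, peaks_4h, min_bp = min_bp)
  cand <- list()
  if (nrow(parts$unique1))
    cand$unique <- data.frame(parts$unique1[, c("chrom", "start", "end")],
                              provenance = "unique_0h",
                              M = NA_real_, pvalue = NA_real_,
                              stringsAsFactors = FALSE)
  if (nrow(parts$pairs)) {
    if (is.null(model)) stop("common peaks present but no normalization model")
    p1 <- peaks_0h[parts$pairs[, "ia"], , drop = FALSE]
    p2 <- peaks_4h[parts$pairs[, "ib"], , drop = FALSE]
    norm <- manorm_normalize(model, p1$raw_density, p2$raw_density)
    cnt1 <- round(p1$raw_density * (p1$end - p1$start) / 1000)
    cnt2 <- round(norm$x2_norm * (p2$end - p2$start) / 1000)
    pv <- differential_pvalue(cnt1, cnt2)
    keep <- norm$M >= min_m & pv < alpha
    if (any(keep))
      cand$diff <- data.frame(p1[keep, c("chrom", "start", "end")],
                              provenance = "differential_common",
                              M = norm$M[keep], pvalue = pv[keep],
                              stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty_degradation(genotype))
  all <- do.call(rbind, cand)
  merged <- merge_intervals(all)
  # annotate merged regions from their parents
  prov <- character(nrow(merged)); M <- rep(NA_real_, nrow(merged))
  pv <- rep(NA_real_, nrow(merged))
  hit <- max_overlap_pairs(all, merged)
  for (k in seq_len(nrow(merged))) {
    src <- all[hit[hit[, "ib"] == k, "ia"], , drop = FALSE]
    prov[k] <- if (any(src$provenance == "differential_common"))
      "differential_common" else "unique_0h"
    if (any(!is.na(src$M))) {
      M[k] <- max(src$M, na.rm = TRUE)
      pv[k] <- min(src$pvalue, na.rm = TRUE)
    }
  }
  merged$provenance <- prov
  merged$M <- M
  merged$pvalue <- pv
  if (!is.null(track_0h))
    merged$density_0h <- track_sums(track_0h, merged$chrom, merged$start,
                                    merged$end) /
      ((merged$end - merged$start) / 1000)
  rownames(merged) <- NULL
  structure(merged, class = c("degradation_regions", "data.frame"),
            genotype = genotype)
}

empty_degradation <- function(genotype) {
  structure(data.frame(chrom = character(), start = numeric(),
                       end = numeric(), provenance = character(),
                       M = numeric(), pvalue = numeric(),
                       stringsAsFactors = FALSE),
            class = c("degradation_regions", "data.frame"),
            genotype = genotype)
}

#' PA200-dependent degradation regions by genotype subtraction
#'
#' Regions degraded in the wild type that do not overlap (by >= `min_bp`)
#' any degraded region of the knockout. The reverse subtraction (regions
#' degraded only in the knockout) is available via `direction = "ko_only"`;
#' it is a secondary output not used in the headline analysis.
#'
#' @param wt,ko `degradation_regions` for the wild-type and knockout
#'   genotypes.
#' @param min_bp Minimum overlap in bp that disqualifies a region (default 1).
#' @param direction `"wt_only"` (default, the PA200-dependent set) or
#'   `"ko_only"`.
#' @return A `degradation_regions` data frame, always a subset of the rows
#'   of the minuend set; attribute `genotype` is `"PA200-dependent"` for the
#'   default direction.
#' @export
pa200_dependent_regions <- function(wt, ko, min_bp = 1L,
                                    direction = c("wt_only", "ko_only")) {
  direction <- match.arg(direction)
  a <- if (direction == "wt_only") wt else ko
  b <- if (direction == "wt_only") ko else wt
  keep <- if (nrow(a) == 0L) logical(0) else !overlaps_any(a, b, min_bp)
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("degradation_regions", "data.frame"),
            genotype = if (direction == "wt_only") "PA200-dependent"
                       else "KO-only (non-headline)")
}

#' @export
print.degradation_regions <- function(x, ...) {
  cat(sprintf("%d degradation region(s) [%s]\n", nrow(x),
              attr(x, "genotype")))
  if (nrow(x)) print(table(x$provenance))
  invisible(x)
}
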