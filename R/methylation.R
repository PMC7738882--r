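#' Mean CpG methylation level per region
#'
#' Unweighted arithmetic mean of the levels of CpG sites falling inside each
#' region (half-open). Regions with fewer than `min_sites` CpGs yield `NA`
#' ("no data").
#'
#' @param regions Interval data frame.
#' @param records Methylation records (see [read_methylation()]): `chrom`,
#'   `pos`, `level`.
#' @param min_sites Minimum number of CpGs for a defined mean (default 3).
#' @return List with `mean_cg` (numeric, `NA` = no data) and `n_sites`.
#' @export
region_mean_methylation <- function(regions, records, min_sites = 3L) {
  n <- nrow(regions)
  mean_cg <- rep(NA_real_, n)
  n_sites <- integer(n)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    sub <- records[records$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    o <- order(sub$pos)
    pos <- sub$pos[o]
    cl <- cumsum(c(0, sub$level[o]))
    lo <- findInterval(regions$start[ri] - 0.5, pos)       # sites < start
    hi <- findInterval(regions$end[ri] - 0.5, pos)         # sites < end
    k <- hi - lo
    n_sites[ri] <- k
    ok <- k >= min_sites
    mean_cg[ri[ok]] <- (cl[hi[ok] + 1] - cl[lo[ok] + 1]) / k[ok]
  }
  list(mean_cg = mean_cg, n_sites = n_sites)
}

#' Classify regions as hyper- or hypo-methylated
#'
#' A region is *hyper*-methylated iff its mean CpG level is strictly greater
#' than 0.5, *hypo*-methylated iff the mean is at most 0.5 (with at least
#' `min_sites` CpGs), and *no data* otherwise.
#'
#' @inheritParams region_mean_methylation
#' @return List with `labels` (character per region), `counts` (named vector
#'   over hyper/hypo/no_data) and `mean_cg`.
#' @export
classify_regions <- function(regions, records, min_sites = 3L) {
  mm <- region_mean_methylation(regions, records, min_sites)
  labels <- ifelse(is.na(mm$mean_cg), "no_data",
                   ifelse(mm$mean_cg > 0.5, "hyper", "hypo"))
  counts <- c(hyper = sum(labels == "hyper"),
              hypo = sum(labels == "hypo"),
              no_data = sum(labels == "no_data"))
  list(labels = labels, counts = counts, mean_cg = mm$mean_cg)
}

#' Segment the genome into hyper-/hypo-methylation areas
#'
#' Tiles each chromosome in fixed windows, classifies every window by its
#' mean CpG level (strictly > 0.5 = hyper), and merges runs of adjacent
#' same-label windows into areas. Windows without enough CpGs are labelled
#' `no_data` and break merging.
#'
#' @param records Methylation records.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param window Window width in bp (>= 1000; default 10000).
#' @param min_sites Minimum CpGs per window (default 3).
#' @return Data frame of areas: `chrom`, `start`, `end`, `label`,
#'   `mean_cg` (site mean over the area; `NA` for no_data areas), plus
#'   attribute `counts` with the hyper/hypo area tally.
#' @export
segment_genome_areas <- function(records, chrom_sizes, window = 10000L,
                                 min_sites = 3L) {
  stopifnot(window >= 1000)
  areas <- list()
  for (ch in names(chrom_sizes)) {
    nwin <- ceiling(chrom_sizes[[ch]] / window)
    if (nwin == 0L) next
    wins <- data.frame(chrom = ch,
                       start = (seq_len(nwin) - 1) * window,
                       end = pmin(seq_len(nwin) * window, chrom_sizes[[ch]]),
                       stringsAsFactors = FALSE)
    cls <- classify_regions(wins, records, min_sites)
    r <- rle(cls$labels)
    to <- cumsum(r$lengths)
    from <- to - r$lengths + 1L
    a <- data.frame(chrom = ch, start = wins$start[from], end = wins$end[to],
                    label = r$values, stringsAsFactors = FALSE)
    areas[[ch]] <- a
  }
  out <- do.call(rbind, areas)
  rownames(out) <- NULL
  mm <- region_mean_methylation(out, records, min_sites = 1L)
  out$mean_cg <- ifelse(out$label == "no_data", NA_real_, mm$mean_cg)
  attr(out, "counts") <- c(hyper = sum(out$label == "hyper"),
                           hypo = sum(out$label == "hypo"))
  out
}

#' Call differentially methylated regions between two conditions
#'
#' Windowed comparison: in every fixed window with at least `min_sites`
#' CpGs in both conditions, the mean level difference is tested. With
#' per-site coverage in both conditions the test is a two-proportion test on
#' coverage-weighted methylated counts; otherwise a Welch t-test on site
#' levels (for degenerate zero-variance windows the p-value is 0 when the
#' means differ and 1 when they do not). Windows passing
#' `|mean_b - mean_a| >= min_diff` and a Benjamini-Hochberg adjusted p-value
#' `<= alpha` are kept, and abutting same-direction windows are merged.
#'
#' @param records_a,records_b Methylation records for the two conditions.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param window Window width in bp (default 1000).
#' @param min_diff Minimum absolute level difference (default 0.2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_sites Minimum CpGs per window per condition (default 3).
#' @return Data frame of DMRs: `chrom`, `start`, `end`, `direction` (`hyper`
#'   = more methylated in b, `hypo` = less), `mean_a`, `mean_b`, `diff`.
#' @export
call_dmrs <- function(records_a, records_b, chrom_sizes, window = 1000L,
                      min_diff = 0.2, alpha = 0.05, min_sites = 3L) {
  wins <- list()
  for (ch in names(chrom_sizes)) {
    nwin <- ceiling(chrom_sizes[[ch]] / window)
    if (nwin)
      wins[[ch]] <- data.frame(chrom = ch,
                               start = (seq_len(nwin) - 1) * window,
                               end = pmin(seq_len(nwin) * window,
                                          chrom_sizes[[ch]]),
                               stringsAsFactors = FALSE)
  }
  wins <- do.call(rbind, wins)
  ma <- region_mean_methylation(wins, records_a, min_sites)
  mb <- region_mean_methylation(wins, records_b, min_sites)
  testable <- which(!is.na(ma$mean_cg) & !is.na(mb$mean_cg))
  if (!length(testable)) return(empty_dmrs())
  use_cov <- !all(is.na(records_a$coverage)) && !all(is.na(records_b$coverage))
  pv <- vapply(testable, function(i) {
    dmr_window_pvalue(wins[i, ], records_a, records_b, use_cov)
  }, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")
  diff <- mb$mean_cg[testable] - ma$mean_cg[testable]
  sig <- abs(diff) >= min_diff & padj <= alpha
  if (!any(sig)) return(empty_dmrs())
  hit <- wins[testable[sig], , drop = FALSE]
  hit$direction <- ifelse(diff[sig] > 0, "hyper", "hypo")
  hit$mean_a <- ma$mean_cg[testable[sig]]
  hit$mean_b <- mb$mean_cg[testable[sig]]
  out <- list()
  for (dir in unique(hit$direction)) {
    m <- merge_intervals(hit[hit$direction == dir, , drop = FALSE])
    m$direction <- dir
    out[[dir]] <- m
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  ra <- region_mean_methylation(out, records_a, min_sites = 1L)
  rb <- region_mean_methylation(out, records_b, min_sites = 1L)
  out$mean_a <- ra$mean_cg
  out$mean_b <- rb$mean_cg
  out$diff <- out$mean_b - out$mean_a
  rownames(out) <- NULL
  out
}

empty_dmrs <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             direction = character(), mean_a = numeric(), mean_b = numeric(),
             diff = numeric(), stringsAsFactors = FALSE)
}

dmr_window_pvalue <- function(win, records_a, records_b, use_cov) {
  sa <- records_a[records_a$chrom == win$chrom & records_a$pos >= win$start &
                    records_a$pos < win$end, , drop = FALSE]
  sb <- records_b[records_b$chrom == win$chrom & records_b$pos >= win$start &
                    records_b$pos < win$end, , drop = FALSE]
  if (use_cov) {
    meth <- c(sum(sa$level * sa$coverage), sum(sb$level * sb$coverage))
    tot <- c(sum(sa$coverage), sum(sb$coverage))
    suppressWarnings(stats::prop.test(round(meth), round(tot))$p.value)
  } else {
    va <- stats::var(sa$level); vb <- stats::var(sb$level)
    if ((is.na(va) || va == 0) && (is.na(vb) || vb == 0)) {
      if (isTRUE(all.equal(mean(sa$level), mean(sb$level)))) 1 else 0
    } else {
      stats::t.test(sa$level, sb$level)$p.value
    }
  }
}

#' Methylation fraction summary from hyper/hypo counts
#'
#' Percentage of classified regions that are hyper-methylated, with the
#' denominator restricted to classified (hyper + hypo) regions. Returns the
#' exact two-decimal value and the headline integer (round half away from
#' zero).
#'
#' @param n_hyper,n_hypo Non-negative counts.
#' @return List with `percent` (two decimals), `percent_headline` (integer),
#'   `n_hyper`, `n_hypo`, `n_classified`.
#' @export
methylation_fraction <- function(n_hyper, n_hypo) {
  n <- n_hyper + n_hypo
  if (n == 0L) stop("no classified regions")
  pct <- 100 * n_hyper / n
  list(percent = round_half_away(pct, 2),
       percent_headline = round_half_away(pct, 0),
       n_hyper = n_hyper, n_hypo = n_hypo, n_classified = n)
}

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
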