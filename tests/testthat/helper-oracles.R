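# Independent brute-force oracles. These deliberately share no code with the
# package internals: everything is computed by direct enumeration.

# Overlap length of two intervals by scanning integer base positions.
oracle_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  sum(seq(a$start, a$end - 1) %in% seq(b$start, b$end - 1))
}

# Per-base rebinning of non-overlapping bedGraph records.
oracle_rebin <- function(records, bin_size, chrom_size) {
  base <- numeric(chrom_size)
  for (i in seq_len(nrow(records)))
    base[(records$start[i] + 1):records$end[i]] <- records$value[i]
  n <- ceiling(chrom_size / bin_size)
  vapply(seq_len(n), function(k) {
    idx <- ((k - 1) * bin_size + 1):min(k * bin_size, chrom_size)
    sum(base[idx]) / bin_size
  }, numeric(1))
}

# Per-base weighted mean of a binned track over [s, e) with possibly
# fractional boundaries, integrating bin values base by base.
oracle_track_mean <- function(values, bin_size, s, e, chrom_size = NULL) {
  if (is.null(chrom_size)) chrom_size <- length(values) * bin_size
  s <- max(0, s); e <- min(e, chrom_size, length(values) * bin_size)
  if (e <= s) return(NA_real_)
  total <- 0
  x <- s
  while (x < e) {
    nxt <- min(floor(x / bin_size) * bin_size + bin_size, e)
    total <- total + values[floor(x / bin_size) + 1] * (nxt - x)
    x <- nxt
  }
  total / (e - s)
}

# Audic-Claverie conditional pmf by direct log-space evaluation, and the
# tail sums / symmetrized diverge probability by explicit summation.
oracle_ac_pmf <- function(y, x, r) {
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log(1 + r))
}

oracle_ac_lower <- function(x, y, r) sum(oracle_ac_pmf(0:y, x, r))

oracle_diverge <- function(ca, cb, la, lb) {
  one_dir <- function(x, y, r) {
    lo <- oracle_ac_lower(x, y, r)
    hi <- 1 - (if (y == 0) 0 else oracle_ac_lower(x, y - 1, r))
    1 - 2 * min(lo, hi)
  }
  d <- (one_dir(ca, cb, lb / la) + one_dir(cb, ca, la / lb)) / 2
  min(1, max(0, d))
}

# Mean methylation by direct site scan.
oracle_region_mean <- function(region, records, min_sites = 3) {
  lv <- records$level[records$chrom == region$chrom &
                        records$pos >= region$start &
                        records$pos < region$end]
  if (length(lv) < min_sites) NA_real_ else mean(lv)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 500) {
  start <- floor(runif(n, 0, max_pos - max_len))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + ceiling(runif(n, 1, max_len)),
             stringsAsFactors = FALSE)
}

# Modify simulation-config fields while keeping the class and validation.
within_cfg <- function(cfg, ...) {
  mods <- list(...)
  cfg[names(mods)] <- mods
  do.call(gahd_sim_config, unclass(cfg))
}

# Decorate random intervals with the columns a peak data frame carries.
empty_peaks_like <- function(df) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$name <- sprintf("p%04d", seq_len(nrow(df)))
  df$summit <- (df$start + df$end) / 2
  df$raw_density <- runif(nrow(df), 10, 1000)
  df$pvalue <- runif(nrow(df), 0, 1e-3)
  rownames(df) <- NULL
  df
}

# Small deterministic annotation helper for profile tests.
tiny_genes <- function(df) {
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tts <- ifelse(df$strand == "+", df$end, df$start)
  df
}
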