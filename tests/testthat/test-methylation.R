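meth_records <- function(pos, level, chrom = "chr1", coverage = NA_real_) {
  data.frame(chrom = chrom, pos = pos, level = level, coverage = coverage,
             stringsAsFactors = FALSE)
}

test_that("region mean methylation is the unweighted site mean with a min_sites guard", {
  recs <- meth_records(c(10, 20, 30), c(0.2, 0.4, 0.6))
  region <- genomic_intervals("chr1", 0, 100)
  expect_equal(region_mean_methylation(region, recs)$mean_cg, 0.4)
  expect_true(is.na(region_mean_methylation(region, recs[1:2, ])$mean_cg))
  # half-open: site at pos == end excluded
  r2 <- genomic_intervals("chr1", 10, 30)
  expect_equal(region_mean_methylation(r2, recs, min_sites = 2)$mean_cg, 0.3)
  expect_equal(region_mean_methylation(r2, recs, min_sites = 2)$n_sites, 2L)
})

test_that("region means match a brute-force site scan on 1000 random regions", {
  set.seed(21)
  recs <- meth_records(sort(sample(0:5e4, 3000)), runif(3000))
  recs2 <- meth_records(sort(sample(0:5e4, 1500)), runif(1500), chrom = "chr2")
  recs <- rbind(recs, recs2)
  regions <- random_intervals(1000, max_pos = 5e4, max_len = 600)
  got <- region_mean_methylation(regions, recs)$mean_cg
  want <- vapply(seq_len(nrow(regions)), function(i)
    oracle_region_mean(regions[i, ], recs), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("classification is strict at 0.5 and exhaustive", {
  regions <- genomic_intervals("chr1", c(0, 100, 200), c(100, 200, 300))
  recs <- meth_records(c(10, 20, 30, 110, 120, 130, 210),
                       c(0.5, 0.5, 0.5, 0.9, 0.8, 0.7, 0.4))
  cls <- classify_regions(regions, recs)
  expect_equal(cls$labels, c("hypo", "hyper", "no_data"))
  expect_equal(sum(cls$counts), 3)
  # invariance to record and region order
  perm <- sample(nrow(recs))
  cls2 <- classify_regions(regions[3:1, ], recs[perm, ])
  expect_equal(cls2$labels, rev(cls$labels))
  expect_equal(cls2$counts, cls$counts)
})

test_that("the printed hyper/hypo tallies give the headline percentages", {
  fr <- methylation_fraction(550, 5972)
  expect_equal(fr$percent_headline, 8)
  expect_equal(fr$percent, 8.43)
  fr2 <- methylation_fraction(684, 123)
  expect_equal(fr2$percent, 84.76)
  expect_error(methylation_fraction(0, 0), "no classified")
})

test_that("genome segmentation merges same-label windows and breaks on no_data", {
  sizes <- c(chr1 = 1e5, chr2 = 4e4)
  pos <- seq(0, 1e5 - 1, by = 100)
  recs <- rbind(meth_records(pos, rep(0.8, length(pos))),
                meth_records(seq(0, 4e4 - 1, 100), rep(0.8, 400),
                             chrom = "chr2"))
  ar <- segment_genome_areas(recs, sizes)
  expect_equal(nrow(ar), 2L)           # one hyper area per chromosome
  expect_equal(ar$label, c("hyper", "hyper"))

  # alternating 10-kb windows of 0.8 and 0.1 stay separate areas
  lev <- ifelse((pos %/% 1e4) %% 2 == 0, 0.8, 0.1)
  ar2 <- segment_genome_areas(meth_records(pos, lev), c(chr1 = 1e5))
  expect_equal(nrow(ar2), 10L)
  expect_equal(unique(rle(ar2$label)$lengths), 1L)

  # a CpG-free window splits an otherwise uniform area
  keep <- pos < 3e4 | pos >= 4e4
  ar3 <- segment_genome_areas(meth_records(pos[keep], rep(0.8, sum(keep))),
                              c(chr1 = 1e5))
  expect_equal(sum(ar3$label == "hyper"), 2L)
})

test_that("planted methylation domains are recovered as areas at the planted ratio", {
  cfg <- gahd_sim_config(seed = 3)
  genome <- simulate_genome(cfg)
  meth <- simulate_methylation(cfg, genome)
  ar <- segment_genome_areas(meth$records, genome$chrom_sizes)
  counts <- attr(ar, "counts")
  expect_lte(abs(counts[["hyper"]] - 684), 684 * 0.02)
  expect_lte(abs(counts[["hypo"]] - 123), ceiling(123 * 0.02))
  fr <- methylation_fraction(counts[["hyper"]], counts[["hypo"]])
  expect_equal(fr$percent, 84.76, tolerance = 0.02)
})

test_that("region labels match planted domain truth almost always", {
  cfg <- gahd_sim_config(seed = 1)
  genome <- simulate_genome(cfg)
  gahd_sim <- simulate_gahd_tracks(cfg, genome)
  meth <- simulate_methylation(cfg, genome,
                               regions = gahd_sim$truth$pa200_dependent_regions)
  cls <- classify_regions(meth$region_truth, meth$records)
  agree <- mean(cls$labels == meth$region_truth$label)
  expect_gte(agree, 0.99)
})

test_that("DMR calling: identical inputs give none; boundary windows are called", {
  set.seed(31)
  pos <- seq(0, 2e4 - 1, by = 100)
  a <- meth_records(pos, runif(length(pos), 0.1, 0.3))
  expect_equal(nrow(call_dmrs(a, a, c(chr1 = 2e4))), 0L)

  # one window shifted by exactly min_diff with zero variance: called
  a2 <- meth_records(seq(0, 999, 20), rep(0.3, 50))
  b2 <- a2
  b2$level <- 0.5
  dm <- call_dmrs(a2, b2, c(chr1 = 1000), min_diff = 0.2)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$direction, "hyper")
  # the same shift below min_diff is not called
  b3 <- a2; b3$level <- 0.45
  expect_equal(nrow(call_dmrs(a2, b3, c(chr1 = 1000), min_diff = 0.2)), 0L)
})

test_that("planted DMRs are recovered with high precision and recall", {
  set.seed(5)
  n_win <- 100
  pos <- seq(0, n_win * 1000 - 1, by = 100)
  base <- runif(length(pos), 0.1, 0.25)
  a <- meth_records(pos, base)
  b <- a
  planted <- sort(sample(n_win, 12))
  in_planted <- (pos %/% 1000) %in% (planted - 1)
  b$level <- pmin(1, base + ifelse(in_planted, 0.5, 0))
  dm <- call_dmrs(a, b, c(chr1 = n_win * 1000))
  truth <- genomic_intervals("chr1", (planted - 1) * 1000, planted * 1000)
  truth_m <- merge_intervals(truth)
  hit_truth <- overlaps_any(truth_m, dm)
  hit_called <- overlaps_any(dm, truth_m)
  expect_gte(mean(hit_truth), 0.9)    # recall on merged planted runs
  expect_gte(mean(hit_called), 0.9)   # precision
  expect_true(all(dm$direction == "hyper"))
})
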