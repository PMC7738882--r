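test_that("the generator is deterministic under a fixed seed", {
  cfg <- gahd_sim_config(n_chroms = 1, chrom_length = 1e6, n_genes = 20,
                         n_degraded_wt = 6, n_shared_degraded = 2,
                         n_stable_peaks = 12, n_hyper_areas = 20,
                         n_hypo_areas = 5, seed = 11)
  s1 <- simulate_gahd_study(cfg)
  s2 <- simulate_gahd_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$tracks$wt_0h$values, s2$tracks$wt_0h$values)
  expect_identical(s1$marks$k4_ko$values, s2$marks$k4_ko$values)
  expect_identical(s1$methylation$records, s2$methylation$records)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_gahd_study(within_cfg(cfg, seed = 12))
  expect_false(identical(s1$tracks$wt_0h$values, s3$tracks$wt_0h$values))
})

test_that("gene packing is non-overlapping and respects edge cases", {
  cfg <- gahd_sim_config(n_genes = 0L)
  expect_equal(nrow(simulate_genome(cfg)$genes), 0L)

  cfg <- gahd_sim_config(n_genes = 200L)
  genes <- simulate_genome(cfg)$genes
  expect_equal(nrow(genes), 200L)
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_true(all(genes$end <= cfg$chrom_length))
  # infeasible packing errors
  tiny <- gahd_sim_config(n_chroms = 1, chrom_length = 5e4, n_genes = 50)
  expect_error(simulate_genome(tiny), "fit")
})

test_that("planted degraded regions lose the configured signal fraction at 4 h", {
  cfg <- gahd_sim_config(seed = 1)
  genome <- simulate_genome(cfg)
  sim <- simulate_gahd_tracks(cfg, genome)
  tr <- sim$truth$degraded_regions_wt
  c0 <- track_sums(sim$tracks$wt_0h, tr$chrom, tr$start, tr$end)
  c4 <- track_sums(sim$tracks$wt_4h, tr$chrom, tr$start, tr$end)
  ratios <- c4 / c0
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - cfg$degraded_fraction_retained_4h_wt), 3 * se)
  # knockout retains most signal at PA200-dependent regions
  pa <- sim$truth$pa200_dependent_regions
  k0 <- track_sums(sim$tracks$ko_0h, pa$chrom, pa$start, pa$end)
  k4 <- track_sums(sim$tracks$ko_4h, pa$chrom, pa$start, pa$end)
  kr <- k4 / k0
  kse <- sd(kr) / sqrt(length(kr))
  expect_lt(abs(mean(kr) - cfg$degraded_fraction_retained_4h_ko), 3 * kse)
  # truth structure: PA200-dependent = WT-planted minus KO-degrading
  expect_equal(nrow(pa) + nrow(sim$truth$degraded_regions_ko), nrow(tr))
  expect_true(all(overlaps_any(pa, tr)))
})

test_that("a null simulation with no enrichment yields ~no degraded regions", {
  cfg <- gahd_sim_config(n_chroms = 1, chrom_length = 4e6, n_genes = 40,
                         peak_enrichment = 1, tss_peak_factor = 1,
                         tss_accumulation_factor_ko_4h = 1,
                         chase_background_factor = 1,
                         degraded_fraction_retained_4h_wt = 1,
                         degraded_fraction_retained_4h_ko = 1, seed = 2)
  genome <- simulate_genome(cfg)
  sim <- simulate_gahd_tracks(cfg, genome)
  p0 <- call_peaks(sim$tracks$wt_0h)
  p4 <- call_peaks(sim$tracks$wt_4h)
  out <- if (nrow(p0) == 0) empty_degradation("WT") else
    call_degraded_regions(p0, p4, NULL)
  expect_lte(nrow(out), 2L)
})

test_that("mark tracks couple knockout changes to the planted gene classes", {
  cfg <- gahd_sim_config(seed = 6, n_chroms = 1, chrom_length = 4e6,
                         n_genes = 60, n_deg_up = 15, n_deg_down = 15)
  genome <- simulate_genome(cfg)
  classes <- plant_deg_classes(cfg, genome)
  marks <- simulate_mark_tracks(cfg, genome, classes)
  g <- genome$genes
  ratio <- function(trk_ko, trk_wt)
    track_sums(marks[[trk_ko]], g$chrom, g$start, g$end) /
    track_sums(marks[[trk_wt]], g$chrom, g$start, g$end)
  r56 <- ratio("k56_ko", "k56_wt")
  names(r56) <- g$gene_id
  other <- setdiff(g$gene_id, c(classes$deg_up_ids, classes$deg_down_ids))
  expect_gt(mean(r56[classes$deg_up_ids]), mean(r56[other]))
  expect_lt(mean(r56[classes$deg_down_ids]), mean(r56[other]))
  # no planted classes: all ratios ~1
  marks0 <- simulate_mark_tracks(cfg, genome,
                                 list(deg_up_ids = character(0),
                                      deg_down_ids = character(0)))
  r0 <- track_sums(marks0$k4_ko, g$chrom, g$start, g$end) /
    track_sums(marks0$k4_wt, g$chrom, g$start, g$end)
  expect_lt(max(abs(r0 - 1)), 0.25)
})

test_that("the hyper-exception fraction controls planted region methylation", {
  base <- gahd_sim_config(seed = 9, n_chroms = 1, chrom_length = 4e6,
                          n_genes = 20, n_degraded_wt = 20,
                          n_shared_degraded = 5, n_hyper_areas = 60,
                          n_hypo_areas = 20)
  genome <- simulate_genome(base)
  sim <- simulate_gahd_tracks(base, genome)
  regions <- sim$truth$degraded_regions_wt
  for (frac in c(0, 1)) {
    cfg <- within_cfg(base, hyper_exception_fraction = frac)
    meth <- simulate_methylation(cfg, genome, regions)
    cls <- classify_regions(regions, meth$records)
    hyper_frac <- cls$counts[["hyper"]] /
      (cls$counts[["hyper"]] + cls$counts[["hypo"]])
    expect_equal(unname(hyper_frac), frac)
  }
})

test_that("the planted hyper fraction matches the binomial expectation at scale", {
  # 6522 spaced regions so each lands in its own window
  cfg <- gahd_sim_config(n_chroms = 2, chrom_length = 50e6, seed = 1)
  chrom_sizes <- c(chr1 = 50e6, chr2 = 50e6)
  genome <- list(chrom_sizes = chrom_sizes,
                 genes = simulate_genome(within_cfg(cfg, n_genes = 0L))$genes)
  k <- 3261
  regions <- rbind(
    data.frame(chrom = "chr1", start = (seq_len(k) - 1) * 15000 + 2000,
               end = (seq_len(k) - 1) * 15000 + 6000),
    data.frame(chrom = "chr2", start = (seq_len(k) - 1) * 15000 + 2000,
               end = (seq_len(k) - 1) * 15000 + 6000))
  meth <- simulate_methylation(cfg, genome, regions)
  cls <- classify_regions(regions, meth$records)
  hyper_frac <- cls$counts[["hyper"]] / sum(cls$counts[c("hyper", "hypo")])
  ci <- 1.96 * sqrt(0.08 * 0.92 / 6522)
  expect_lt(abs(hyper_frac - 0.08), ci)
})

test_that("count simulation library sizes stay within 2x of each other", {
  for (s in 1:5) {
    cfg <- gahd_sim_config(seed = s)
    genome <- simulate_genome(cfg)
    classes <- plant_deg_classes(cfg, genome)
    tab <- simulate_counts(cfg, genome, classes)
    expect_lt(max(tab$lib_a, tab$lib_b) / min(tab$lib_a, tab$lib_b), 2)
  }
})
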