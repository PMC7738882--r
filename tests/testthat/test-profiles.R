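const_track <- function(v, nbins = 2000, bs = 50)
  signal_track(list(chr1 = rep(v, nbins)), bin_size = bs)

two_genes <- function() tiny_genes(data.frame(
  chrom = "chr1", start = c(30000, 60000), end = c(42000, 71000),
  gene_id = c("gA", "gB"), strand = c("+", "-"),
  stringsAsFactors = FALSE))

test_that("a constant track gives a constant metagene matrix", {
  tr <- const_track(7)
  pm <- metagene_matrix(tr, two_genes(), flank = 3000, flank_bin = 300,
                        rpm = FALSE)
  expect_equal(dim(pm), c(2L, 10 + 100 + 10))
  expect_true(all(abs(pm - 7) < 1e-9))
  expect_equal(unname(column_summary(pm)), rep(7, 120))
})

test_that("minus-strand genes are flipped so column 1 is biologically upstream", {
  tr <- const_track(0)
  # delta signal in the first 500 bp downstream of each TSS
  tr$values$chr1[(30000 / 50 + 1):(30500 / 50)] <- 10     # gA (+): TSS 30000
  tr$values$chr1[(70500 / 50 + 1):(71000 / 50)] <- 10     # gB (-): TSS 71000
  pm <- metagene_matrix(tr, two_genes(), flank = 3000, flank_bin = 300,
                        rpm = FALSE)
  first_body <- 10 + 1
  expect_gt(pm["gA", first_body], 0)
  expect_gt(pm["gB", first_body], 0)
  expect_equal(unname(pm["gA", first_body]), unname(pm["gB", first_body]),
               tolerance = 0.2)
  # no signal on the downstream-most columns
  expect_lt(max(pm[, 115:120]), 1e-9)
})

test_that("metagene cells match a per-base averaging oracle on random genes", {
  set.seed(44)
  tr <- signal_track(list(chr1 = runif(2000, 0, 20)), bin_size = 50)
  genes <- tiny_genes(data.frame(
    chrom = "chr1",
    start = s <- sort(sample(5000:60000, 50)),
    end = s + sample(500:4000, 50, replace = TRUE),
    gene_id = sprintf("g%02d", 1:50),
    strand = sample(c("+", "-"), 50, replace = TRUE),
    stringsAsFactors = FALSE))
  nb <- 20
  pm <- metagene_matrix(tr, genes, flank = 1500, n_body_bins = nb,
                        flank_bin = 300, rpm = FALSE)
  for (i in sample(nrow(genes), 10)) {
    g <- genes[i, ]
    up <- seq(g$start - 1500, g$start, by = 300)
    body <- seq(g$start, g$end, length.out = nb + 1)
    down <- seq(g$end, g$end + 1500, by = 300)
    bounds <- c(up, body[-1], down[-1])
    want <- vapply(seq_len(length(bounds) - 1), function(k)
      oracle_track_mean(tr$values$chr1, 50, bounds[k], bounds[k + 1]),
      numeric(1))
    if (g$strand == "-") want <- rev(want)
    expect_equal(unname(pm[g$gene_id, ]), want, tolerance = 1e-9)
  }
})

test_that("out-of-chromosome flank bins are NA and excluded from summaries", {
  tr <- const_track(3, nbins = 100)           # 5 kb chromosome
  genes <- tiny_genes(data.frame(chrom = "chr1", start = 1000, end = 3000,
                                 gene_id = "g1", strand = "+",
                                 stringsAsFactors = FALSE))
  pm <- metagene_matrix(tr, genes, flank = 3000, flank_bin = 300, rpm = FALSE)
  expect_true(all(is.na(pm[1, 1:6])))         # flank reaches below 0
  expect_equal(unname(column_summary(pm)[7]), 3)
})

test_that("genes shorter than the body bin count are skipped with a warning", {
  tr <- const_track(1)
  genes <- tiny_genes(data.frame(chrom = "chr1", start = c(1000, 5000),
                                 end = c(1050, 15000),
                                 gene_id = c("tiny", "ok"), strand = "+",
                                 stringsAsFactors = FALSE))
  expect_warning(pm <- metagene_matrix(tr, genes, flank = 300,
                                       n_body_bins = 100, rpm = FALSE),
                 "skipped")
  expect_equal(rownames(pm), "ok")
  expect_equal(attr(pm, "n_skipped"), 1L)
})

test_that("profiles are invariant to gene order and scale linearly with the track", {
  set.seed(45)
  tr <- signal_track(list(chr1 = rpois(2000, 8)), bin_size = 50)
  genes <- two_genes()
  pm1 <- metagene_matrix(tr, genes, flank = 3000, flank_bin = 300,
                         rpm = FALSE)
  pm2 <- metagene_matrix(tr, genes[2:1, ], flank = 3000, flank_bin = 300,
                         rpm = FALSE)
  expect_equal(pm1[rownames(pm2), ], unclass(pm2)[, ], ignore_attr = TRUE)
  pm3 <- metagene_matrix(track_scale(tr, 3), genes, flank = 3000,
                         flank_bin = 300, rpm = FALSE)
  expect_equal(unclass(pm3)[, ], 3 * unclass(pm1)[, ], tolerance = 1e-12)
  # with depth normalization, scaling has no effect at all
  pm4 <- metagene_matrix(tr, genes, flank = 3000, flank_bin = 300)
  pm5 <- metagene_matrix(track_scale(tr, 3), genes, flank = 3000,
                         flank_bin = 300)
  expect_equal(unclass(pm4)[, ], unclass(pm5)[, ], tolerance = 1e-12)
})

test_that("coordinate reversal with strand flip leaves profiles unchanged", {
  set.seed(46)
  L <- 2000 * 50
  v <- rpois(2000, 6)
  tr_f <- signal_track(list(chr1 = v), bin_size = 50)
  tr_r <- signal_track(list(chr1 = rev(v)), bin_size = 50)
  genes <- two_genes()
  genes_r <- genes
  genes_r$start <- L - genes$end
  genes_r$end <- L - genes$start
  genes_r$strand <- ifelse(genes$strand == "+", "-", "+")
  genes_r <- tiny_genes(genes_r)
  pm_f <- metagene_matrix(tr_f, genes, flank = 3000, flank_bin = 300,
                          rpm = FALSE)
  pm_r <- metagene_matrix(tr_r, genes_r, flank = 3000, flank_bin = 300,
                          rpm = FALSE)
  expect_equal(unclass(pm_f)[, ], unclass(pm_r)[, ], tolerance = 1e-9)
})

test_that("ratio profiles recover planted fold changes and trivial identities", {
  tr <- const_track(5)
  genes <- two_genes()
  pm <- metagene_matrix(tr, genes, flank = 3000, flank_bin = 300, rpm = FALSE)
  expect_equal(unname(ratio_profile(pm, pm)), rep(0, ncol(pm)))
  pm2x <- metagene_matrix(track_scale(tr, 2), genes, flank = 3000,
                          flank_bin = 300, rpm = FALSE)
  r <- ratio_profile(pm2x, pm, pseudocount = 1e-4)
  expect_equal(unname(r), rep(1, ncol(pm)), tolerance = 1e-3)
  # double normalization: equal H3 leaves the mark ratio untouched
  r2 <- ratio_profile(pm2x, pm, pm, pm, pseudocount = 1e-4)
  expect_equal(unname(r2), rep(1, ncol(pm)), tolerance = 1e-2)
  expect_error(ratio_profile(pm[, 1:10], pm), "geometry")
})

test_that("planted up/down mark classes separate in gene-body ratio profiles", {
  cfg <- gahd_sim_config(seed = 4, n_chroms = 1, chrom_length = 4e6,
                         n_genes = 60, n_deg_up = 15, n_deg_down = 15)
  genome <- simulate_genome(cfg)
  classes <- plant_deg_classes(cfg, genome)
  marks <- simulate_mark_tracks(cfg, genome, classes)
  sel <- function(ids) genome$genes[genome$genes$gene_id %in% ids, ]
  body_cols <- 10 + seq_len(100)
  prof <- function(ids, trk) {
    m <- metagene_matrix(marks[[trk]], sel(ids), flank = 3000,
                         flank_bin = 300)
    m
  }
  up_r <- ratio_profile(prof(classes$deg_up_ids, "k56_ko"),
                        prof(classes$deg_up_ids, "k56_wt"),
                        prof(classes$deg_up_ids, "h3_ko"),
                        prof(classes$deg_up_ids, "h3_wt"))
  down_r <- ratio_profile(prof(classes$deg_down_ids, "k56_ko"),
                          prof(classes$deg_down_ids, "k56_wt"),
                          prof(classes$deg_down_ids, "h3_ko"),
                          prof(classes$deg_down_ids, "h3_wt"))
  expect_gt(mean(up_r[body_cols]), 0)
  expect_lt(mean(down_r[body_cols]), 0)
  # mean KO/WT H3K56ac ratio over up genes exceeds that over down genes
  expect_gt(mean(up_r[body_cols]), mean(down_r[body_cols]))
})

test_that("TSS windows are strand-oriented and match brute-force means", {
  set.seed(47)
  tr <- signal_track(list(chr1 = runif(2000, 0, 10)), bin_size = 50)
  genes <- two_genes()
  ts <- tss_signal(tr, genes, half_width = 1000, bin = 50, rpm = FALSE)
  expect_equal(dim(ts$matrix), c(2L, 40L))
  for (i in 1:2) {
    g <- genes[i, ]
    want <- oracle_track_mean(tr$values$chr1, 50, g$tss - 1000, g$tss + 1000)
    expect_equal(unname(ts$promoter_mean[g$gene_id]), want, tolerance = 1e-9)
    bounds <- seq(g$tss - 1000, g$tss + 1000, by = 50)
    cells <- vapply(seq_len(40), function(k)
      oracle_track_mean(tr$values$chr1, 50, bounds[k], bounds[k + 1]),
      numeric(1))
    if (g$strand == "-") cells <- rev(cells)
    expect_equal(unname(ts$matrix[g$gene_id, ]), cells, tolerance = 1e-9)
  }
  # delta signal at the TSS lands in a centre bin for either strand
  tr0 <- const_track(0)
  tr0$values$chr1[30000 / 50 + 1] <- 100      # gA TSS bin
  ts0 <- tss_signal(tr0, genes[1, ], half_width = 1000, bin = 50,
                    rpm = FALSE)
  expect_equal(unname(which(ts0$matrix[1, ] > 0)), 21L)
})
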