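#' Simulation configuration for the synthetic GAHD study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' define the study conditions used throughout the package's validation:
#' a 2 x 10 Mb genome with 200 genes, 60 planted wild-type degraded regions
#' of which 40 are PA200-dependent (the remaining 20 also degrade in the
#' knockout), pulse-chase coverage with a TSS-proximal deposition peak,
#' histone-mark and Pol II tracks coupled to planted up-/down-regulated
#' gene classes, bimodal CpG methylation domains, and a two-condition count
#' table with planted 4-fold changes.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length_range Min/max gene length in bp.
#' @param n_degraded_wt Planted regions degraded in the wild type.
#' @param n_shared_degraded How many of those also degrade in the knockout
#'   (the rest are PA200-dependent truth).
#' @param n_stable_peaks Enriched regions present at both chase times (the
#'   common-peak backbone for normalization).
#' @param region_length_range Min/max planted region length in bp.
#' @param background_rate Background reads per bin.
#' @param peak_enrichment Fold enrichment of planted regions over background.
#' @param degraded_fraction_retained_4h_wt Fraction of 0 h signal a
#'   degraded region retains at 4 h in the wild type (default 0.2).
#' @param degraded_fraction_retained_4h_ko Same for non-degrading regions in
#'   the knockout (default 0.85).
#' @param tss_accumulation_factor_ko_4h Extra multiplier on knockout 4 h
#'   signal within `tss_halfwidth` of every TSS (default 1.5).
#' @param tss_halfwidth Half-width of the TSS window in bp (default 500).
#' @param tss_peak_factor TSS-proximal deposition enrichment at 0 h
#'   (default 3): newly deposited histones concentrate at starts of genes.
#' @param ko_scale Global knockout 0 h signal scale relative to wild type
#'   (default 0.7): overall labeled-histone enrichment is lower without
#'   PA200.
#' @param chase_background_factor Global 4 h / 0 h background ratio shared
#'   by both genotypes (default 0.8).
#' @param bin_size Track bin width in bp (default 50).
#' @param n_deg_up,n_deg_down Planted up-/down-regulated genes.
#' @param deg_log2fc Planted absolute log2 fold change (default 2).
#' @param dispersion Negative-binomial dispersion of gene counts
#'   (default 0.01, technical-replicate scale noise matching a
#'   one-library-per-condition design).
#' @param count_base_meanlog,count_base_sdlog Log-normal parameters of
#'   baseline gene expression means.
#' @param mark_fold_up,mark_fold_down Knockout/wild-type mark (and Pol II)
#'   fold over up-/down-regulated genes (defaults 2 and 0.5).
#' @param n_hyper_areas,n_hypo_areas Planted methylation domains genome-wide
#'   (defaults 684 and 123).
#' @param area_window Window width for domain planting and area segmentation
#'   (default 10000).
#' @param methyl_hyper_level,methyl_hypo_level Mean CpG level in hyper/hypo
#'   domains (defaults 0.8 and 0.15).
#' @param methyl_concentration Beta concentration of per-site levels
#'   (default 10).
#' @param cpg_spacing Distance between simulated CpG sites in bp
#'   (default 100).
#' @param hyper_exception_fraction Fraction of planted degradation regions
#'   placed in hyper-methylated domains (default 0.08).
#' @param n_replicates Tracks simulated per condition (default 1, matching
#'   single-library sequencing designs).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list of class `gahd_sim_config`.
#' @export
gahd_sim_config <- function(n_chroms = 2L, chrom_length = 10e6,
                            n_genes = 200L,
                            gene_length_range = c(5000, 20000),
                            n_degraded_wt = 60L, n_shared_degraded = 20L,
                            n_stable_peaks = 150L,
                            region_length_range = c(2000, 4000),
                            background_rate = 10,
                            peak_enrichment = 8,
                            degraded_fraction_retained_4h_wt = 0.2,
                            degraded_fraction_retained_4h_ko = 0.85,
                            tss_accumulation_factor_ko_4h = 1.5,
                            tss_halfwidth = 500L,
                            tss_peak_factor = 3,
                            ko_scale = 0.7,
                            chase_background_factor = 0.8,
                            bin_size = 50L,
                            n_deg_up = 30L, n_deg_down = 30L,
                            deg_log2fc = 2,
                            dispersion = 0.01,
                            count_base_meanlog = log(200),
                            count_base_sdlog = 1,
                            mark_fold_up = 2, mark_fold_down = 0.5,
                            n_hyper_areas = 684L, n_hypo_areas = 123L,
                            area_window = 10000L,
                            methyl_hyper_level = 0.8,
                            methyl_hypo_level = 0.15,
                            methyl_concentration = 10,
                            cpg_spacing = 100L,
                            hyper_exception_fraction = 0.08,
                            n_replicates = 1L,
                            seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0,
              degraded_fraction_retained_4h_wt >= 0,
              degraded_fraction_retained_4h_wt <= 1,
              degraded_fraction_retained_4h_ko >= 0,
              degraded_fraction_retained_4h_ko <= 1,
              hyper_exception_fraction >= 0, hyper_exception_fraction <= 1,
              tss_accumulation_factor_ko_4h > 0, ko_scale > 0,
              peak_enrichment > 0, background_rate > 0,
              n_shared_degraded <= n_degraded_wt,
              dispersion >= 0, n_replicates >= 1)
  })
  structure(cfg, class = "gahd_sim_config")
}

# Fixed per-stage seed offsets: all randomness derives from config$seed.
seed_offsets <- c(genome = 0L, deg_classes = 101L, gahd = 202L,
                  marks = 303L, methylation = 404L, counts = 505L)

stage_seed <- function(config, stage) {
  set.seed((config$seed + seed_offsets[[stage]]) %% .Machine$integer.max)
}

sim_chrom_sizes <- function(config) {
  stats::setNames(rep(config$chrom_length, config$n_chroms),
                  sprintf("chr%d", seq_len(config$n_chroms)))
}

#' Simulate a genome annotation with non-overlapping genes
#'
#' Genes are packed without overlap by stick-breaking the free space per
#' chromosome; strands are random. Deterministic under the config seed.
#'
#' @param config A [gahd_sim_config()].
#' @return List with `chrom_sizes` (named vector) and `genes` (annotation
#'   data frame as from [read_gene_annotation()]).
#' @export
simulate_genome <- function(config) {
  stage_seed(config, "genome")
  chrom_sizes <- sim_chrom_sizes(config)
  if (config$n_genes == 0L)
    return(list(chrom_sizes = chrom_sizes,
                genes = add_tss_tts(data.frame(chrom = character(),
                                               start = numeric(),
                                               end = numeric(),
                                               gene_id = character(),
                                               strand = character(),
                                               stringsAsFactors = FALSE))))
  per_chrom <- table(factor(rep_len(names(chrom_sizes), config$n_genes),
                            levels = names(chrom_sizes)))
  genes <- list()
  gid <- 0L
  for (ch in names(chrom_sizes)) {
    k <- as.integer(per_chrom[[ch]])
    if (k == 0L) next
    len <- round(stats::runif(k, config$gene_length_range[1],
                              config$gene_length_range[2]))
    free <- chrom_sizes[[ch]] - sum(len)
    if (free < 0)
      stop("simulate_genome: genes do not fit on ", ch)
    gaps <- floor(free * diff(c(0, sort(stats::runif(k)))))
    starts <- cumsum(gaps) + cumsum(c(0, len[-k]))
    gid_range <- gid + seq_len(k)
    genes[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = starts + len,
                              gene_id = sprintf("gene_%04d", gid_range),
                              strand = sample(c("+", "-"), k, replace = TRUE),
                              stringsAsFactors = FALSE)
    gid <- gid + k
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  list(chrom_sizes = chrom_sizes, genes = add_tss_tts(genes))
}

#' Assign planted up-/down-regulated gene classes
#'
#' @param config A [gahd_sim_config()].
#' @param genome Result of [simulate_genome()].
#' @return List with `deg_up_ids` and `deg_down_ids`.
#' @export
plant_deg_classes <- function(config, genome) {
  stage_seed(config, "deg_classes")
  ids <- sample(genome$genes$gene_id)
  n_up <- min(config$n_deg_up, length(ids))
  n_down <- min(config$n_deg_down, max(0L, length(ids) - n_up))
  list(deg_up_ids = sort(ids[seq_len(n_up)]),
       deg_down_ids = sort(ids[n_up + seq_len(n_down)]))
}

# Place n non-overlapping regions avoiding `avoid` intervals, by rejection
# sampling. Errors if the genome is too crowded.
place_regions <- function(n, len_range, chrom_sizes, avoid) {
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  tries <- 0L
  while (nrow(placed) < n) {
    if ((tries <- tries + 1L) > 200L * n)
      stop("place_regions: cannot pack ", n, " regions")
    ch <- sample(names(chrom_sizes), 1L)
    len <- round(stats::runif(1, len_range[1], len_range[2]))
    s <- floor(stats::runif(1, 0, chrom_sizes[[ch]] - len))
    cand <- data.frame(chrom = ch, start = s, end = s + len,
                       stringsAsFactors = FALSE)
    occupied <- rbind(avoid, placed[, c("chrom", "start", "end")])
    if (nrow(occupied) == 0L || !any(overlaps_any(cand, occupied)))
      placed <- rbind(placed, cand)
  }
  placed[order(placed$chrom, placed$start), , drop = FALSE]
}

# Multiply `field[[chrom]]` bins covered by each interval by `factor`.
apply_region_factor <- function(field, regions, bs, factor) {
  if (nrow(regions) == 0L) return(field)
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    b0 <- floor(regions$start[i] / bs) + 1L
    b1 <- min(ceiling(regions$end[i] / bs), length(field[[ch]]))
    field[[ch]][b0:b1] <- field[[ch]][b0:b1] * factor
  }
  field
}

poisson_track <- function(field, bs, chrom_sizes) {
  signal_track(lapply(field, function(mu) stats::rpois(length(mu), mu)),
               bs, chrom_sizes)
}

#' Simulate pulse-chase (GAHD) coverage tracks with planted degradation
#'
#' Produces four Poisson count tracks (WT 0 h, WT 4 h, KO 0 h, KO 4 h) over
#' the simulated genome. Planted regions (degraded + stable) are enriched
#' `peak_enrichment`-fold at 0 h in both genotypes; newly deposited histone
#' signal additionally peaks `tss_peak_factor`-fold within
#' `tss_halfwidth` of every TSS. At 4 h the background drops by
#' `chase_background_factor`, wild-type degraded regions retain
#' `degraded_fraction_retained_4h_wt` of their 0 h mean, knockout regions
#' retain the shared fraction where degradation is PA200-independent and
#' `degraded_fraction_retained_4h_ko` where it is not, and knockout 4 h
#' signal around TSSs is multiplied by `tss_accumulation_factor_ko_4h`.
#' The knockout 0 h field is globally scaled by `ko_scale`.
#'
#' @param config A [gahd_sim_config()].
#' @param genome Result of [simulate_genome()].
#' @return List with `tracks` (named list `wt_0h`, `wt_4h`, `ko_0h`,
#'   `ko_4h`) and `truth`: `degraded_regions_wt`, `degraded_regions_ko`,
#'   `pa200_dependent_regions`, `stable_regions`, `tss_windows`.
#' @export
simulate_gahd_tracks <- function(config, genome) {
  stage_seed(config, "gahd")
  bs <- config$bin_size
  chrom_sizes <- genome$chrom_sizes
  genes <- genome$genes
  tssw <- if (nrow(genes)) data.frame(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - config$tss_halfwidth - 1000),
    end = pmin(unname(chrom_sizes[genes$chrom]),
               genes$tss + config$tss_halfwidth + 1000),
    stringsAsFactors = FALSE)
  else data.frame(chrom = character(), start = numeric(), end = numeric())
  # plant regions away from TSS windows so the two effects never mix
  wt_regions <- place_regions(config$n_degraded_wt,
                              config$region_length_range, chrom_sizes, tssw)
  stable <- place_regions(config$n_stable_peaks, config$region_length_range,
                          chrom_sizes, rbind(tssw, wt_regions))
  shared_idx <- sort(sample(nrow(wt_regions),
                            min(config$n_shared_degraded, nrow(wt_regions))))
  shared <- wt_regions[shared_idx, , drop = FALSE]
  pa200 <- wt_regions[setdiff(seq_len(nrow(wt_regions)), shared_idx), ,
                      drop = FALSE]
  tss_core <- if (nrow(genes)) data.frame(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - config$tss_halfwidth),
    end = pmin(unname(chrom_sizes[genes$chrom]),
               genes$tss + config$tss_halfwidth),
    stringsAsFactors = FALSE)
  else tssw

  base0 <- lapply(chrom_sizes, function(sz)
    rep(config$background_rate, ceiling(sz / bs)))
  names(base0) <- names(chrom_sizes)
  base0 <- apply_region_factor(base0, wt_regions, bs, config$peak_enrichment)
  base0 <- apply_region_factor(base0, stable, bs, config$peak_enrichment)
  base0 <- apply_region_factor(base0, tss_core, bs, config$tss_peak_factor)

  field_4h <- function(base, retained_deg, retained_nondeg) {
    f <- lapply(base, function(mu) mu * config$chase_background_factor)
    names(f) <- names(base)
    # degraded/retained regions: set to the configured fraction of 0 h mean
    reset <- function(f, regions, frac) {
      for (i in seq_len(nrow(regions))) {
        ch <- regions$chrom[i]
        b0 <- floor(regions$start[i] / bs) + 1L
        b1 <- min(ceiling(regions$end[i] / bs), length(f[[ch]]))
        f[[ch]][b0:b1] <- base[[ch]][b0:b1] * frac
      }
      f
    }
    f <- reset(f, retained_deg$regions, retained_deg$frac)
    if (!is.null(retained_nondeg))
      f <- reset(f, retained_nondeg$regions, retained_nondeg$frac)
    f
  }

  wt0 <- base0
  wt4 <- field_4h(wt0, list(regions = wt_regions,
                            frac = config$degraded_fraction_retained_4h_wt),
                  NULL)
  ko0 <- lapply(base0, function(mu) mu * config$ko_scale)
  names(ko0) <- names(base0)
  ko4 <- field_4h(ko0, list(regions = shared,
                            frac = config$degraded_fraction_retained_4h_wt),
                  list(regions = pa200,
                       frac = config$degraded_fraction_retained_4h_ko))
  ko4 <- apply_region_factor(ko4, tss_core, bs,
                             config$tss_accumulation_factor_ko_4h)

  tracks <- list(wt_0h = poisson_track(wt0, bs, chrom_sizes),
                 wt_4h = poisson_track(wt4, bs, chrom_sizes),
                 ko_0h = poisson_track(ko0, bs, chrom_sizes),
                 ko_4h = poisson_track(ko4, bs, chrom_sizes))
  list(tracks = tracks,
       truth = list(degraded_regions_wt = wt_regions,
                    degraded_regions_ko = shared,
                    pa200_dependent_regions = pa200,
                    stable_regions = stable,
                    tss_windows = tss_core))
}

#' Simulate histone-mark and Pol II tracks coupled to DEG classes
#'
#' H3 is approximately uniform over gene bodies; H3K4me3, H3K56ac and
#' Pol II are enriched over gene bodies and promoters, and their knockout
#' level over a gene is multiplied by `mark_fold_up` for planted up genes
#' and `mark_fold_down` for planted down genes, so knockout/wild-type mark
#' ratios separate the classes and co-vary with Pol II.
#'
#' @param config A [gahd_sim_config()].
#' @param genome Result of [simulate_genome()].
#' @param truth List containing `deg_up_ids` and `deg_down_ids` (see
#'   [plant_deg_classes()]).
#' @return Named list of [signal_track()]s: `h3_wt`, `h3_ko`, `k4_wt`,
#'   `k4_ko`, `k56_wt`, `k56_ko`, `polii_wt`, `polii_ko`.
#' @export
simulate_mark_tracks <- function(config, genome, truth) {
  stage_seed(config, "marks")
  bs <- config$bin_size
  chrom_sizes <- genome$chrom_sizes
  genes <- genome$genes
  gene_fold <- stats::setNames(rep(1, nrow(genes)), genes$gene_id)
  gene_fold[truth$deg_up_ids] <- config$mark_fold_up
  gene_fold[truth$deg_down_ids] <- config$mark_fold_down
  bodies <- data.frame(chrom = genes$chrom,
                       start = pmax(0, pmin(genes$start, genes$tss - 2500)),
                       end = pmin(unname(chrom_sizes[genes$chrom]),
                                  pmax(genes$end, genes$tss + 2500)),
                       stringsAsFactors = FALSE)
  flat <- function(level) {
    f <- lapply(chrom_sizes, function(sz) rep(level, ceiling(sz / bs)))
    names(f) <- names(chrom_sizes)
    f
  }
  gene_field <- function(bg, level, fold_by_gene) {
    f <- flat(bg)
    for (i in seq_len(nrow(genes))) {
      ch <- bodies$chrom[i]
      b0 <- floor(bodies$start[i] / bs) + 1L
      b1 <- min(ceiling(bodies$end[i] / bs), length(f[[ch]]))
      f[[ch]][b0:b1] <- level * fold_by_gene[[genes$gene_id[i]]]
    }
    f
  }
  ones <- stats::setNames(rep(1, nrow(genes)), genes$gene_id)
  fields <- list(
    h3_wt = gene_field(2, 20, ones),
    h3_ko = gene_field(2, 20, ones),
    k4_wt = gene_field(2, 15, ones),
    k4_ko = gene_field(2, 15, gene_fold),
    k56_wt = gene_field(2, 15, ones),
    k56_ko = gene_field(2, 15, gene_fold),
    polii_wt = gene_field(2, 12, ones),
    polii_ko = gene_field(2, 12, gene_fold))
  lapply(fields, poisson_track, bs = bs, chrom_sizes = chrom_sizes)
}

#' Simulate per-CpG methylation with planted hyper/hypo domains
#'
#' Plants `n_hyper_areas + n_hypo_areas` single-window methylation domains
#' separated by CpG-free gap windows (so each planted domain is recoverable
#' as one area). CpG sites sit every `cpg_spacing` bp inside domains, with
#' Beta-distributed levels of mean `methyl_hyper_level` or
#' `methyl_hypo_level`. When planted degradation `regions` are supplied,
#' every window they touch is converted to a domain whose label is drawn
#' hyper with probability `hyper_exception_fraction` (hypo otherwise),
#' emulating degradation that happens predominantly in open, hypo-methylated
#' chromatin.
#'
#' @param config A [gahd_sim_config()].
#' @param genome Result of [simulate_genome()].
#' @param regions Optional interval data frame of planted degradation
#'   regions.
#' @return List with `records` (methylation data frame), `hyper_domains`,
#'   `hypo_domains` (interval frames of planted truth) and `region_truth`
#'   (per-region planted label, `NULL` without `regions`).
#' @export
simulate_methylation <- function(config, genome, regions = NULL) {
  stage_seed(config, "methylation")
  w <- config$area_window
  chrom_sizes <- genome$chrom_sizes
  nwin <- vapply(chrom_sizes, function(sz) floor(sz / w), numeric(1))
  total_win <- sum(nwin)
  n_dom <- config$n_hyper_areas + config$n_hypo_areas
  if (2 * n_dom > total_win)
    stop("simulate_methylation: genome too small for ", n_dom, " domains")
  labels_pool <- sample(c(rep("hyper", config$n_hyper_areas),
                          rep("hypo", config$n_hypo_areas)))
  # window label vector per chromosome; "gap" = CpG-free
  win_labels <- lapply(nwin, function(n) rep("gap", n))
  di <- 1L
  for (ch in names(win_labels)) {
    slots <- seq(1L, nwin[[ch]], by = 2L)
    for (s in slots) {
      if (di > n_dom) break
      win_labels[[ch]][s] <- labels_pool[di]
      di <- di + 1L
    }
  }
  region_truth <- NULL
  if (!is.null(regions) && nrow(regions)) {
    lab <- ifelse(stats::runif(nrow(regions)) < config$hyper_exception_fraction,
                  "hyper", "hypo")
    region_truth <- data.frame(regions[, c("chrom", "start", "end")],
                               label = lab, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(regions))) {
      ch <- regions$chrom[i]
      w0 <- floor(regions$start[i] / w) + 1L
      w1 <- min(floor((regions$end[i] - 1) / w) + 1L,
                length(win_labels[[ch]]))
      win_labels[[ch]][w0:w1] <- lab[i]
    }
  }
  kappa <- config$methyl_concentration
  recs <- list()
  domains <- list()
  for (ch in names(win_labels)) {
    lab <- win_labels[[ch]]
    dom <- which(lab != "gap")
    if (!length(dom)) next
    pos <- unlist(lapply(dom, function(k)
      seq((k - 1) * w, k * w - 1, by = config$cpg_spacing)))
    m <- rep(ifelse(lab[dom] == "hyper", config$methyl_hyper_level,
                    config$methyl_hypo_level),
             each = w / config$cpg_spacing)
    level <- stats::rbeta(length(pos), m * kappa, (1 - m) * kappa)
    recs[[ch]] <- data.frame(chrom = ch, pos = pos, level = level,
                             coverage = NA_real_, stringsAsFactors = FALSE)
    r <- rle(lab)
    to <- cumsum(r$lengths); from <- to - r$lengths + 1L
    keep <- r$values != "gap"
    domains[[ch]] <- data.frame(chrom = ch, start = (from[keep] - 1) * w,
                                end = to[keep] * w, label = r$values[keep],
                                stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  domains <- do.call(rbind, domains)
  list(records = records,
       hyper_domains = domains[domains$label == "hyper",
                               c("chrom", "start", "end")],
       hypo_domains = domains[domains$label == "hypo",
                              c("chrom", "start", "end")],
       region_truth = region_truth)
}

#' Simulate a two-condition count table with planted fold changes
#'
#' Baseline means are log-normal; counts are negative binomial with the
#' configured dispersion. Planted up (down) genes have their condition-b
#' mean multiplied (divided) by `2^deg_log2fc`; condition b additionally
#' gets a random depth factor within 2x of condition a.
#'
#' @param config A [gahd_sim_config()].
#' @param genome Result of [simulate_genome()].
#' @param truth List with `deg_up_ids`, `deg_down_ids`.
#' @return A [count_table()]; attribute `truth` carries the planted ids.
#' @export
simulate_counts <- function(config, genome, truth) {
  stage_seed(config, "counts")
  ids <- genome$genes$gene_id
  mu <- stats::rlnorm(length(ids), config$count_base_meanlog,
                      config$count_base_sdlog)
  fold <- stats::setNames(rep(1, length(ids)), ids)
  fold[truth$deg_up_ids] <- 2^config$deg_log2fc
  fold[truth$deg_down_ids] <- 2^(-config$deg_log2fc)
  sf <- 2^stats::runif(1, -0.5, 0.5)
  rnb <- function(m) {
    if (config$dispersion == 0) stats::rpois(length(m), m)
    else stats::rnbinom(length(m), mu = m, size = 1 / config$dispersion)
  }
  ca <- rnb(mu)
  cb <- rnb(mu * unname(fold[ids]) * sf)
  # library sizes are the true sequencing depths (whole-library scale), not
  # the realized gene-count sums, so depth normalization is free of
  # DE-composition bias
  tab <- count_table(ids, ca, cb, lib_a = round(sum(mu)),
                     lib_b = round(sum(mu) * sf))
  attr(tab, "truth") <- truth
  tab
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper composing [simulate_genome()],
#' [plant_deg_classes()], [simulate_gahd_tracks()],
#' [simulate_mark_tracks()], [simulate_methylation()] and
#' [simulate_counts()] into one object.
#'
#' @param config A [gahd_sim_config()].
#' @return List with `genome`, `tracks`, `marks`, `methylation`, `counts`
#'   and the combined `truth`.
#' @export
simulate_gahd_study <- function(config = gahd_sim_config()) {
  genome <- simulate_genome(config)
  classes <- plant_deg_classes(config, genome)
  gahd <- simulate_gahd_tracks(config, genome)
  marks <- simulate_mark_tracks(config, genome, classes)
  meth <- simulate_methylation(config, genome,
                               regions = gahd$truth$pa200_dependent_regions)
  counts <- simulate_counts(config, genome, classes)
  truth <- c(gahd$truth, classes,
             list(hyper_domains = meth$hyper_domains,
                  hypo_domains = meth$hypo_domains,
                  region_methylation = meth$region_truth))
  list(genome = genome, tracks = gahd$tracks, marks = marks,
       methylation = meth, counts = counts, truth = truth, config = config)
}
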