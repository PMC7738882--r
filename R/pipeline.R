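pipeline_defaults <- function() {
  list(outdir = "gahd_out", seed = 1L,
       bin_size = 50L, fdr = 0.05, min_len = 200L, merge_gap = 100L,
       pseudocount = 1.0, alpha = 0.01, min_m = 1.0, min_bp = 1L,
       min_sites = 3L, area_window = 10000L,
       dmr_window = 1000L, dmr_min_diff = 0.2, dmr_alpha = 0.05,
       deg_lfc = 1.0, deg_dp = 0.8,
       flank = 21000L, flank_bin = 300L, n_body_bins = 100L,
       promoter_half_width = 2500L, promoter_bin = 50L)
}

#' Build and validate a pipeline configuration
#'
#' All thresholds of the synthetic end-to-end pipeline with their documented
#' defaults. Unknown keys are rejected; basic sanity constraints are
#' enforced.
#'
#' @param ... Named overrides of the defaults (see
#'   [run_gahd_pipeline()]).
#' @param config_file Optional JSON file of overrides; explicit `...`
#'   arguments win over file values.
#' @return A validated list of class `gahd_pipeline_config`.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  cfg <- pipeline_defaults()
  override <- list()
  if (!is.null(config_file))
    override <- jsonlite::read_json(config_file, simplifyVector = TRUE)
  dots <- list(...)
  override[names(dots)] <- dots
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  with(cfg, stopifnot(fdr > 0, fdr < 1, alpha > 0, alpha < 1,
                      dmr_alpha > 0, dmr_alpha < 1,
                      min_m >= 0, min_bp >= 1, min_sites >= 1,
                      deg_lfc >= 0, deg_dp >= 0, deg_dp <= 1,
                      flank %% flank_bin == 0,
                      promoter_half_width %% promoter_bin == 0))
  structure(cfg, class = c("gahd_pipeline_config", "list"))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic GAHD pipeline
#'
#' Simulates a study with planted truth under the pipeline seed, then runs
#' every analysis stage in dependency order: peak calling on the four
#' pulse-chase tracks, M-A normalization per genotype, degraded-region and
#' PA200-dependent region calling, methylation classification of the
#' PA200-dependent regions and genome-area segmentation, DEG calling,
#' metagene/TSS profiling of the mark tracks, and the per-gene integration
#' report. All outputs are plain text (BED/bedGraph/TSV/JSON) written under
#' `config$outdir`, together with the serialized configuration and a
#' manifest listing every file with its MD5 hash. Re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param sim_config Optional [gahd_sim_config()] (its seed is overridden by
#'   the pipeline seed).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (data frame of file, md5).
#' @export
run_gahd_pipeline <- function(config = pipeline_config(),
                              sim_config = NULL) {
  stopifnot(inherits(config, "gahd_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  if (is.null(sim_config)) sim_config <- gahd_sim_config()
  sim_config$seed <- config$seed
  sim_config$bin_size <- config$bin_size

  study <- simulate_gahd_study(sim_config)
  genome <- study$genome
  write_gene_annotation(genome$genes, out("genes.tsv"))
  for (nm in names(study$tracks))
    write_bedgraph(study$tracks[[nm]], out(paste0("gahd_", nm, ".bedgraph")))
  write_bed(study$truth$degraded_regions_wt, out("truth_degraded_wt.bed"))
  write_bed(study$truth$pa200_dependent_regions, out("truth_pa200.bed"))
  write_methylation(study$methylation$records, out("methylation.bedgraph"))
  write_count_table(study$counts, out("counts.tsv"))

  peaks <- lapply(study$tracks, call_peaks, fdr = config$fdr,
                  min_len = config$min_len, merge_gap = config$merge_gap)
  for (nm in names(peaks))
    write_bed(peaks[[nm]][, c("chrom", "start", "end", "name")],
              out(paste0("peaks_", nm, ".bed")))

  call_genotype <- function(p0, p4, track0, label) {
    parts <- classify_common_unique(p0, p4, min_bp = config$min_bp)
    model <- NULL
    if (nrow(parts$pairs) >= 10L) {
      d1 <- p0$raw_density[parts$pairs[, "ia"]]
      d2 <- p4$raw_density[parts$pairs[, "ib"]]
      model <- fit_manorm(d1, d2, pseudocount = config$pseudocount)
    }
    call_degraded_regions(p0, p4, model, alpha = config$alpha,
                          min_m = config$min_m, min_bp = config$min_bp,
                          track_0h = track0, genotype = label)
  }
  deg_wt <- call_genotype(peaks$wt_0h, peaks$wt_4h, study$tracks$wt_0h, "WT")
  deg_ko <- call_genotype(peaks$ko_0h, peaks$ko_4h, study$tracks$ko_0h, "KO")
  pa200 <- pa200_dependent_regions(deg_wt, deg_ko, min_bp = config$min_bp)
  write_degradation_bed <- function(x, f) {
    df <- as.data.frame(x)
    if (nrow(df)) {
      df$name <- df$provenance
      df$score <- ifelse(is.na(df$M), 0, df$M)
    }
    write_bed(df, out(f))
  }
  write_degradation_bed(deg_wt, "degraded_wt.bed")
  write_degradation_bed(deg_ko, "degraded_ko.bed")
  write_degradation_bed(pa200, "pa200_dependent.bed")

  meth_summary <- if (nrow(pa200))
    degradation_methylation_summary(pa200, study$methylation$records,
                                    min_sites = config$min_sites) else NULL
  areas <- segment_genome_areas(study$methylation$records,
                                genome$chrom_sizes,
                                window = config$area_window,
                                min_sites = config$min_sites)
  area_fr <- methylation_fraction(attr(areas, "counts")[["hyper"]],
                                  attr(areas, "counts")[["hypo"]])

  degs <- call_degs(study$counts, lfc = config$deg_lfc, dp = config$deg_dp,
                    pseudocount = config$pseudocount)
  write_degs(degs, out("degs.tsv"))

  prof <- function(track) metagene_matrix(track, genome$genes,
                                          flank = config$flank,
                                          n_body_bins = config$n_body_bins,
                                          flank_bin = config$flank_bin)
  k4 <- lapply(study$marks[c("k4_wt", "k4_ko")], prof)
  h3 <- lapply(study$marks[c("h3_wt", "h3_ko")], prof)
  k4_profile <- ratio_profile(k4$k4_ko, k4$k4_wt, h3$h3_ko, h3$h3_wt)
  write_profile(k4_profile, out("profile_k4_ko_over_wt.tsv"))

  promoter <- function(track) tss_signal(track, genome$genes,
                                         half_width = config$promoter_half_width,
                                         bin = config$promoter_bin)$promoter_mean
  pm <- lapply(study$marks, promoter)
  lr <- function(a, b) log2(pm[[a]] + 0.01) - log2(pm[[b]] + 0.01)
  k4_ratio <- lr("k4_ko", "k4_wt")
  k56_ratio <- lr("k56_ko", "k56_wt")
  polii_ratio <- lr("polii_ko", "polii_wt")

  report <- integration_report(genome$genes, degs, k4_ratio, k56_ratio,
                               polii_ratio)
  utils::write.table(report, out("integration_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")

  summary <- list(
    seed = config$seed,
    n_peaks = lapply(peaks, nrow),
    degraded = list(
      wt = list(n = nrow(deg_wt), by_provenance = as.list(table(deg_wt$provenance))),
      ko = list(n = nrow(deg_ko), by_provenance = as.list(table(deg_ko$provenance))),
      pa200_dependent = nrow(pa200)),
    methylation = list(
      region_counts = as.list(meth_summary$counts),
      region_hyper_percent = meth_summary$percent,
      region_hyper_percent_headline = meth_summary$percent_headline,
      area_counts = as.list(attr(areas, "counts")),
      area_hyper_percent = area_fr$percent),
    degs = as.list(attr(degs, "summary")))
  write_json_out(summary, out("summary.json"))
  cfg_out <- unclass(config)
  cfg_out$outdir <- NULL      # path-free so identical runs serialize identically
  write_json_out(cfg_out, out("config.json"))

  files <- sort(list.files(config$outdir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_json_out(manifest, out("manifest.json"))
  invisible(list(study = study, peaks = peaks, degraded_wt = deg_wt,
                 degraded_ko = deg_ko, pa200 = pa200,
                 methylation_summary = meth_summary, areas = areas,
                 degs = degs, report = report, summary = summary,
                 manifest = manifest))
}
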