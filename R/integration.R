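#' Promoter mark change by DEG class
#'
#' Groups per-gene promoter mark log2(KO/WT) ratios by DEG call and reports
#' the class means plus a Mann-Whitney test between the up and down classes.
#'
#' @param deg_records Result of [call_degs()] (needs `gene_id`, `call`).
#' @param tss_means_wt,tss_means_ko Named numeric vectors of promoter mark
#'   means per gene (e.g. `promoter_mean` from [tss_signal()]).
#' @param pseudocount Pseudocount for the log2 ratio (default 0.01).
#' @return List with `per_gene` (data frame gene_id, call, ratio),
#'   `class_means` (named vector over up/down/unchanged; `NA` for empty
#'   classes) and `p_up_vs_down` (Mann-Whitney; `NA` if either class is
#'   empty).
#' @export
mark_change_by_deg_class <- function(deg_records, tss_means_wt, tss_means_ko,
                                     pseudocount = 0.01) {
  ids <- intersect(deg_records$gene_id,
                   intersect(names(tss_means_wt), names(tss_means_ko)))
  call <- deg_records$call[match(ids, deg_records$gene_id)]
  ratio <- log2(tss_means_ko[ids] + pseudocount) -
    log2(tss_means_wt[ids] + pseudocount)
  per_gene <- data.frame(gene_id = ids, call = call, ratio = unname(ratio),
                         stringsAsFactors = FALSE)
  class_means <- vapply(c(up = "up", down = "down", unchanged = "unchanged"),
                        function(cl) {
                          r <- per_gene$ratio[per_gene$call == cl]
                          if (length(r)) mean(r, na.rm = TRUE) else NA_real_
                        }, numeric(1))
  up <- per_gene$ratio[per_gene$call == "up"]
  down <- per_gene$ratio[per_gene$call == "down"]
  p <- if (length(up) && length(down))
    suppressWarnings(stats::wilcox.test(up, down)$p.value) else NA_real_
  list(per_gene = per_gene, class_means = class_means, p_up_vs_down = p)
}

#' Concordance between mark changes and Pol II recruitment
#'
#' Spearman rank correlation and sign-agreement fraction between per-gene
#' mark and Pol II KO/WT log2 ratios. Rank correlation is used because the
#' claim of interest is direction, not linearity.
#'
#' @param mark_ratio,polii_ratio Named numeric vectors (gene_id ->
#'   log2 ratio) with >= 10 shared genes.
#' @return List with `spearman`, `sign_agreement`, `n`.
#' @export
polii_concordance <- function(mark_ratio, polii_ratio) {
  ids <- intersect(names(mark_ratio), names(polii_ratio))
  ids <- ids[is.finite(mark_ratio[ids]) & is.finite(polii_ratio[ids])]
  if (length(ids) < 10L)
    stop("polii_concordance: fewer than 10 shared genes")
  m <- mark_ratio[ids]; p <- polii_ratio[ids]
  list(spearman = stats::cor(m, p, method = "spearman"),
       sign_agreement = mean(sign(m) * sign(p) > 0),
       n = length(ids))
}

#' Mark-change inversion across DMR overlap classes
#'
#' Splits genes by whether they overlap hyper- or hypo-direction DMRs and
#' compares mean mark ratios; the inversion statistic is
#' `mean(hypo-DMR genes) - mean(hyper-DMR genes)` (positive when mark gains
#' concentrate where methylation is lost).
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param mark_ratio_per_gene Named numeric vector (gene_id -> log2 ratio).
#' @param genes Gene annotation data frame.
#' @return List with `mean_hyper`, `mean_hypo`, `inversion`,
#'   `n_hyper_genes`, `n_hypo_genes`; all-`NA`/empty summary when there are
#'   no DMRs.
#' @export
dmr_mark_inversion <- function(dmrs, mark_ratio_per_gene, genes) {
  empty <- list(mean_hyper = NA_real_, mean_hypo = NA_real_,
                inversion = NA_real_, n_hyper_genes = 0L, n_hypo_genes = 0L)
  if (is.null(dmrs) || nrow(dmrs) == 0L) return(empty)
  grp_mean <- function(dir) {
    sub <- dmrs[dmrs$direction == dir, , drop = FALSE]
    if (!nrow(sub)) return(list(mean = NA_real_, n = 0L))
    hit <- overlaps_any(genes, sub)
    ids <- intersect(genes$gene_id[hit], names(mark_ratio_per_gene))
    if (!length(ids)) return(list(mean = NA_real_, n = 0L))
    list(mean = mean(mark_ratio_per_gene[ids], na.rm = TRUE),
         n = length(ids))
  }
  hyper <- grp_mean("hyper"); hypo <- grp_mean("hypo")
  list(mean_hyper = hyper$mean, mean_hypo = hypo$mean,
       inversion = hypo$mean - hyper$mean,
       n_hyper_genes = hyper$n, n_hypo_genes = hypo$n)
}

#' Methylation summary of degradation regions
#'
#' Classifies (e.g. PA200-dependent) degradation regions by CpG methylation
#' and reports how many are hyper- vs hypo-methylated, with the headline
#' percentage computed over classified regions only (hyper + hypo), as in
#' the 550/6522 arithmetic.
#'
#' @param regions Interval data frame of degradation regions.
#' @param records Methylation records.
#' @param min_sites Minimum CpGs per region (default 3).
#' @return List with `counts` (hyper/hypo/no_data), `percent` (two
#'   decimals), `percent_headline` (integer, round half away from zero) and
#'   `labels`.
#' @export
degradation_methylation_summary <- function(regions, records, min_sites = 3L) {
  cls <- classify_regions(regions, records, min_sites)
  fr <- methylation_fraction(cls$counts[["hyper"]], cls$counts[["hypo"]])
  list(counts = cls$counts, percent = fr$percent,
       percent_headline = fr$percent_headline, labels = cls$labels)
}

#' Per-gene integration report
#'
#' Joins DEG calls, promoter mark ratios, gene-body Pol II ratios and DMR
#' overlap direction into one row per annotated gene (genes with missing
#' data keep `NA` fields rather than being dropped).
#'
#' @param genes Gene annotation data frame.
#' @param deg_records Result of [call_degs()].
#' @param k4_ratio,k56_ratio,polii_ratio Named per-gene log2(KO/WT) ratios.
#' @param dmrs DMR data frame (may be empty).
#' @return Data frame with one row per gene: `gene_id`, `deg_call`,
#'   `k4_ratio`, `k56_ratio`, `polii_ratio`, `dmr_direction`.
#' @export
integration_report <- function(genes, deg_records, k4_ratio, k56_ratio,
                               polii_ratio, dmrs = NULL) {
  ids <- genes$gene_id
  dmr_dir <- rep(NA_character_, length(ids))
  if (!is.null(dmrs) && nrow(dmrs)) {
    for (dir in c("hyper", "hypo")) {
      sub <- dmrs[dmrs$direction == dir, , drop = FALSE]
      if (nrow(sub)) dmr_dir[overlaps_any(genes, sub)] <- dir
    }
  }
  data.frame(gene_id = ids,
             deg_call = deg_records$call[match(ids, deg_records$gene_id)],
             k4_ratio = unname(k4_ratio[ids]),
             k56_ratio = unname(k56_ratio[ids]),
             polii_ratio = unname(polii_ratio[ids]),
             dmr_direction = dmr_dir,
             stringsAsFactors = FALSE)
}
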