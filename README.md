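# gahd — genome-wide analysis of histone degradation

`gahd` is an R package for analysing **pulse-chase sequencing of
metabolically labeled histones** (GAHD: genome-wide analysis of histone
degradation). In this design, newly synthesised histones are pulse-labeled
(e.g. with the methionine analog azidohomoalanine), the DNA co-purifying
with the labeled histones is sequenced at successive chase times, and loss
of signal between chase times marks regions where histones were degraded.
Comparing a wild type with a proteasome-activator knockout (PA200⁻/⁻)
identifies *PA200-dependent* degradation regions, which can then be related
to CpG methylation state, histone marks (H3K4me3, H3K56ac), RNA polymerase
II occupancy and differential gene expression.

The package is aimed at epigenomics analysts who have coverage tracks
(bedGraph), peak/region sets (BED), per-CpG methylation levels (bedGraph)
and gene-level count tables (TSV), and want a tested, reproducible version
of this analysis. A synthetic-data generator with planted ground truth
drives end-to-end validation of every stage.

## What it computes

* **Peak calling** (`call_peaks`) — per-bin Poisson test against
  `λ = max(genome mean, local 10-kb mean)`, Benjamini–Hochberg across all
  bins, merge/minimum-length rules.
* **M–A normalization** (`fit_manorm`) — over peaks common to two samples,
  with densities *x₁*, *x₂* and pseudocount *c*:

  ```
  M = log2((x1+c)/(x2+c)),   A = 0.5·log2((x1+c)(x2+c))
  ```

  an OLS fit of M on A (intercept re-centred on the median residual)
  rescales sample 2 by `2^(slope·A + intercept)` so the median normalized M
  over common peaks is 0.
* **Degraded regions** (`call_degraded_regions`) — the union of peaks
  unique to 0 h and common peaks with normalized `M ≥ 1` and one-sided
  Audic–Claverie `p < 0.01`; **PA200-dependent regions**
  (`pa200_dependent_regions`) are wild-type degraded regions with no
  overlap in the knockout's degraded set.
* **Methylation classification** (`classify_regions`,
  `segment_genome_areas`, `call_dmrs`) — a region/area is
  hyper-methylated iff its mean CpG level is strictly > 0.5; percentages
  are reported over classified regions only.
* **DEG calling** (`call_degs`) — a gene is differentially expressed iff
  `|log2-ratio| ≥ 1` **and** `diverge probability ≥ 0.8` (both inclusive),
  where the diverge probability is a symmetrized two-sided score under the
  Audic–Claverie model of digital expression.
* **Profiles** (`metagene_matrix`, `tss_signal`, `ratio_profile`) —
  scaled-gene-body metagene matrices with fixed flanks (21 kb or 1.5 kb),
  TSS ± 2.5 kb promoter means, and KO/WT log2 ratio profiles optionally
  normalized to H3.
* **Integration** (`mark_change_by_deg_class`, `polii_concordance`,
  `dmr_mark_inversion`, `degradation_methylation_summary`,
  `integration_report`) — per-gene joins of all of the above.
* **Synthetic data** (`gahd_sim_config`, `simulate_gahd_study`) — genomes,
  pulse-chase tracks, mark/Pol II tracks, methylation domains and count
  tables with planted, recoverable truth.

## Worked example

```r
library(gahd)

res <- run_gahd_pipeline(pipeline_config(outdir = "gahd_out", seed = 1))
res$summary$degraded
#> $wt$n        [1] 63
#> $ko$n        [1] 20
#> $pa200_dependent  [1] 43

truth  <- res$study$truth$pa200_dependent_regions   # 40 planted regions
called <- as.data.frame(res$pa200)                  # 43 called regions
res$methylation_summary$counts
#>   hyper    hypo no_data
#>       2      39       2
res$methylation_summary$percent
#> [1] 4.88
attr(res$degs, "summary")
#>   n_up n_down
#>     30     30
```

Here the pipeline called 43 PA200-dependent regions of which all 40 planted
regions are recovered at per-region Jaccard ≥ 0.5 (the 3 extra calls are
noise peaks, ≈7% of calls); most called regions are hypo-methylated because
the generator plants degradation in open chromatin; and the DEG caller
recovered exactly the 30 + 30 planted up/down genes. Every file the run
writes, with MD5 hashes, is in `gahd_out/manifest.json`; re-running with
the same seed is byte-identical.

The same pipeline can be driven from a shell:

```sh
Rscript inst/scripts/gahd-pipeline.R --outdir gahd_out --seed 1
```

## Vignette

`vignettes/gahd-methods.Rmd` describes the statistical models, every
tunable threshold with its default and rationale, what the synthetic
generator does and does not emulate, and known limitations.
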