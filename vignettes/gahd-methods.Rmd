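---
title: "Models and methods behind the gahd pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the gahd pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement being modelled

Pulse-chase sequencing of metabolically labeled histones produces, per
sample, a genome-wide coverage track whose height is proportional to the
local amount of labeled (i.e. newly deposited) histone. Two chase times
(0 h and 4 h) per genotype (wild type and PA200-knockout) give four tracks.
Histone degradation appears as signal *loss* between 0 h and 4 h; the
PA200-dependent component is what is lost in the wild type but not in the
knockout. All coordinates in the package are 0-based half-open (BED
convention), a single convention chosen to eliminate off-by-one drift;
strand matters only for TSS/TTS orientation and profile flipping, never for
interval arithmetic, which is delegated to IRanges/GenomicRanges behind the
package's data-frame surface.

Tracks are held in fixed 50-bp bins by default: kilobase-scale degradation
regions are well resolved at that width while a 2 × 10 Mb synthetic genome
stays at ~400k bins, comfortable for a laptop. bedGraph input is rebinned
by length-weighted averaging, with uncovered bases counted as zero and
overlapping records rejected as ambiguous.

## Peak calling

The enrichment caller is deliberately simple and fully specified, playing
the decision role a general-purpose caller plays in practice. Each bin
count is tested against a Poisson null with rate
`λ = max(genome-wide mean, local mean in a centred 10-kb window)`; the
local term absorbs broad enrichment and copy-number-like structure, the
genome-wide floor keeps empty regions from generating significance.
Per-bin upper-tail p-values are Benjamini–Hochberg corrected across all
bins genome-wide (`fdr = 0.05`), significant bins at most `merge_gap =
100` bp apart are merged, peaks shorter than `min_len = 200` bp are
dropped, and the summit is the centre of the highest bin. On null
(uniform Poisson) tracks the fraction of genome covered by calls stays
below the bin-level FDR — this is checked by a 20-seed Monte-Carlo test.

## M–A normalization over common peaks

Two samples are compared only where both have peaks ("common" peaks,
overlap ≥ 1 bp; the 1-bp default is the least-assuming reading of peak
co-occurrence and is configurable). For paired common-peak densities
(reads/kb) the package computes, with pseudocount `c = 1`,

```
M = log2((x1 + c)/(x2 + c))        A = 0.5 · log2((x1 + c)(x2 + c))
```

fits `M = slope · A + intercept` by ordinary least squares, and rescales
sample 2 by `2^(slope · A + intercept)`. One refinement: the intercept is
re-centred on the median residual. Genuinely changed peaks enter the fit as
one-sided outliers; the median re-centring makes the post-normalization
median M over common peaks exactly zero without requiring an iterative
robust fit, and is a no-op when no peaks changed. The per-peak differential
test is the closed-form Audic–Claverie (equal-library Poisson) test applied
to rounded normalized counts (`density × length / 1000`): conditional on
the first count `x`, the second follows `NegBinomial(size = x + 1,
prob = 1/2)`, and the one-sided p-value is its lower tail. This replaces
the Bayesian significance machinery of the normalization tool the approach
is modelled on; it is closed-form, oracle-verifiable in tests by direct
pmf summation, and plays the same decision role. A common peak is called
degraded when normalized `M ≥ min_m = 1` (two-fold) **and** `p < alpha =
0.01`; the field convention of a two-fold/1% rule is used because the
analysis definition specifies significance without fixing a level, and
both knobs are exposed.

## Degraded and PA200-dependent regions

Per genotype, the degraded set is the union of 0-h peaks with no 4-h
overlap ("unique at 0 h") and differentially lost common peaks.
Overlapping results are merged; a merged region with any differential
parent is labelled `differential_common`, and region densities are
re-measured from the 0-h track rather than averaged from parents (parent
averages would depend on arbitrary peak fragmentation). Both the merged
count and the by-provenance tallies are reported, since either convention
could underlie a published region count. PA200-dependent regions are
wild-type degraded regions with no ≥ 1 bp overlap in the knockout's
degraded set; the reverse (knockout-only) subtraction is available but
labelled as a secondary, non-headline output.

## Methylation classification

A region is hyper-methylated iff the unweighted mean of the CpG levels
inside it is **strictly greater than 0.5** (the strict inequality follows
the definition's wording); at least `min_sites = 3` CpGs are required,
otherwise the region is `no_data`. Percentages are computed over
classified regions only (hyper + hypo), matching the arithmetic of a
550-of-6522 style tally, and headline values round half away from zero.

Genome-wide "areas" are built by tiling fixed 10-kb windows, classifying
each, and merging adjacent same-label windows; `no_data` windows break
merging. The underlying area construction of the published ratio is not
operationally defined, so this windowed segmentation is the package's own
reproducible definition, with the window width exposed; only the ratio
arithmetic itself is treated as exactly reproducible.

The DMR caller is likewise the package's own simple definition (the term
is used in the field without a canonical method): fixed 1-kb windows, mean
level difference ≥ 0.2, a coverage-weighted two-proportion test when
coverage is available and a Welch t-test on site levels otherwise
(windows with zero variance in both conditions are called directly from
the mean difference), BH correction at 0.05, and merging of abutting
same-direction windows.

## The DEG rule and the diverge probability

A gene is differentially expressed iff `|log2-ratio| ≥ 1` **and**
`diverge probability ≥ 0.8`, both thresholds inclusive. The log2 ratio is
library-size normalized with pseudocount 1. The diverge probability has no
published closed form (it originates in a sequencing-provider pipeline),
so the package defines it explicitly on the Audic–Claverie model: given
count `x` in one library, the count in the other follows
`NegBinomial(size = x + 1, prob = N1/(N1 + N2))`, and the score is
`1 − 2·min(lower tail, upper tail)` at the observed count — near 0 for
concordant counts, near 1 for clearly diverged ones. The naive one-sided
construction is not exactly exchangeable between samples, so the score is
symmetrized by averaging the two conditioning directions, which makes
swap-invariance exact; tests verify the value against direct pmf
summation. No pseudocount enters the probability (zeros are handled
natively), and no multiple-testing correction is applied because the rule
is a plain double threshold; BH-adjusted values are emitted as an optional
extra column only. Because the model is Poisson at its core, the rule is
well calibrated for technical-scale noise but anti-conservative under
strong biological overdispersion — a known property of threshold rules of
this family, and the reason the generator's default dispersion is 0.01
(below).

## Profiles

Metagene matrices scale every gene body to `n_body_bins = 100` equal
segments and attach fixed-width flank bins: 300 bp bins for 21-kb flanks,
50 bp for 1.5-kb and 2.5-kb windows (smooth at these scales; all exposed).
Segment means are exact base-pair-weighted integrals of the binned track
(fractional segment boundaries included), verified against per-base
oracles to 1e-9. Minus-strand rows are reversed so column 1 is always
biologically upstream; positions outside a chromosome are `NA` and drop
out of column means; genes shorter than the body bin count are skipped
with a warning. Tracks are depth-normalized to signal-per-million before
profiling by default, so profiles are comparable across libraries; the
raw mode (`rpm = FALSE`) preserves exact linearity in the track, which the
invariance tests exercise. Overlapping genes are profiled independently —
no masking is attempted. Promoter summaries use TSS ± 2.5 kb; gene-body
Pol II summaries use the 1.5-kb-flank metagene. Ratio profiles are
computed from column summaries with a pseudocount of 0.01 (small against
per-million-scale signals), in single (`mark`) or double (`mark/H3`)
normalization mode.

## Integration choices

Rank (Spearman) correlation is used for the mark/Pol II concordance
because the claim of interest is directional coupling, not linearity. The
DMR/mark inversion statistic is `mean(ratio over hypo-DMR genes) −
mean(ratio over hyper-DMR genes)`, positive when mark gains concentrate
where methylation is lost; it is exactly antisymmetric under swapping the
DMR direction labels. Integration reports keep one row per annotated gene,
with `NA` fields rather than dropped rows.

## The synthetic generator: what it emulates

The generator's defaults *are* the study conditions used by the tests and
the acceptance script: a 2 × 10 Mb genome, 200 non-overlapping genes of
5–20 kb, 60 planted wild-type degraded regions (2–4 kb, 8-fold enriched
over a background of 10 reads/bin) of which 40 are PA200-dependent and 20
also degrade in the knockout, plus 150 stable enriched regions that form
the common-peak backbone for normalization. Pulse-chase structure: newly
deposited histone signal peaks 3-fold within ±500 bp of every TSS; at 4 h
the background retains 0.8 of its 0-h level in both genotypes, wild-type
degraded regions retain 0.2 of their 0-h mean, non-degrading knockout
regions retain 0.85, the knockout 0-h field is globally scaled by 0.7
(the knockout's overall enrichment is visibly lower), and knockout 4-h
signal within ±500 bp of TSSs is multiplied by 1.5 — the TSS accumulation
factor, a free simulation parameter since the real effect's magnitude is
not quantified. Counts are Poisson per bin; gene counts are negative
binomial with log-normal baselines and ±2 planted log2 fold changes;
methylation plants 684 hyper and 123 hypo single-window domains separated
by CpG-free gaps (so each is recoverable as one area), CpGs every 100 bp
with Beta-distributed levels (means 0.8 / 0.15, concentration 10), and
92% of planted degradation regions are placed in hypo-methylated chromatin.

Three generator choices deserve justification:

* **Dispersion 0.01.** The design being emulated sequences one library per
  condition, so the only honest noise model is technical-scale: Poisson
  counting noise plus mild extra-Poisson variation. 0.01 is the
  conventional technical/cell-line-scale dispersion. With
  biological-replicate-scale dispersion the threshold DEG rule (which has
  no dispersion estimation — there are no replicates to estimate from)
  would be strongly anti-conservative; that is a property of the rule, not
  of the implementation, and the vignette section above documents it.
* **True library sizes.** The written count tables carry the generator's
  true sequencing depths rather than realized gene-count sums, so depth
  normalization is free of DE-composition bias (the analog of using
  whole-library mapped-read totals rather than the sum of a biased gene
  subset).
* **Separation of effects.** Planted regions avoid TSS ± 1.5 kb so the
  degradation and TSS-accumulation effects never mix, and stable regions
  avoid planted regions; this keeps every planted effect independently
  recoverable, which is what makes the truth set usable as an oracle.

What the generator does **not** emulate: fragment-length and GC effects,
read-level noise, CpG-density variation (spacing is fixed at 100 bp),
replicate structure beyond an optional track count, overlapping genes'
signal interference, and copy-number or mappability artifacts. Passing the
planted-truth tests therefore shows the *pipeline logic* is correct under
its stated noise model — not that real libraries with unmodelled biases
would behave as cleanly.

## Problem sizes and numerical details

The end-to-end validation runs the full default study (2 × 10 Mb, four
tracks, ~25 s); null calibration uses twenty 1 × 5 Mb simulations, a size
chosen to make a 20-seed Monte-Carlo loop quick at a desk while leaving
hundreds of peaks per seed. Seeds derive from a single top-level seed with
fixed per-stage offsets (documented in `seed_offsets`), so every stage is
independently reproducible. Ties and boundaries: the hyper/hypo rule is
strict at 0.5; DEG thresholds are inclusive; peak merging measures gaps in
bp between significant bins; an M–A fit on constant-A input (a pure depth
shift with no density spread) degenerates to slope 0 with the median shift
as intercept. All text outputs are written with fixed numeric formats so
identical runs are byte-identical, which the manifest's MD5 hashes make
checkable.

## Known limitations

* The diverge probability is this package's explicit reconstruction of an
  undocumented score; published DEG counts obtained with the original
  pipeline are not expected to reproduce exactly.
* The peak and DMR callers are intentionally minimal; they stand in for
  (and accept regions produced by) specialised external callers, which
  remain preferable on real data.
* Single-library designs cannot estimate biological dispersion; every
  downstream significance statement inherits that limitation.
* Genome-area counts depend on the window width; only the hyper/hypo
  ratio arithmetic is scale-free.
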