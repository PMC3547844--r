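---
title: "Detecting centromere-like regions from kinetochore ChIP-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting centromere-like regions from kinetochore ChIP-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrscan)
```

## The scientific problem

*Saccharomyces cerevisiae* has sequence-defined point centromeres (*CEN*s)
of about 125 bp, one per chromosome, marked by the centromeric histone H3
variant Cse4 (CENP-A/CenH3). When Cse4 is overproduced (the "Cse4 OP"
genotype), discrete non-centromeric loci become co-occupied by four
kinetochore proteins — Cse4, Mif2, Ndc10 and Ndc80 — at levels roughly an
order of magnitude below centromeric occupancy. These centromere-like
regions (CLRs) confer partial segregation function on plasmids and
chromosomes, tend to form near centromeres and inside larger-than-average
intergenic regions, and carry a short AT-enriched stretch reminiscent of the
CDEII element.

`clrscan` implements the complete computational side of this analysis as a
reusable, tested pipeline: a windowed enrichment scorer, the four-protein
overlap caller, randomization tests for genomic context, the sliding
maximum-AT statistic, centromere-anchored signal aggregation with a paired
peak-width test, a 12-variable discriminant/principal-component stage, and
the small-assay statistics (qPCR fold enrichment, doubling times,
fluctuation-analysis aggregation, Fisher's exact tests). A synthetic-data
generator emulating the study design makes every stage runnable offline.

## Coordinates and interval containers

Intervals are plain data frames with `chrom`, `start`, `end` columns,
**1-based and inclusive on both ends** (`width = end - start + 1`), matching
the convention of the published coordinate table shipped with the package
(`load_table1_sites()`: 23 CLRs and 38 low-confidence negative control
regions, LCNCRs). Whether those published coordinates are 0- or 1-based is
not stated in the source; 1-based inclusive is assumed and conversion to BED
(0-based half-open) happens only at the I/O boundary. Overlap and distance
computations are delegated to IRanges/GenomicRanges; the gap between two
disjoint intervals is `start2 - end1 - 1`, so touching intervals have
distance 0.

## The synthetic-data generator defines the study conditions

`sim_config()` encodes the conditions the analysis assumes, not knobs to be
tuned per test:

* **Genome**: 4 chromosomes x 300 kb — large enough for the 25-kb
  centromere-proximity logic and a realistic ORF landscape, small enough
  that the complete pipeline runs in well under a minute. ORFs tile ~70% of
  each chromosome (exponential ORF ~1.4 kb / gap ~0.6 kb alternation, the
  budding-yeast gene density); maximal inter-ORF gaps define intergenic
  regions. One CEN per chromosome, kept intergenic.
* **Planted CLRs**: 20 per genome, 600 bp (published CLRs span 0.5–1.2 kb),
  centered in intergenic gaps, with half placed within 25 kb of a CEN
  (matching "about half" in the source data) and each carrying a 90-bp
  patch at AT fraction 0.9 against a 38%-GC background (the yeast genome
  average).
* **Occupancy**: centromeres are enriched 50-fold over background in both
  genotypes; planted CLRs are enriched `cen_multiplier / 10` (an order of
  magnitude weaker, as reported) and **only** in the OP genotype and only in
  tagged-protein tracks. Untagged controls are background-only.
* **Counts**: Poisson with block-level (1 kb) Gamma overdispersion at CV
  0.1. The source is silent on the noise model; Poisson-Gamma is the
  standard count-noise family for ChIP-seq coverage and keeps expectations
  analytic. Background depth is 2 reads/bp per replicate (~2.4 M reads per
  1.2 Mb genome, comparable to the ~2.1 M uniquely mapped reads per
  replicate of the original libraries). Each track also receives a
  lognormal (SD 0.1) enrichment factor for replicate-to-replicate
  variability, which the source does not quantify.
* **OP centromere broadening**: implemented as a wider enrichment footprint
  (800 bp vs 400 bp box kernel), not higher amplitude, because the reported
  effect is "a broader distribution" at centromeres. Footprint widths get a
  small per-centromere lognormal jitter (SD 0.05): real centromeric
  footprints differ between chromosomes, and exactly identical widths would
  make the paired width test degenerate.

Everything is deterministic given the seed; per-stage child seeds are
derived by a stable string hash (`derive_seed()`) so that stages have
independent, reproducible streams.

What the generator deliberately does **not** emulate: read-level artifacts
(FASTQ, alignment, duplicates), mappability and repeat structure, GC bias,
fragment-length effects, and chromatin features (nucleosome positioning,
HOT regions) beyond flat background. Passing tests therefore demonstrate
that the *procedures* behave per contract on data with the assumed
statistical structure — not that the thresholds would reproduce the
published site list from raw reads.

## Peak scoring

`call_peaks()` is a deliberately simple scorer with the output contract the
downstream caller needs (q-value, enrichment ratio, excess reads). It
slides 200-bp windows in 50-bp steps, tests each window's sample count
against the depth-scaled control count with a one-sided binomial test
(conditioning on the window total, success probability = the sample's share
of total depth), applies Benjamini–Hochberg across all windows, and merges
significant windows closer than one step. Ratios are depth-normalized with
a 1-read pseudocount. It does not attempt to reproduce the two-pass
simulation-based scorer used on the original data; its q-values are not
comparable numerically, only contractually.

## The CLR caller

The identification procedure mirrors the published rules:

1. per replicate, keep sites with q-value < 1e-5;
2. reconcile replicates per protein: a region survives only if every
   replicate has an overlapping surviving site; its ratio is the duplicate
   mean;
3. overlap the four proteins with maxgap = 150 bp. The source does not say
   whether "overlap" is pairwise or chained; single-linkage chaining is
   used (the common convention of interval tools), then the chain must
   contain all four proteins. The candidate is the union span.
4. ratio floors on the duplicate means: 2.0 for Cse4, 1.5 for Mif2 and
   Ndc10. Ndc80 has no stated floor and is treated as presence-only
   (configurable).
5. confidence filters, made quantitative because the original relied partly
   on manual track inspection: demote to LCNCR if >50% of the candidate
   lies over an ORF whose PolII rank is in the top decile, if it overlaps a
   supplied HOT-region list, or if untagged-control signal exceeds a
   ceiling. Candidates overlapping an annotated CEN are removed outright —
   CLRs are by definition non-centromeric.

Raising any ratio floor can only shrink the CLR set (tested as a
monotonicity property). On the default synthetic conditions the caller
attains recall >= 0.9 of planted CLRs with zero false positives in OP and
calls nothing in WT.

## Randomization tests

Feature association uses an empirical null: random point positions are
drawn per iteration, matching the observed per-chromosome site counts, and
the statistic is the number of points within the proximity window of a
feature (25 kb for CENs, 5 kb for ARSs/tRNAs/retrotransposons). The
p-value is the **plain fraction** of iterations with a statistic at least
as extreme (no +1 pseudocount), so the resolution is 1/iterations and a
zero count is reported as "< 1/iterations" rather than 0. Bonferroni
adjustment uses family size 3 — the three discrete feature classes — while
the CEN and intergenic tests are reported unadjusted, as in the source.
Null positions are single base points (a site-midpoint surrogate), since
the source randomizes "sites" without specifying their extent.

The intergenic-length test excludes sites that partly overlap an ORF,
takes the mean length of intergenic regions hosting the remaining sites,
and compares it to means of randomly drawn intergenic regions.

One calibration note: the association count is a discrete statistic, so
its empirical p-values are exactly uniform only in the near-continuous
regime. The calibration tests therefore draw many sites per repetition
(250), spreading the null count over enough values that a
Kolmogorov–Smirnov uniformity check is meaningful; with a handful of sites
the p-values are super-uniform by discreteness, which is expected behavior
rather than a defect.

The "MCMC simulation" group comparisons of the original study (rjags) are
implemented as a nonparametric bootstrap of the group-mean difference
(`resampling_group_compare()`, 100,000 draws, two-sided crossing-zero
p-value). The original estimator is described only as "the maximum
likelihood estimator"; the group mean is used here and the aggregation is
configurable. Inputs to this comparison are fluctuation-analysis values:
the median of 3–5 technical replicates per transformant (lower median for
even counts, a documented convention).

## Signal aggregation and peak width

`aggregate_cen_signal()` averages the per-million-normalized tracks of the
four proteins at every position of a 4-kb window centered on the CEN
midpoint (4001 positions) and forms `log2((signal + 0.1) / (control +
0.1))`; the 0.1 rpm pseudocount handles zero-control positions, on which
the source is silent. `peak_width()` counts the contiguous above-threshold
(ratio >= 2) run containing the window center. The source's "length of
centromeric signal" is ambiguous between the central run and all
above-threshold positions; the contiguous run is the conservative reading
and the alternative is available via `contiguous = FALSE`. WT-vs-OP widths
are compared per centromere with a two-sided paired t-test.

## The 12-variable classification stage

`extract_features()` computes, per site: percent of length overlapping an
ORF; mean and maximum AT content (90-bp sliding window over a 500-bp
region centered at the site midpoint, or at the aggregated-signal maximum
when tracks are supplied); distances to the nearest CEN, retrotransposon,
tRNA and ARS; the length of the closest intergenic region; and four "rank
of the closest region" variables (two open-chromatin lists scored against
HA and Myc controls, PolII, and Cse4 in a WT strain). "Rank" is the row
position of the nearest region in that assay's significance-sorted target
list (sorted by q-value, then excess reads) — the reading most consistent
with how the target lists are built; it is configurable by re-sorting the
supplied list.

Each variable is then transformed toward normality by whichever of
identity / log / square root maximizes the Shapiro–Wilk W (the original
chose transforms by eye from quantile–quantile plots; an automated
criterion is required for reproducibility), and z-scored. Multivariate
normality is checked with a chi-square quantile plot plus simulation
envelope. Group differences use one-way MANOVA (Wilks) and per-variable
ANOVA.

Classification uses two-class LDA on the standardized data, reported with
leave-one-out cross-validated accuracy, in both the 12-variable and the
11-variable form (dropping percent-ORF-overlap, which is arguably an
artifact of site length). Discriminant coefficient signs are
unidentifiable in themselves, so they are oriented to make the CLR-group
mean score positive. As comparisons, k-nearest neighbors (k = 3, LOOCV)
and a 2-means cluster-to-label matching accuracy are provided — the
original text mentions both clustering and k-NN in different places, so
both modes exist and neither is asserted to be the published 83%.

PCA is run on the CLR rows alone, standardized via the correlation matrix.
Component retention uses parallel analysis: 1000 standard-normal datasets
of the same shape, retaining leading components whose eigenvalue exceeds
the 95th percentile of the matched null eigenvalue (the original states
neither the replicate count nor the percentile; these are the conventional
choices). A 95% confidence ellipse on the first two score dimensions uses
the chi-square(2) quantile of the score covariance.

## Assay statistics

* **qPCR**: triplicate crossing points are summarized by their mean (the
  instrument's second-derivative-maximum step is upstream of this
  package). Raw ratio `2^(Cp_control - Cp_experimental)` per primer;
  normalized enrichment = positive-primer raw ratio divided by the mean
  negative-primer raw ratio; enrichment > 2 flags significant binding.
  The estimator is invariant to adding a constant to all Cp values.
* **Doubling times**: least squares on `log2(OD)` vs time restricted to an
  exponential OD range (0.05–1.0 by default; whether the original fit used
  all points is unstated, so full-range fitting is available via
  `od_bounds = c(0, Inf)`).
* **Segregation counts**: Fisher's exact test (`stats::fisher.test`),
  verified in the test suite against exhaustive hypergeometric enumeration.

## Problem sizes and reproducibility

The shipped tests exercise the pipeline at the generator's default scale
(4 x 300 kb genome, 20 planted CLRs, 2 replicates x 4 proteins x 2
genotypes) over multiple seeds, with randomization tests at 2,000–10,000
iterations in tests and 100,000 (the study's value) in
`scripts/acceptance.R`. These sizes were chosen so the whole suite runs on
a laptop in a few minutes while every statistical claim retains its
designed resolution. All randomness flows from explicit seeds;
`run_pipeline()` reruns byte-identically for its deterministic outputs.

## Known limitations

* The peak scorer is a stand-in with a compatible contract, not a
  reimplementation of the original two-pass scorer; q-values differ.
* Synthetic data omit mappability, repeats and chromatin structure, so
  recovery results bound behavior only under the assumed noise model.
* The published site list cannot be re-derived here (it requires the raw
  sequencing archives); it is shipped as the published result of record
  and used as a fixture, not recomputed.
* Cross-species conservation analyses (BLAST against fungal genomes) are
  out of scope; the in-scope statistics they reuse (association tests,
  max-AT, intergenic lengths) are all available for external annotation
  tables via the exported functions.
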