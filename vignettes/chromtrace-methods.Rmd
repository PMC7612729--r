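---
title: "Methods: chromatin-state tracing, linking and target calling"
author: "chromtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state tracing, linking and target calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chromtrace` implements a rule-based pipeline for following regulatory
elements through chromatin-state space along an ordered cell-fate
trajectory (by default hESC → PreME → ME → DE / hPGCLC → hPGC, six cell
types with two replicates each). This vignette explains the models and
rules, the parameters that matter, the synthetic data the package
validates itself on, and the numerical and design choices that were
genuinely open.

## Coordinates and containers

Peaks and elements live in `GRanges` (1-based, closed intervals, the
Bioconductor convention); narrowPeak and BED files are converted at the
I/O boundary (disk coordinates are 0-based half-open). The MACS2 summit
is kept as the narrowPeak column-10 offset, so `start(gr) + peak` is the
1-based summit position. Count matrices are
`SummarizedExperiment` objects with the element `GRanges` as row ranges
and the sample sheet as column data.

## Reproducible peak retention

Peak calling with a relaxed threshold produces five call sets per mark
and cell type: two biological replicates, the pooled replicates, and two
pooled pseudoreplicates. `retain_reproducible()` keeps a pooled peak when
it is covered to at least a fraction *f* of its own length either by
peaks of both replicates or by peaks of both pseudoreplicates. Defaults
follow assay convention: *f* = 0.20 (ATAC) and 0.30 (histone marks).
Three details are deliberate:

* the denominator is the pooled peak's own length, and coverage by
  several supporting peaks is unioned, never double-counted;
* the test is anchored on the pooled peak. Whether the overlap should be
  reciprocal is genuinely ambiguous in common practice, so a
  `reciprocal` flag additionally demands that at least one supporting
  peak is itself covered to *f* by the pooled peak;
* the subsequent q-score filter (`filter_by_qscore()`) uses a strict
  inequality — −log10(q) > 4 keeps FDR strictly below 10⁻⁴ — so a peak
  exactly at the boundary is dropped.

The filter is anti-monotone in *f* and idempotent, which the test suite
asserts as properties rather than examples.

## Element construction

Promoters are TSS ± 1 kb for every transcript of the configured
biotypes (protein-coding and lincRNA by default); transcripts sharing an
identical interval collapse into one non-redundant promoter whose
representative gene is the lexicographically first (all collapsed ids
are retained). Intervals that would start before the chromosome start
are clipped with a warning.

Putative enhancers are built from ATAC peaks in five steps: q-filter
(−log10 q > 4), merge across cell types, pick per combined peak the
constituent summit with the best q (ties: leftmost summit — a
deterministic, position-independent rule), drop combined peaks touching
any promoter by ≥ 1 bp, extend the surviving distal summits by ± 500 bp
and merge overlapping windows (the merged element keeps its best-q
summit). The ≥ 1 bp promoter exclusion is intentionally stricter than
the 20 % rule used for state flags: promoter contamination of the
enhancer set is worse than losing borderline distal peaks. Peaks lacking
a summit annotation either abort the run (default) or fall back to the
peak midpoint (`missing_summit = "use-centre"`).

## State classification

For each element and cell type a mark flag is set when that mark's peaks
cover ≥ 20 % of the element (`min_overlap_frac`). The flag combination
is looked up in a truth table shipped as a versioned YAML config
(`inst/extdata/truth_tables.yaml`) rather than hard-coded, because the
mapping for a handful of combinations (H3K27ac alone; all three marks
simultaneously) is a judgement call rather than settled convention. The
shipped defaults, complete over all 8 combinations:

| H3K4me1 | H3K27ac | H3K27me3 | enhancer state |
|---|---|---|---|
| 0 | 0 | 0 | neutral |
| 0 | 0 | 1 | repressed |
| 0 | 1 | 0 | active |
| 0 | 1 | 1 | mixed |
| 1 | 0 | 0 | primed |
| 1 | 0 | 1 | poised |
| 1 | 1 | 0 | active |
| 1 | 1 | 1 | mixed |

Promoters use H3K4me3 in place of H3K4me1 and lack "primed": any
acetylated or H3K4me3-marked promoter without H3K27me3 is active, the
bivalent H3K4me3 + H3K27me3 combination (without H3K27ac) is poised,
acetylation together with H3K27me3 is mixed, H3K27me3 alone is
repressed. Users can swap the whole table by editing the YAML and
passing it through `read_truth_table()`; the classifier is a pure
function of the flags, which the suite checks by exactness over all 8
combinations and by order-permutation invariance.

`state_transitions()` tallies element flows between consecutive cell
types; its marginals equal the per-cell-type state counts by
construction, and that identity is asserted, not assumed.

## Signal quantification and differential calling

Counts at elements (or at 1-kb tiling bins restricted to peak-covered
tiles, `make_analysis_bins()`) follow featureCounts "-O" semantics: a
fragment increments every region it overlaps by ≥ 1 bp. Size factors
default to relative library depth, s_j = depth_j / geometric mean of
depths (a median-of-ratios estimator is selectable), and the normalized
value is log2(count/s_j + 1), which preserves within-sample ranks.

Differential signal between two cell types uses a negative-binomial Wald
test: the log fold change is the ratio of group means of normalized
counts with a 0.5 pseudocount, and the Wald variance comes from the
delta method under Var(K) = sμ + α(sμ)². The dispersion α is estimated
per region by method of moments and then, by default, **pooled into a
single common value across regions**. This is the one place the package
deviates from the most obvious per-region design: with two replicates
per condition, per-region moment estimates are so noisy that the Wald
test's type-I error runs at ~3× nominal, while the pooled estimate is
calibrated (the null-channel acceptance test asserts the empirical
type-I rate lies within the binomial 99 % interval of 0.05 at 2,000
regions). Per-region dispersion remains available via
`dispersion = "genewise"` for data with more replicates. The test is
deliberately simple and documented — no shrinkage, no outlier
replacement — and is **not** a DESeq2 replica; the downstream rule it
feeds is the conventional dynamic gate |log2 FC| > 1 and BH-adjusted
p < 0.05.

The contrasts that define "dynamic" are a configuration input; the
default is the consecutive pairs of the trajectory order, which covers
every branch point without testing all 15 pairs.

Dynamically active enhancers are those active in ≥ 1 cell type and
dynamic in ≥ 1 contrast, minus the constitutively active ones (active in
all six cell types), for which no trajectory information exists.
Clustering of the dynamic set runs k-means (Hartigan–Wong, 25 random
starts, `iter.max = 100`) on per-element z-scores across all 12 samples;
zero-variance rows get an all-zero profile instead of NaNs. The seed is
an explicit argument recorded in the result, making runs bit-reproducible;
k defaults to 9 for enhancers and is the user's choice elsewhere.
`rank_auc()` (Mann–Whitney with midranks) backs the evaluation of marks
as expression classifiers; AUC is invariant under monotone transforms of
the signal, which the suite asserts.

## Enhancer–gene linking

Each enhancer is assigned to the nearest TSS strictly within 100 kb of
its summit. The link statistic is Kendall's τ-b (tie-corrected, via
`stats::cor`; an independent pair-enumeration oracle checks it to 1e-12
in the tests) between enhancer H3K27ac and gene expression across the 12
samples. Significance comes from an empirical null: the τ values of the
same enhancer against all expressed genes on its chromosome, with
p = #(null τ ≥ observed)/N. Choices worth recording:

* the focal gene is excluded from its own null by default (it would
  otherwise contribute one guaranteed "equal-or-better" value);
  `exclude_focal = FALSE` restores the literal all-genes set;
* the literal count/N is used, so p = 0 is possible; `add_one` switches
  to the conventional (k+1)/(N+1);
* genes enter the null only if their mean expression exceeds
  `min_expression` (default 0, i.e. all-zero genes are excluded —
  zero-variance vectors have no defined τ and are dropped with a warning
  anyway);
* with 12 samples, τ lives on a lattice (steps of ~1/66), so
  "equal-or-better" counting carries a small conservative (upward) bias
  in p from exact ties. The null-channel uniformity check in the
  acceptance suite passes at its fixed seed; users comparing p-value
  histograms should expect the mean slightly above 0.5.

High-confidence links require τ ≥ 0.3 **and** p ≤ 0.05; boundary values
pass, matching the usual reading of "≥ / ≤".

## TF cooperativity and direct targets

`intersect_tf_peaks()` merges the peak sets of a TF trio into a combined
binding universe and labels every region with the subset of TFs binding
it (≥ 1 bp overlap), giving the 7 cooperativity classes; pairwise
co-binding significance is an upper-tail hypergeometric test with the
observed count included (the `phyper(k-1, ..., lower.tail = FALSE)`
convention, asserted against direct summation in the tests).

Regulatory potential sums a distance decay over a TF's peak summits
within 100 kb of each TSS. The decay is a config entry with default
w(Δ) = exp(−(0.5 + 4Δ)), Δ = distance/window — the BETA-style form with
weight exp(−0.5) at the TSS falling to exp(−4.5) at the window edge.
Activator/repressor predictions compare up- and down-response gene
groups against the unchanged group with one-sided Kolmogorov–Smirnov
tests, oriented so that a small p means the group is stochastically
enriched for high potential (in R: `alternative = "less"` with the group
as `x`); groups under 5 genes are flagged unreliable rather than
silently trusted. The asymptotic p is checked against a 10,000-draw
permutation oracle in the acceptance suite.

Direct up targets of a class require (i) knockout down-regulation
(log2 FC < −1, adjusted p < 0.05) in **every** member TF's knockout —
the conservative reading of class-resolved evidence — (ii) a class peak
within 100 kb of the TSS, and (iii) at least one such peak overlapping
an element that is active or mixed in the context cell type. Direct down
targets mirror this with knockout up-regulation and the requirement that
none of the nearby class peaks overlaps an active element. Missing
knockout tables skip the affected classes with a warning instead of
failing the run.

## The synthetic study and what it does (not) show

`simulate_study()` generates a complete in-silico experiment: a gene
annotation on a jittered grid (guaranteed minimum TSS spacing), 2,000
enhancers on 2 × 10 Mb chromosomes placed clear of promoters, one of
nine activity archetypes per enhancer (patterns of active cell types
along the trajectory), a background state (neutral/primed/repressed/
poised) where inactive, peak emission per the planted state's mark
flags with replicate dropout and jitter, NB counts with state-dependent
means scaled by a per-enhancer baseline and a graded latent activity per
enhancer × cell type (log-sd 0.75), expression of linked genes driven by
the same latent activity (8-fold contrast at `link_strength = 1`,
10 % of enhancers linked), and a TF trio with planted per-class direct
targets and noise-free knockout tables. A `null_structure` switch
removes all planted structure (flat means, no links) and is what the
calibration checks run on. Everything is a deterministic function of the
config seed; sub-stages draw from derived seed streams.

The generator emulates the *statistical* structure of such a study —
replicate concordance, state-dependent count means, correlated
enhancer–gene pairs, class-resolved knockout responses. It does **not**
emulate read-level artefacts (duplicates, GC bias, mappability), peak
shape, overlapping or nested real-genome element architecture, or
trans-acting correlation between unlinked genes. Passing the planted
recovery tests therefore demonstrates the pipeline's rules and
statistics are implemented correctly, not that the thresholds are
optimal for any particular real dataset.

Scales used by the validation suite were chosen to finish comfortably on
one CPU: interval oracles at 1,000 random instances; noise-free state
recovery on a 250-enhancer study; null calibration at 500 enhancers
(link p uniformity) and 2,000 regions (type-I rate); planted recovery at
the full default 2,000-enhancer study; determinism by running the entire
pipeline twice and comparing content hashes.

## Degenerate inputs and tie-breaks, collected

* malformed intervals (start ≥ end) are rejected at parse time naming
  the offending record; empty pooled peak sets warn and return empty;
* nearest-TSS ties break by smaller |distance|, then lexicographic
  gene id; summit ties by q break leftmost;
* τ is undefined (NA, with a warning) for zero-variance vectors and
  those pairs are dropped from link tables;
* k > number of elements, zero-depth libraries, missing mark/cell-type
  peak sets and non-disjoint KS groups are hard errors;
* signed TSS distances are negative 5′ of the TSS on the gene's strand;
  every threshold uses the magnitude.

## Known limitations

The NB test is unshrunk and relies on a shared dispersion, appropriate
for the generator's single-dispersion model and for quick screening, but
datasets with strong mean-dispersion trends deserve a dedicated tool.
The empirical link p is conservative under heavy τ ties (12 samples).
Cooperativity classes are binary (bound/unbound per TF); no affinity
grading. The pipeline consumes peak calls and count tables — peak
calling itself, read processing and expression quantification are
upstream of this package by design.
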