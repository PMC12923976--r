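---
title: "Discovering orphan non-coding RNAs: models, parameters and design choices"
author: "orphanRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering orphan non-coding RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumors express small RNA species that are essentially absent from
non-transformed tissue and from the extracellular RNA of healthy people.
We call these orphan non-coding RNAs (oncRNAs). Because any single oncRNA
is rare even across tumors of its own tissue, their value is collective:
the binary presence/absence vector of a catalog of oncRNAs -- an *oncRNA
barcode* -- encodes the identity of a cancer sample, and the number of
oncRNA species detectable in serum (the *oncRNA burden*) tracks how much
tumor-derived RNA is circulating. This package implements the full
analysis chain: building small-RNA loci from aligned reads, calling
cancer-emergent loci with a cascade of filters and an enrichment test,
barcode-level statistics, presence--chromatin-accessibility association,
and residual-burden survival analysis -- together with a seeded synthetic
cohort generator that plants ground truth so every stage can be verified.

```{r, eval = FALSE}
library(orphanRNA)
co <- simulateCohort(simulationConfig())
reads <- filterLowComplexity(co$reads)
disc <- reads[reads$sample_id %in%
                  co$manifest$sample_id[co$manifest$role %in%
                                            c("tumor", "normal")], ]
loci <- splitLongLoci(mergeLoci(disc), disc)
pm <- buildPresenceMatrix(loci, reads, co$manifest)
catalog <- runCascade(pm, co$annotations)
```

## From reads to loci

**Low-complexity filtering.** Reads are scored with the DUST triplet
statistic: for a read of length $L$ with $k = L - 2$ overlapping triplets
and $c_t$ occurrences of triplet $t$,

$$ \mathrm{DUST} = \frac{\sum_t c_t (c_t - 1) / 2}{k - 1}. $$

All-distinct triplets score 0; a homopolymer of length $L$ scores
$(L-2)/2$ (a 30-nt homopolymer scores exactly 14). Higher means less
complex. Reads scoring strictly above the threshold (default 3) are
removed. On this scale the default removes homopolymers and dinucleotide
repeats at small-RNA lengths while keeping essentially all random-sequence
reads; both the scale and the threshold are exposed in the configuration.
Note one subtlety at the boundary: a 15-nt dinucleotide repeat scores
exactly 3.0 and is therefore *kept* under strictly-greater removal; the
synthetic generator draws its decoys at 18 nt and above, where both decoy
families are safely above threshold.

**Merging.** Read intervals pooled over the discovery cohort (tumors and
tumor-adjacent normals) are collapsed into maximal transitively
overlapping groups, with book-ended intervals merging (gap 0, the default
of the standard interval-merge tools). Strand is carried but ignored by
default -- nothing in the calling procedure requires strand-aware merging
-- and a switch enables strand-stratified processing.

**Peak splitting.** Merged loci longer than 200 bp usually contain more
than one discrete small-RNA signal. They are split by a one-dimensional
peak caller on the pooled per-base coverage profile with the familiar
parameters height = 10, width in [15, 200], distance = 20: plateau-aware
local maxima above the height, greedy distance pruning from the highest
peak down (ties to the leftmost), prominence by the lowest saddle toward
the nearest higher point, and peak width measured where the profile
crosses `height - prominence/2`. The peak caller reports the
half-prominence crossings; sub-locus bounds are those crossings rounded
outward, clipped to the parent, with adjacent sub-loci truncated at the
midpoint between peak positions so the output is pairwise disjoint. A long
locus with no qualifying peak is discarded by default -- splitting exists
precisely to isolate well-formed small-RNA signals -- with
`keepUnsplitLongLoci` to retain them whole. The coverage signal is pooled
over all discovery samples (per-sample splitting would make locus
boundaries sample-dependent).

**Presence.** A locus is present in a sample as soon as one read overlaps
it by one base. A read overlapping several disjoint loci (possible after
splitting) increments each, since presence is defined per locus. Library
sizes come from the manifest when given and are otherwise the per-sample
total retained read weight; counts per million are
`counts * 1e6 / library_size`.

## The annotation cascade

Six stages, each only removing loci, applied in order:

1. **Biofluid atlas** -- remove loci seen in more than 0.43% of
   non-cancerous biofluid atlas samples. The default threshold can be
   replaced by the knee of the observed atlas prevalence curve
   (`elbowThreshold()`, the Kneedle rule: the point of maximum
   perpendicular distance to the chord joining the curve's endpoints; on a
   step-shaped curve this is the corner where the curve lands on its low
   plateau).
2. **Tumor-adjacent normals** -- remove loci seen in more than 10% of the
   normals of *any* tissue with at least 10 normal samples.
3. **Cancer prevalence** -- keep loci present in at least 10% of the
   tumors of at least one tissue (boundary inclusive, per "at least").
4. **Fisher enrichment** -- per tumor tissue, a one-sided Fisher exact
   test of presence in that tissue's tumors against all normal samples
   pooled; Benjamini--Hochberg correction within each tissue's family;
   keep loci with q <= 0.1 in at least one tissue.
5. **Known annotations** -- remove loci overlapping any known small-RNA
   annotation by one base or more.
6. **Non-cancerous serum** -- remove loci detected in more than one of the
   non-cancer serum samples.

Boundary conventions follow the wording of the rules: removal filters are
strictly-greater ("more than"), the retention filter is inclusive ("at
least"). The Fisher alternative is one-sided *greater* because the
selection criterion is significant *presence* in tumors; the p-value is
the hypergeometric upper tail accumulated in log space, and the odds ratio
is the unconditional $ad/bc$ (with $+\infty$ when $bc = 0 < ad$), reported
for ranking only. BH families are per tissue: tests within a tissue share
the tumor cohort, and the keep rule is "significant in at least one
tissue". Whether families should instead be pooled globally is genuinely
open; per-tissue is the default and the one the tests pin down. The three
presence filters (1, 2, 6) are independent predicates of the input
matrix, so permuting them does not change the final catalog; the catalog
records cumulative per-stage flags and survivor counts in the canonical
order regardless of application order.

## Barcode statistics

Barcodes are compared with Jaccard similarity (defined 0 for two all-zero
barcodes, which carry no identity signal). `barcodeSimilaritySummary()`
contrasts median within-group and between-group pairwise similarity per
tissue with a one-sided rank test. The tissue-of-origin baseline is a
nearest-centroid classifier under the real-valued Jaccard generalization
$\sum_i \min(x_i, c_i) / \sum_i \max(x_i, c_i)$ -- deliberately the
simplest classifier that can read a barcode, with ties resolved to the
lexicographically smallest label so degenerate all-zero barcodes behave
deterministically.

Subtype association is a per-locus one-way ANOVA screen across subtype
labels, computed row-wise (the textbook between/within decomposition,
vectorized over loci) on `log(cpm + 1)` by default, with a binary-presence
mode. Presence/absence structure makes two degeneracies common: loci with
identical values everywhere report F = 0, p = 1; loci with zero
within-group but nonzero between-group variance are flagged degenerate
rather than given an infinite F, because such a split carries no
within-group error estimate. `exclusiveCounts()` assigns each locus to the
exact set of subtype groups detecting it (UpSet semantics); the counts
always partition the catalog.

## Accessibility association

For loci with at least 5 expressing samples, accessibility scores of
expressing and non-expressing samples are compared with a one-sided
Mann-Whitney U test (higher accessibility when the oncRNA is present).
The effect size is $\log_2((\mathrm{med}_{present} + 1) /
(\mathrm{med}_{absent} + 1))$; the unit pseudocount handles zero medians.
Significance is BH-corrected at FDR 1% and the significant set is
additionally required to have a positive effect, so the reported
association is one-sided by construction. The U test is exact (from the
null distribution of U) when $n + m \le 12$ without ties and uses the
normal approximation with tie and continuity corrections otherwise; the
switch point is exposed.

## Burden and survival

The circulating oncRNA burden of a serum sample is the number of distinct
catalog species detected, per million sequenced reads. A read-count mode
(total oncRNA read CPM) is provided as an alternative quantification. The
residual burden across a treatment window is
$\Delta = N_{T3} - N_{T0}$; patients are stratified high/low at a
threshold $\tau$ (default 0, with `tauSweep()` to examine sensitivity to
the cut). Kaplan--Meier estimation and the two-group log-rank test are
delegated to the survival package behind thin validating wrappers;
multivariable regression modelling is intentionally out of scope -- the
burden table is tidy input for any standard survival tooling.

## The synthetic cohort generator

`simulateCohort()` emulates the *structure* of the discovery data, not its
sequence content. The default configuration is the condition all
package-level guarantees are stated under: 4 tumor tissues with 60 tumors
and 15 tumor-adjacent normals each, a 200-sample biofluid atlas, 30
non-cancerous sera; per tissue 75 planted tissue-specific oncRNA loci at
within-tissue prevalence 0.30 (rare-per-locus, informative-in-aggregate);
400 ubiquitous background loci at prevalence 0.90 in tumors and normals;
50 biofluid contaminant loci expressed across tumors (prevalence 0.30)
and present in 10% of atlas and serum samples -- exactly the loci the
atlas filter exists to catch; 100 loci coinciding with the known
annotation track; 5% low-complexity decoy reads (half homopolymers, half
dinucleotide repeats, 18--38 nt, on a decoy chromosome outside all planted
loci). Reads per present locus are negative binomial (mean 10, dispersion
1, floored at 1) -- the real distribution is not documented, so this is a
package choice exposed in the configuration. Locus lengths are 15--38 nt,
the small-RNA regime the caller expects. Twenty percent of true loci are
embedded as peaks inside 400-bp parent spans held together by low-depth
tiling reads, producing the >200-bp merged loci the splitter must resolve.
Reads land on the locus span with +/-2 nt jitter. One global seed fans out
to per-sample substreams keyed by a stable hash of the sample identifier,
so resizing a cohort leaves the reads of retained samples untouched.

What the generator does *not* model: genome sequence, mappability, GC
content, per-locus expression heterogeneity, batch effects, or any
coupling between loci. Passing tests therefore demonstrate that the
implementation computes its statistics correctly and recovers planted
structure under the stated noise model -- not that the thresholds are
optimal for any particular real dataset.

`simulateAccessibility()` plants a chosen fraction of accessible loci
whose score is baseline + effect x presence + Gaussian noise (floored at
0); null loci get baseline + noise regardless of presence.
`simulateSerumPairs()` plants responders who lose an exact fraction of
their T0 species at T3 and non-responders who retain theirs and gain at
least one (so stratification at tau = 0 is well defined), with
exponential survival whose rate differs by the planted hazard ratio
between the high- and low-residual-burden groups and administrative
censoring at 8 years.

## Numerical and interface choices

- **Coordinates.** On disk, BED is 0-based half-open and GFF3 1-based
  closed. In memory every interval is a `GRanges` (1-based closed), the
  container the whole Bioconductor stack dispatches on; conversion happens
  only in the readers/writers. Chromosome order is normalized with
  `sortSeqlevels` so locus order does not depend on file order.
- **Containers.** The locus-by-sample matrices live in a
  `PresenceMatrix`, a `RangedSummarizedExperiment` with `counts` and
  `presence` assays whose validity ties presence to counts >= 1; the
  cascade output is an `OncRNACatalog` carrying per-stage cumulative
  flags (nested by construction), the per-tissue enrichment table and
  survivor counts.
- **Fisher in log space.** Upper-tail hypergeometric mass is summed from
  log densities with a log-sum-exp, so extreme tables (p down to 1e-300)
  keep full relative accuracy.
- **Ties.** Peak candidates tie to the leftmost position; classifier ties
  to the lexicographically smallest label; Mann-Whitney ties use midranks
  with the tie-corrected variance.
- **Problem sizes.** The packaged checks run the default cohort (530
  samples, ~1.3 million reads), a 500-locus null cohort for Fisher
  calibration, and 1000-replicate log-rank size/power simulations at 60
  patients per arm -- sizes chosen to make the binomial error bars on the
  measured rates small relative to the margins being asserted.

## Known limitations

- The caller assumes disjoint loci; quantification after splitting
  re-counts a read that spans a sub-locus boundary once per sub-locus.
- The elbow rule returns the corner value on step-shaped prevalence
  curves; on smooth convex curves the knee is interior. It warns rather
  than guesses when the curve is flat.
- ANOVA on binarized presence is a chi-square-like screen at heart;
  the F approximation degrades for very unbalanced subtype groups.
- Survival utilities cover two-group comparison only; treatment arms,
  competing risks and multivariable adjustment are out of scope.
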