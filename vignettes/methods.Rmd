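---
title: "Methods: exact trial statistics and the HER2 whole-slide patch pipeline"
author: "trialpatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact trial statistics and the HER2 whole-slide patch pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialpatch)
```

`trialpatch` collects the bespoke translational computations around a
single-arm anti-HER2 antibody--drug-conjugate (ADC) trial in metastatic
breast cancer: the exact binomial design and response-rate machinery, a
whole-slide HER2 immunohistochemistry (IHC) patch-clustering pipeline, the
post-calling rules for paired baseline/resistance tumor biopsies, and the
multiplex-immunofluorescence microenvironment statistics. Every stage is
driven and verified by seeded synthetic-data generators with recorded
ground truth, so the full pipeline is testable offline, without access to
patient images or controlled-access sequencing data.

This vignette explains the models and procedures, their assumptions, the
tunable parameters, the numerical choices, and what the synthetic data do
and do not establish about behaviour on real data.

## Exact single-arm design statistics

### Single-stage exact design

A single-stage phase 2 design is specified by an unacceptable response
probability $p_0$, a target $p_1 > p_0$, a one-sided type-I error
$\alpha$ and a required power $1-\beta$. `ahern_design()` finds the
smallest sample size $n$ admitting a threshold $r$ such that, for
$X \sim \mathrm{Bin}(n, p)$,

$$P(X \ge r \mid n, p_0) \le \alpha
\quad\text{and}\quad
P(X \ge r \mid n, p_1) \ge 1-\beta,$$

with $r$ the smallest such threshold at that $n$. Tails are computed with
the regularized incomplete beta function behind `pbinom()`; no normal
approximation is involved. The search iterates $n$ upward from 1 and, at
each $n$, scans $r$ downward from $n$; a configurable ceiling (default
1000) guards against infeasible specifications. The two hypothesis sets
used in the package's tests, $(0.30, 0.45, 0.05, 0.80)$ and
$(0.20, 0.40, 0.05, 0.85)$, give $(n, r) = (67, 27)$ and $(40, 13)$.

### Two-stage rule evaluation

For the dual-endpoint two-stage design the package evaluates a stated
rule (`two_stage_rule(n1, s1_min, n_total, r_final)`): stop for futility
when stage-1 successes fall below `s1_min`; otherwise the trial continues,
and at the final analysis the regimen is promising iff successes reach
`r_final`. The *search* for an optimal two-stage rule is deliberately not
implemented: the optimality criterion behind such designs (expected sample
size under which hypothesis, dual-endpoint weighting) varies by reference
and the evaluation of a given rule is all the downstream analyses need.
At an interim look (no final count supplied) the decision is `"continue"`;
passing `final_analysis = TRUE` turns an absent final count into an error
instead, so batch re-analyses cannot silently skip the final test.

### Exact confidence intervals and response rates

`clopper_pearson(k, n, level)` inverts the exact binomial test via beta
quantiles: the lower bound solves $P(X \ge k \mid p) = (1-\text{level})/2$,
i.e. $\mathrm{qbeta}((1-\text{level})/2;\, k,\, n-k+1)$, and the upper
bound is $\mathrm{qbeta}((1+\text{level})/2;\, k+1,\, n-k)$, with the
conventions $k=0 \Rightarrow \mathrm{lo}=0$ and
$k=n \Rightarrow \mathrm{hi}=1$. The exact interval is conservative: its
coverage is at least nominal, which the test suite verifies by
simulation. `confirmed_orr()` counts confirmed complete/partial responses
over *all* records of a cohort — non-evaluable patients stay in the
denominator, matching full-analysis-set conventions. Printed percentages
round half away from zero to one decimal and drop a trailing `.0`.

## The whole-slide HER2 patch pipeline

The pipeline turns a cohort of brightfield HER2 IHC slides into per-slide
cluster-proportion profiles and a cluster--response association table.

### Tissue detection

Each slide is downsampled by a factor of 8 (block means), converted to
grayscale (Rec.601 luma), and flattened by subtracting a local 30 x 30
average so the result is near-zero-mean. Texture is then scored with
Law's spot kernel: the separable S5$^\top$S5 convolution
(S5 $= (-1, 0, 2, 0, -1)$) followed by a 15 x 15 moving average of
absolute responses. The energy map is binarized at 20, eroded by a disc
of radius 6 (one less than the energy-window radius — this compensates
the filter's known support dilation, which otherwise pushes contours
5--6 downsampled pixels past the true tissue edge; the radius was
calibrated so boundaries sit without bias on synthetic tissue discs of
known extent), interior holes are flood-filled, and 4-connected
components with area at most 1,500 downsampled pixels are discarded.
Numerical details: the even 30 x 30 window has no centre pixel, so the
two opposite anchorings are averaged, keeping the filter symmetric; all
filters use reflect padding, so a slide whose field is entirely tissue
yields an all-tissue mask rather than an eroded frame.

### Patch extraction

The full-resolution slide is tiled by non-overlapping 64 x 64 px squares
anchored at pixel (0, 0); partial tiles at the right/bottom edge are not
emitted. A tile is kept when at least 50% of its footprint lies in the
tissue mask (and in the region-of-interest polygons, when provided —
ROI-free slides simply skip that conjunct; there is no separate code
path). Black and white tiles are then discarded: a tile is dropped when
strictly more than 70% of its $64 \cdot 64 \cdot 3$ channel values are
below 2, or strictly more than 80% are above 250. Counting channel
values jointly (rather than per-pixel luminance) was chosen because the
rule's thresholds are channel-value thresholds; the boundary behaviour
is pinned by tests.

### Descriptors

The default, fully deterministic descriptor concatenates per tile:

* hematoxylin and DAB optical-density statistics — mean, s.d., and the
  0.1/0.25/0.5/0.9 quantiles of the per-pixel ODs after stain unmixing
  (the 0.75 quantile is deliberately omitted: it sits on the
  nuclei/background boundary fraction and contributes mostly sampling
  noise);
* four Law's texture energies (E5E5, S5S5, L5E5, L5S5) of the zero-mean
  grayscale tile;
* the nuclei-density proxy: the number of segmented, deduplicated nuclei
  in the tile (see the morphometrics section). Nucleus shape means are
  *not* part of the descriptor — with a handful of nuclei per tile their
  per-tile means are dominated by noise and dilute the cluster geometry.

Deep descriptors (e.g. a truncated ResNet50 emitting 1,024 features) are
supported through `descriptor_plugin()`: any deterministic
fixed-dimension tile function satisfies the same contract. No network
weights ship with the package.

Features are pooled over all slides of a cohort and standardized to mean
0 / s.d. 1 per feature (`normalize_features()`); features with s.d.
below $10^{-12}$ are dropped (not divided by ~0) and reported.

### Clustering and model selection

`minibatch_kmeans()` implements Sculley-style mini-batch k-means:
k-means++ initialization, batches of 1,024 (capped at the number of
patches), per-centre learning rates $1/\text{count}$, at most 100 batch
updates, and early stopping when centres move less than $10^{-6}$ on
average. Ten independent starts are run on substreams of the given seed
and the fit with the lowest within-cluster sum of squares is kept;
everything is deterministic given the seed. Empty clusters are reseeded
to the point farthest from its centre. The batch size, iteration cap and
start count are package choices (the underlying method reference leaves
them open).

The number of clusters is selected over k = 7..12 by the Davies--Bouldin
index,

$$\mathrm{DB} = \frac{1}{k} \sum_i \max_{j \ne i}
\frac{S_i + S_j}{M_{ij}},$$

with $S_i$ the mean distance of cluster members to their centroid and
$M_{ij}$ the centroid separation; ties break toward smaller k. The
tests cross-check this implementation against an independent
direct-formula implementation.

### Profiles and association

For slide $i$ with $N_i$ patches and patch labels
$L_{n_i} \in \{0..k-1\}$, the profile is
$$V_i[c] = \frac{1}{N_i} \sum_{n_i=1}^{N_i} 1\{L_{n_i} = c\},$$
a point on the k-simplex. Association with confirmed response uses a
two-sided Mann--Whitney U test per cluster on the per-slide proportions
(exact null when both groups have at most 8 slides and no ties; normal
approximation with tie and continuity corrections otherwise) and
Benjamini--Hochberg adjustment across the k clusters. The direction of
the median difference (responders minus non-responders) is reported
alongside p and q.

## Nuclei morphometrics

Stain separation follows Beer--Lambert optical density:
$\mathrm{OD} = -\log_{10}((I + 1)/I_0)$ per channel (the offset of one
8-bit count avoids $\log 0$), projected by least squares onto unit
hematoxylin and DAB OD vectors (defaults are the standard published
brightfield vectors; bases closer than 10 degrees are rejected).
Negative projections are clipped to zero.

Nuclei are segmented classically: Otsu threshold on the hematoxylin OD
map, distance-transform watershed (tolerance 1) to split touching
nuclei, then shape filters — perimeter within [8, 200] px and
circularity $4\pi A / P^2 \ge 0.15$ by default. These thresholds are
configurable and recorded in the output; the defaults were chosen to
pass nuclei of radius 2--10 px while rejecting specks and ribbons. This
classical segmenter deliberately stands in for trained neural
segmentation: the downstream, rule-defined steps are the reproducible
part. Those rules are implemented exactly: a nucleus whose centroid lies
strictly within 20 px (6.5 um at 0.325 um/px) of an already-kept nucleus
is discarded (greedy scan ordered by descending area, then raster order
— the processing order is otherwise unspecified, and a deterministic
order makes dedup idempotent); per-nucleus DAB intensity is the mean DAB
OD within a 30-um-diameter disc centred on the centroid (converted to
the nearest odd pixel diameter, clipped at image borders); per-patch
summaries average nuclei whose centroid falls in the half-open patch
footprint, and the nucleus count per patch is the cell-density measure.

## Paired-biopsy genomic rules

The package consumes variant calls, pileup counts and copy-number
segments produced upstream; it implements only the paired-timepoint
decision rules.

* **Coverage-dependent rescue** (`rescue_mutations()`): a mutation
  retained in one timepoint is also called in the paired sample when the
  pileup there shows at least 1 supporting read below coverage 100, 2
  from 100 to below 500, and 3 at 500 and above. Coverage exactly 500 is
  undefined in the source rule ("< 500" then "> 500"); the package
  applies the conservative 3-read requirement and records every decision
  in an audit table (position, coverage, threshold, outcome), so each
  rescued call's provenance is reconstructable.
* **Unmatched-germline discard**: for patients without a matched normal,
  any variant flagged germline at either timepoint is removed from both
  call sets.
* **Copy-number filtering** (`filter_cna()`): per sample and gene,
  the primary-run segment is used unless the gene is a driver and the
  sensitive-run segment is shorter than 3 Mb or more than three times
  shorter; segments spanning 10 Mb or more are discarded (only focal
  events remain); and only high-level amplifications and homozygous
  deletions survive, plus medium-level amplifications on oncogenes.
  Hemizygous deletions are excluded by default but exposed as a switch
  (`keep_hemizygous`), since their status in downstream displays is
  ambiguous. Gene--segment association uses any-base overlap with
  1-based inclusive coordinates; input order never affects the result.
* **Acquired alterations** (`call_acquired()`): a gene is acquired when
  no baseline sample is altered and at least 2 resistance samples are
  (at least 3 when every resistance event is a copy-number event).
  "Altered" means a driver mutation or a surviving CNA event. The driver
  and oncogene lists are supplied as a two-column TSV; the package ships
  a small synthetic list (`driver_genes_synthetic.tsv`) standing in for
  curated databases, with the same schema.

## Microenvironment statistics

Cell tables carry coordinates in micrometres and one logical column per
marker. Densities are counts of cells satisfying a conjunctive marker
query divided by the analyzed tissue area (supplied explicitly — the
trained tissue classifier used upstream is not reproduced; an area can
also be taken from any polygon the user computes). Distances to the
nearest CK+ (tumor) cell are Euclidean; CK+ cells measure to the nearest
*other* CK+ cell, and binning is half-open with a first bin of 0--10 um,
so "tumor-cell-proximate" cells are those strictly below 10 um.

Paired pre/on-treatment comparisons use the two-sided Wilcoxon
matched-pairs signed-rank test with Wilcoxon's original zero-handling:
zero differences are dropped before ranking (the convention is recorded
in the output; the alternative Pratt convention is not offered). The
exact null is used up to 25 non-zero differences when their magnitudes
are untied; otherwise the normal approximation with tie and continuity
corrections. All-zero difference sets return p = 1 with a warning. The
batch variant adjusts across marker/bin families with
Benjamini--Hochberg.

## Synthetic-data generators

All generators are pure functions of (config, seed). A master seed
spawns per-artifact substreams through a Lehmer-style mixing function
(`derive_seed()`), so regenerating one artifact never shifts another.

### IHC cohorts

`gen_ihc_cohort()` emulates ROI-cropped tumor fields: 512 x 512 px
slides at 0.325 um/px, tiled by patch-aligned 64 px region cells, each
cell drawn from one of eight tissue classes. The palette crosses the
HER2 IHC phenomenology — negative (OD 0.02), moderate diffuse (0.35),
strong diffuse (0.90) and strong membranous staining (DAB confined to a
3 px annulus around each nucleus) — with two cell densities (6 and 16
nuclei per cell). Class 1, the "stroma-like" class, is HER2-negative
with moderate density. Rendering is forward Beer--Lambert: hematoxylin
OD 1.0 inside nuclei over a faint 0.06 tissue background, the class's
DAB field, transmitted intensity $I = I_0 10^{-\mathrm{OD}}$ with
$I_0 = 240$, additive Gaussian sensor noise (s.d. 2 counts), rounding
and clipping to 8 bits. Nuclei radii are Gaussian (per-class mean, s.d.
0.6 px); counts per cell are drawn as a rounded Gaussian (s.d. 1.0)
rather than Poisson — packed epithelium is underdispersed relative to
complete spatial randomness — and positions sit on a jittered lattice
for the same reason. Responders draw cells from the uniform mixture;
non-responders carry an absolute excess of 0.15 of the stroma-like
class, the others rescaled proportionally. Neither the source trial nor
any published table fixes this excess; 0.15 was chosen once as a
plausible planted effect — large enough that a 12-versus-12 cohort has
sampling noise well below it, small enough that the class remains a
minority component — and is not revisited.

The disc mode (`shape = "disc"`) places the tissue on blank glass with a
known boundary, and an optional textured speck supports the minimum-area
tests; ground truth (per-cell class, nuclei, tissue support, mixtures)
is returned alongside every slide.

What the generator does *not* emulate: real chromatin texture, stain
variability between slides, scanner artifacts, non-rectangular region
geometry, or the empty-patch regime of sparse biopsies. Passing tests
therefore demonstrate that the pipeline recovers planted structure of a
realistic magnitude under controlled imaging physics — not that eight
clusters or any specific cluster--response association exists in real
cohorts.

### Paired variant tables

`gen_paired_variants()` emits, for 11 patients, calls at both
timepoints, pileup counts in the paired sample at every called position,
and SEG-like segment tables. It plants: shared clonal passenger
mutations across the three coverage regimes; a full 5 x 3 rescue
boundary grid (coverages 99/100/499/500/501 by 1--3 supporting reads) as
baseline-only calls; acquired driver mutations in 2 and 3 resistance
samples; a CNA-only gene in exactly 3 resistance samples (acquired under
the CNA-only rule) and one in exactly 2 (not acquired); a gene blocked
by a single baseline alteration; germline contaminants in the unmatched
patients; and the copy-number filter boundary constructions (12 Mb
primary with 2.5 Mb sensitive replacement, 9.9 Mb versus 10 Mb
deletions, medium amplifications on an oncogene and a non-oncogene).
The truth list records every planted case so the rules can be scored
without rerunning the generator.

### Trial outcomes and cell maps

`gen_trial_outcomes()` draws per-cohort Bernoulli confirmed responses
(defaults: assessable sizes 68/72/37 with response probabilities
0.706/0.375/0.297) with RECIST categories and target-lesion changes
consistent with the response. `gen_cell_maps()` draws spatial Poisson
processes per phenotype over a 1 mm^2 field (baseline intensities: CK
250, CD3 150, CD8 80, CD4 70, CD68 60, PD-1 40, FoxP3 20 cells/mm^2,
PD-L1 positive in 30% of CK+ and 10% of immune cells), log-normal
patient-level intensity multipliers (s.d. 0.3) shared between
timepoints, and a planted multiplicative on-treatment change of the
CK+/PD-L1+ density (default 0.3, emulating a treatment-induced drop of
tumor PD-L1; set to 1 for null calibration).

## Problem sizes and verification scales

The package's own verification runs at scales chosen to exercise every
stage meaningfully: the end-to-end imaging check uses 10 replicate
cohorts of 24 slides (12 per response group) at 512 x 512 px and
requires the Davies--Bouldin selection to return k = 8 in at least 8 of
10 replicates and the planted excess class to rank first by q in at
least 9 of 10; the null calibration of the paired microenvironment test
uses 200 replicate cohorts of 18 pairs (uniformity checked by a
Kolmogorov--Smirnov test) plus 100 effect-size-0.3 replicates for power;
oracle equivalences (Mann--Whitney enumeration, step-up BH, quadratic
nearest-neighbour scan, binomial-test grid inversion) run at the sizes
where exhaustive computation is cheap.

## Known limitations

* The nuclei segmenter is a classical stand-in; absolute counts on real
  slides will differ from trained segmenters, though the downstream
  rules are segmenter-agnostic.
* The handcrafted descriptor is not a learned representation; on real
  slides a deep extractor plugged in through `descriptor_plugin()` is
  expected to separate tissue phenotypes it cannot.
* Davies--Bouldin selection is sensitive to cluster-geometry anisotropy;
  near-flat landscapes across k are reported in `select_k()$db` and
  should be inspected rather than trusted blindly.
* Exact Mann--Whitney and signed-rank nulls are unavailable under ties;
  the implementations fall back to corrected normal approximations, as
  recorded in their `method` fields.
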