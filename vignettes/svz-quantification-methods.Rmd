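---
title: "Quantifying marker expression in the primate SVZ niche: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marker expression in the primate SVZ niche: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svzquant)
```

## What the package measures

The adult primate subventricular zone (SVZ) is a neurogenic niche whose
cellular composition changes after brain ischemia. Characterising that
response requires counting, for thousands of cells on tissue sections,
which combinations of markers each cell expresses — for example, what
fraction of apelin-receptor (*APLNR*) FISH-positive cells in the
subependymal layer (SEL) also stain for GFAP, VIM or GLUT1 — and, at the
transcriptome level, which genes change between sham-operated and
ischemic animals.

svzquant implements the three quantification stages of that analysis:

1. **Digital image cytometry** of multi-channel wide-field fluorescence
   stacks: all-in-focus projection, non-local-means denoising, top-hat
   filtering by morphological reconstruction with granulometry-derived
   structuring elements, DAPI nuclear segmentation with declumping,
   restricted dilation to cellular masks, two-step Z-score/Li channel
   thresholding, ROC-calibrated per-cell positivity calls, and
   co-expression matrices.
2. **Four-level grading of colorimetric ISH**: per-cell precipitate fill
   fractions, level 0–3 grades, level-2+3 ratios within anatomical
   regions of interest (RoIs), fold changes between conditions, and the
   assignment of genes to induction groups 1–9 from per-RoI visual
   scores.
3. **Paired differential expression**: RPKM normalization, a paired
   t-test across the 9 sham / 9 ischemic sample pairs, a
   negative-binomial test with batch adjustment, a combined three-part
   call, and a permutation-based FDR estimate.

A synthetic-data module generates inputs for all three stages with exact
ground truth, so the whole chain is testable without any external data.

## The image cytometry chain

### Projection and denoising

Z-stacks are collapsed to one all-in-focus plane before any measurement.
The default `best_focus_manifold` method of `project_stack()` scores each
image tile by its intensity variance per slice, picks the best slice per
tile, smooths the resulting slice-index map and samples each pixel from
its selected slice. This is intentionally a simple surrogate for full
smooth-manifold extraction: the acceptance surface of the workflow is
per-cell calls, and a test asserts those are robust to switching between
`best_focus_manifold` and plain `max` projection.

Denoising uses non-local means (`denoise_nlm()`; patch radius 3 px,
search radius 10 px). The filtering strength `h` defaults to 0.8 times a
robust noise estimate obtained from the median absolute Laplacian
response (`estimate_noise_sd()`), so it adapts per channel without
manual tuning. The order is fixed: projection first, then denoising, and
all downstream arithmetic operates on floating-point copies.

### Background suppression: top-hat by reconstruction

A plain top-hat subtracts an opening-based background estimate, but dark
blotches (vessel lumina, tissue folds) bias that estimate. The filter
implemented in `modified_tophat()` therefore first applies a *closing by
reconstruction* with the same structuring element (SE), which fills dark
structures narrower than the SE, and then subtracts the opening-based
background of that closed image:

$$T = \max(C - \gamma^{rec}(C),\, 0), \qquad C = \phi^{rec}(I)$$

where $\phi^{rec}$ and $\gamma^{rec}$ are closing and opening by
reconstruction. Subtracting from the *closed* image (not the original)
means dark variations are absent from both operands, so the output
contains only bright structure standing above the background and is
invariant to constant intensity offsets. Reconstruction operators are
used instead of plain structural filters because they restore the exact
shape of every surviving structure (no SE-shaped artefacts). The
implementation is a hybrid raster/queue reconstruction in C++
(8-connectivity), verified pixel-exactly against a naive
iterate-to-stability oracle.

### Structuring-element size from granulometry

The SE radius is the filter's one size parameter. `granulometry()`
computes the pattern spectrum — intensity volume lost per SE radius as
successive openings by reconstruction remove structures of each size —
and `select_se_radius()` picks the smallest radius strictly above the
dominant spectrum peak, so structures at the modal size survive the
filter. Two refinements:

* For punctate FISH channels the peak search is capped (default 5 px),
  since occasional large autofluorescent structures must not inflate
  the SE.
* For batch calibration (`calibrate_se_radii()`), the reference size is
  the edge of the spectrum's *support* rather than its mode
  (`rule = "support"`). On tissue, stains of adjacent cells coalesce:
  dense cytoplasmic staining or touching nuclei form patches larger
  than any single cell, and an SE sized to the single-cell mode would
  push those patches into the background estimate and erase them. The
  support rule sizes the SE past the largest appreciable structure
  scale. On fields of identically sized compact objects the two rules
  agree, which is how the selection contract is tested.

SE radii are calibrated once per *channel class* on a calibration field
and reused across a batch, not re-estimated per image.

### Cellular masks

Nuclei are segmented from the top-hat-filtered DAPI channel: Li
threshold, hole filling, then a watershed on the Gaussian-smoothed
distance transform to split touching nuclei, and a minimum-area filter
(default 10 µm²) for debris. The smoothing sigma default is 1 µm; the
watershed tolerance default (0.2 px of distance) was chosen on synthetic
touching fields as the value that splits adjacent nucleus pairs without
fragmenting isolated nuclei.

`restricted_dilation()` grows each nuclear label outward by up to 3 µm
(configurable) to form the cellular mask. Distances are exact Euclidean;
a pixel joins the nearest nucleus, so growth halts at the equidistant
frontier between neighbours and cellular masks are disjoint by
construction. Equidistant ties are resolved by the geometric order of
nucleus centroids, making the partition independent of label
enumeration order (a property test permutes labels and compares
geometry). RoI restriction (`apply_roi()`) keeps cells whose nuclear
centroid falls inside a user-supplied polygon — in real use the band
below the ependymal layer is drawn by the operator; synthetic tests use
the full frame.

### Thresholding and per-cell calls

Channel thresholding is two-step, in the order gate-then-threshold:

1. `zscore_gate()` replaces each pixel by its Z-score over the whole
   frame and zeroes everything at or below Z = 1, i.e. below the mean
   plus one standard deviation. Surviving pixels keep their original
   intensities. Statistics are computed frame-wide because the gate runs
   before any mask exists. A constant frame gates to all zeros.
2. `li_threshold()` computes Li's minimum cross-entropy threshold on the
   surviving intensities. The gate's zeros are excluded from the fit —
   they would otherwise dominate the histogram and collapse the
   criterion. The minimiser is found exactly (vectorised search over all
   candidate gray levels) and is tested against an independent
   brute-force evaluation of the criterion.

Each cell's *area fraction* is the share of its compartment mask covered
by the binarised signal: nuclear antigens (and DAPI) are scored in the
nuclear mask, cytoplasmic and FISH signal in the cellular mask (these
compartment assignments are configuration defaults). A cell is called
positive for a channel when its area fraction reaches the channel's
cutoff, boundary inclusive (`f >= c`). Cutoffs are calibrated by ROC
analysis against expert labels (~300 cells): `calibrate_cutoff()`
maximises Youden's J over all midpoints between consecutive observed
fractions, ties resolved toward the smallest cutoff. In tests the
"expert" is the generator's ground truth; in real use the labels come
from a researcher's CSV. A single area-fraction cutoff per channel is
used as the decision rule.

`coexpression_matrix()` aggregates calls into marginal positivity
percentages and the conditional matrix M[a, b] = % of a-positive cells
that are b-positive. Cells with any invalid call (zero-area compartment)
are excluded from numerator and denominator; a marker with zero positive
cells yields an undefined (NA) row rather than zeros.

## Colorimetric ISH grading

`detect_colorimetric_cells()` handles scanned chromogenic ISH images
(dark precipitate on pale cell footprints, bright background). Intensity
is inverted, footprints are cut at a robust threshold above the inverted
background mode, split by a distance-transform watershed, and the
precipitate is binarised by one global Li threshold over all footprint
pixels. The threshold is accepted only if the two intensity classes it
separates differ by at least 5 robust deviations of the image noise;
otherwise the field is treated as precipitate-free — without this guard
a field of entirely level-0 cells would have its noise split into
spurious "precipitate".

Levels follow the qualitative definitions — level 3 filled, level 2
partially filled, level 1 scattered minute particles, level 0 nothing —
operationalised on the precipitate area fraction f with bin edges 0,
0.3 and 0.8 (`grade_cell()`). Only the f = 0 and f = 1 anchors are fixed
by the definitions; the interior edges are this package's calibration
and are exposed as a parameter. RoI quantification is the ratio of
level-2+3 cells to all cells in the RoI, and fold change is the ratio of
those ratios between ischemic and control; a zero control ratio is
flagged as induced-from-zero rather than divided by.

Genes are assigned to induction groups 1–9 from per-RoI visual scores
(0–3) in control and ischemic tissue. "Strongly induced" is
operationalised as ischemic score ≥ 2 *and* an increase of ≥ 1 over
control (both constants configurable; the underlying grouping is
qualitative). The induced-RoI set is matched against the group
definitions in order (all four RoIs; EL+SEL+STR; EL+SEL+CSVZ;
EL+CSVZ+STR; EL+SEL; EL+STR; EL; STR), with everything else falling
through to group 9. The mapping is total: every profile receives exactly
one group.

## Paired differential expression

The design is 2 conditions × 3 subjects × 3 adjacent tissue fragments
(9 vs 9, fragments paired across conditions by index). Two independent
tests are combined:

* **Paired t-test** on RPKM values
  (RPKM = counts × 10⁹ / (length × total mapped reads), with the
  per-sample total taken over annotated genes). Differences are taken
  within (subject, fragment) pairs; zero-variance differences get p = 1
  (conservative).
* **Negative-binomial Wald test** on raw counts — an openly independent
  DESeq-style implementation: median-of-ratios size factors,
  method-of-moments dispersions within condition-by-subject replicate
  groups (so between-animal differences do not inflate them), a robust
  parametric mean-dispersion trend fitted through per-bin medians, and
  per-gene shrinkage as the log-space average of gene-wise and trend
  values. The Wald test comes from an NB log-linear model with
  condition and subject (batch) terms, fitted by IRLS in C++ and
  verified against R's `glm.fit` at fixed dispersion. Numerical
  agreement with any historical package is a non-goal; a test checks
  rank agreement of p-values with DESeq2 on simulated data.

A gene is called UP when both p-values are below 0.05 and the log2 fold
change exceeds 0.5, DOWN symmetrically below −0.5 (signed-symmetric
reading of the threshold), NS otherwise; all three thresholds are
parameters. The fold change entering the call is computed from condition
means of *size-factor-normalised* counts (pseudocount 1). The
normalisation choice matters: a fold change on total-count-normalised
RPKM inherits a composition bias — when differential genes shift a
noticeable share of the library, every null gene's RPKM shifts in the
opposite direction, which pushes a one-sided excess of null genes across
the ±0.5 threshold and made the permutation FDR understate the
truth-based false discovery proportion by about threefold in our signal
simulations. Median-of-ratios normalisation removes that bias, and the
count normalisation is the one the NB stage already uses. Mean RPKM per
condition is still reported per gene.

**Permutation FDR.** The condition labels are permuted by independent
swaps within each of the 9 pairs — the subject-respecting permutation
group of a paired design. The 2⁹ = 512 distinct swap patterns are fewer
than the 1000 permutations used at study scale, so patterns are sampled
uniformly *with replacement*. For each permutation the entire criterion
(both tests and the fold-change threshold) is re-applied, and the FDR
estimate is the median significant count across permutations divided by
the significant count on the real labels; zero real significant genes
yield a flagged undefined estimate. The estimate is a ratio of small
counts under the null, so validation compares medians across simulation
seeds rather than single draws.

`fisher_enrichment()` supplies the two-sided Fisher's exact test used to
compare DE gene sets against cell-type expression profiles; it is a thin
wrapper over `fisher.test()` on the 2×2 overlap table, tested against an
exhaustive hypergeometric tail sum.

## The synthetic-data module

Every stage is validated against generated data whose ground truth is
recorded *as realized draws* (the sampled marker combinations, levels and
fold changes — not just their target probabilities), so tests compare
against the draw and are free of sampling ambiguity. Determinism is
bitwise: the same spec and seed reproduce identical images and tables.

**Fluorescence fields** (`generate_fluorescence_field()`): round nuclei
with truncated-normal radii (default mean 3 µm), placed by random
sequential adsorption; a configurable fraction is placed edge-to-edge
against an earlier nucleus to exercise declumping. Each cell draws its
marker combination from the co-expression table. DAPI fills every
nucleus; nuclear antigens fill positive nuclei; cytoplasmic antigens
fill the cell's cytoplasmic *territory* — the 3 µm annulus clipped
against neighbours by the same nearest-nucleus partition the analysis
uses, since real cytoplasm does not interpenetrate; FISH channels render
blurred puncta (Poisson count, default mean 14) in that territory.
Stains carry multiplicative texture with a correlation length of 0.8 µm
and 45 % contrast — chromatin granularity and cytoskeletal filaments are
not flat, and spatially correlated texture survives the optical blur
where white noise would average out. Background adds a gradient plane,
dark blotches and bright blobs (low-frequency Gaussian bumps, exercising
the dark-variation suppression of the top-hat), then Gaussian noise,
clipped and rounded to 16-bit. The default field is 768×768 px at
0.325 µm/px with 500 cells, a realistic SEL density; cell density and
nucleus size are configuration values, as the tissue's true values are
not fixed by the analysis.

`sel_reference_field_spec()` encodes the reference SEL panel — APLNR
(FISH) with GFAP, VIM and GLUT1 — with marginal P(APLNR+) = 0.60 and
conditionals P(GFAP|APLNR) = 0.75, P(VIM|APLNR) = 0.41,
P(GLUT1|APLNR) = 0.15, the APLNR-negative rates set so that the GFAP
marginal is 0.54 and 98 % of GLUT1+ cells are APLNR+. The antibody
markers are conditionally independent given APLNR status; the published
pairwise fractions come from separate co-staining experiments and are
not jointly consistent, so a single joint table can only embed one
consistent subset of them.

**Colorimetric fields** (`generate_colorimetric_field()`): pale
footprints on a bright background at 0.501 µm/px (slide-scanner
resolution); levels drawn from the configured proportions, fill
fractions from per-level ranges that must be ordered and non-overlapping
(defaults 0.06–0.24, 0.36–0.72, 0.88–1.0, leaving margins around the
grading edges so that detection noise does not straddle a bin boundary —
the generator's level semantics, not a tuned quantity). Level ≥ 2
precipitate is a concentric fill covering the drawn fraction; level 1 is
scattered ~1-px particles.

**Count matrices** (`generate_count_matrix()`): NB counts around
condition × subject means; log-normal baseline abundances; per-gene,
per-subject batch effects (log2 sd 0.25) shared by both members of a
pair — exactly the nuisance the paired analysis removes; true DE genes
(fraction, sign mix and magnitude distribution configurable, all
magnitudes above the call threshold by construction); library sizes
drawn from 0.8–1.6 million reads. The simulated libraries are smaller
than typical study-scale libraries; per-gene means are what matter to
the tests. Dispersion 0 switches to the Poisson limit.

What the generator does *not* emulate: realistic optics (PSF, chromatic
shift), tissue autofluorescence, 3-D structure, gene-gene correlation,
and transcript-level effects. Passing tests therefore demonstrate that
the algorithms recover truth under the stated statistical structure, not
that they are robust to every property of real sections.

## Numerical choices and degenerate inputs

* Reconstruction uses 8-connectivity; preconditions (marker under/over
  the mask) are checked with a relative tolerance of 1e-9.
* Grayscale erosion/dilation ignore out-of-frame pixels (padding with
  the image extremum), so borders are not darkened or brightened.
* A flat marker below a flat mask is a fixed point of reconstruction by
  dilation: the output equals the marker, as the definition requires.
* `li_threshold()` requires at least two distinct positive values and
  asks for a manual threshold otherwise; `segment_nuclei()` returns an
  empty label map with a warning on an empty foreground.
* Zero-area compartments yield NA area fractions and exclude the cell
  from co-expression counts; a zero control ratio flags the fold change
  instead of dividing.
* Sub-seeds for multi-part simulations stay below 2³¹ − 1.

## Problem sizes used in the validation suite

The test and acceptance runs use 768² px fields with 500 cells (512²
with ~200 cells for unit tests and SE calibration), 10 simulation seeds
for the end-to-end co-expression recovery, 200-cell colorimetric fields,
and 2000-gene count matrices with 60–200 permutations per FDR estimate
(down from 1000 at study scale, which only narrows the median's
Monte-Carlo error). These sizes were chosen so the full suite exercises
every stage at realistic density while remaining routine to run on a
laptop.

## Known limitations

* The projection is a tile-variance surrogate, not a smooth-manifold
  extraction; fields whose focus surface varies faster than the tile
  size will blend slices.
* The single global Li threshold per channel assumes one intensity
  population of positive signal; strongly bimodal staining within one
  channel would need per-region thresholds.
* The NB test is asymptotic (Wald); at very low counts its p-values are
  approximate, which the conservative combined criterion absorbs.
* The permutation group of a 9-pair design has only 512 elements, which
  bounds the resolution of the FDR estimate at about 1/512 per
  permutation quantile.
* Grading bin edges (0.3, 0.8) are a calibration, not a measured
  property of any particular chromogen; `detect_colorimetric_cells()`
  exposes them, and an expert-labelled fixture can be used to refit
  them.
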