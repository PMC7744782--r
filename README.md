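# svzquant

Quantitative image cytometry and expression profiling of the primate
subventricular zone (SVZ) neurogenic niche.

## The problem

After transient brain ischemia, the composition of the primate SVZ —
the stem-cell niche lining the lateral ventricle — changes before any
visible proliferation. Characterising that response takes three kinds of
quantification, each tedious and bias-prone when done by eye:

* **Which cells express which markers?** On multi-channel fluorescence
  sections (DAPI plus FISH and antibody channels such as *APLNR*, GFAP,
  VIM, GLUT1, BrdU), thousands of cells in the subependymal layer (SEL)
  must each be called positive or negative per channel, and the calls
  combined into co-expression fractions ("75 % of APLNR⁺ cells are
  GFAP⁺").
* **How strong is expression in each anatomical region?** Colorimetric
  in situ hybridization (ISH) slides are graded per cell on a 0–3 scale
  from the dye precipitate, summarised per region of interest (ependymal
  layer, SEL, callosal SVZ, striatum) and compared between conditions.
* **Which genes change?** Bulk RNA-seq of 9 sham vs 9 ischemic samples
  (3 subjects × 3 adjacent tissue fragments, paired by fragment) is
  tested for differential expression with a conservative combined
  criterion and a permutation-based FDR.

svzquant implements all three stages as a tested, scriptable R package,
plus a synthetic-data module that generates fluorescence fields,
colorimetric fields and paired count matrices with exact ground truth,
so every stage can be validated end to end without external data.

## The methods in brief

**Image cytometry.** Channels are projected to an all-in-focus plane,
denoised with non-local means, and background-suppressed with a top-hat
by morphological reconstruction: `T = max(C − γʳᵉᶜ(C), 0)` with
`C = φʳᵉᶜ(I)`, where the closing-by-reconstruction step removes dark
blotches before the opening-based background estimate, so only bright
structure above the background survives. The disk structuring element is
sized per channel class by granulometry (pattern spectrum of successive
openings by reconstruction). Nuclei are segmented from the DAPI top-hat
(Li threshold + distance-transform watershed declumping) and grown by
restricted dilation (≤ 3 µm, halting at equidistant frontiers) into
disjoint cellular masks. Each marker channel is thresholded in two
steps — a whole-frame Z-score gate (Z > 1) followed by Li's minimum
cross-entropy threshold on the surviving intensities — and each cell is
called positive when the thresholded-signal area fraction of its
compartment reaches a ROC-calibrated cutoff (Youden's J on ~300
expert-labelled cells).

**ISH grading.** Cells are detected on inverted colorimetric images,
precipitate is binarised by a guarded global Li threshold, and each cell
is graded level 0–3 from its precipitate fill fraction (edges 0 / 0.3 /
0.8). RoI expression is the level-2+3 cell ratio; genes are assigned to
induction groups 1–9 from per-RoI visual scores.

**Differential expression.** RPKM-based paired t-test, plus an
independent DESeq-style negative-binomial Wald test (median-of-ratios
size factors, method-of-moments dispersions shrunk to a robust trend,
condition + subject model). A gene is UP if both p < 0.05 and the
size-factor-normalised log2 fold change exceeds 0.5 (DOWN
symmetrically). The FDR is estimated from the median significant count
over label permutations (within-pair swaps) divided by the real count.

## Worked example

Generate a synthetic SEL field with the reference marker panel, run the
full cytometry chain, and compare against the generator's ground truth:

```r
library(svzquant)

## 500 cells, DAPI + APLNR (FISH) + GFAP/VIM/GLUT1 (antibodies)
field <- generate_fluorescence_field(sel_reference_field_spec(seed = 42))

## calibrate SE radii per channel class, segment, and quantify;
## cutoffs calibrated on 300 cells labelled from ground truth
stack <- preprocess_stack(field$stack)
se    <- calibrate_se_radii(stack)
nuc   <- segment_nuclei(modified_tophat(stack$images$DAPI,
                                        se_disk(se[["DAPI"]])))
masks <- cell_mask_set(nuc, restricted_dilation(nuc), 0.325)
mm    <- match_cells(masks$table, field$truth)
cal   <- do.call(rbind, lapply(c("APLNR", "GFAP", "VIM", "GLUT1"),
  function(m) data.frame(cell_id = mm$detected_id[1:300], channel_name = m,
    label = field$truth[[m]][match(mm$truth_id[1:300], field$truth$id)])))
res <- quantify_field(stack, se, calibration = cal, preprocess = FALSE)
res$coexpression
#> co-expression over 495 cells
#> marginal %:
#> APLNR  GFAP GLUT1   VIM
#>  62.0  49.7  12.1  32.1
#> P(column + | row +) in %:
#>       APLNR  GFAP GLUT1   VIM
#> APLNR 100.0  68.7  18.9  40.7
#> GFAP   85.8 100.0  16.7  36.6
#> GLUT1  96.7  68.3 100.0  36.7
#> VIM    78.6  56.6  13.8 100.0
```

Reading the output: 62.0 % of detected SEL cells are APLNR⁺ (the
generator drew exactly 62.0 % for this seed), 68.7 % of APLNR⁺ cells
are GFAP⁺ (realized truth: 72.6 %), and 96.7 % of GLUT1⁺ (endothelial)
cells are APLNR⁺ (realized truth: 96.7 %). Across ten seeds the mean
absolute error of all matrix entries is one to two percentage points.

The DE stage runs the same way from a count matrix:

```r
d  <- generate_count_matrix(count_spec(n_genes = 2000, de_fraction = 0.1,
                                       seed = 1))
de <- de_analysis(d$counts, d$gene_lengths, d$meta)
de
#> paired DE analysis: 2000 genes, 90 UP, 112 DOWN
#> criteria: paired-t p < 0.05, NB p < 0.05, |log2FC| > 0.5
permutation_fdr(d$counts, d$gene_lengths, d$meta,
                n_permutations = 200, seed = 1)
#> permutation FDR: 0.025 (real significant: 202, median over 200 permutations: 5)
```

A thin command-line front end (`inst/exec/svzquant.R`) exposes the
pipeline as subcommands (`preprocess`, `tophat`, `call-markers`,
`grade-ish`, `assign-groups`, `de-call`) over the package's TIFF/JSON,
CSV/TSV and YAML interfaces.

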