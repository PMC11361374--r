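---
title: "Methods: nuclear-envelope phenotyping with nepheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear-envelope phenotyping with nepheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nepheno)
```

# Scope and model

`nepheno` quantifies nuclear-envelope (NE) integrity phenotypes from
two-channel fluorescence images and two companion assays. The package
covers five readouts:

1. **Nuclear form factor** `4πA/P²` — 1 for a circle, lower for deformed
   nuclei — computed per segmented nucleus from the DAPI channel.
2. **Nuclear blebs** — chromatin protrusions through lamina gaps — called
   by subtracting the (hole-filled) lamin B1 object from the DAPI object
   of the same nucleus and filtering the residual components.
3. **Nuclear foci** (cGAS at rupture sites, proximity-ligation puncta) —
   counted per nucleus after white top-hat speckle enhancement.
4. **FRAP recovery kinetics** — bleach-corrected traces fitted with
   `y = y0 + (a − y0)(1 − e^{−bx})`, reporting the immobile fraction and
   the half-time `t½ = ln 2 / b`.
5. **Differential-expression filtering** — median-of-ratios size factors,
   Benjamini–Hochberg adjustment, and subsetting at `padj < 0.001`,
   `|log2FC| > 2` (strict inequalities).

Every stage is exercised against synthetic data with known ground truth;
the generators are first-class, tested package code, not test fixtures.

# Synthetic data: what it emulates, and what it does not

`make_nucleus_image()` draws non-overlapping elliptical nuclei
(area-preserving parameterization: semi-axes `r/s` and `r·s` with
`s = (1 − e²)^{1/4}`), a lamin-B1 boundary ring of fixed width, optional
bleb disks planted just outside the ellipse boundary (present in DAPI,
absent from the ring — exactly the DAPI-positive/lamin-negative signature
that bleb calling assumes), Gaussian blur, and additive Gaussian noise.
`make_foci_image()` plants Gaussian puncta inside nuclei on a diffuse
intra-nuclear pool. `simulate_frap()` emits a 3 pre-bleach + 90 recovery
frame protocol at 1 s intervals (93 frames), with an instantaneous bleach
between frames 3 and 4 and exponential acquisition fade applied to both
ROI and reference. `simulate_counts()` draws negative-binomial counts
(variance `μ + φμ²`, shared dispersion `φ`) with per-sample size factors
and a planted DE gene set.

Default study conditions mirror the assay designs the package targets:
93-frame FRAP protocols with 25 traces per condition, imaging experiments
of 3 replicates with 100–300 nuclei each, and count matrices of a few
thousand genes with small per-group sample numbers.

Deliberately **not** modeled: 3D optics (a Gaussian blur stands in for
the PSF), cell-to-cell intensity heterogeneity, chromatin texture,
touching nuclei (placement forbids overlap), spatially correlated noise,
and gene–gene correlation in counts. Passing tests therefore demonstrate
correctness of the measurement logic under controlled conditions, not
robustness to every pathology of real micrographs; segmentation of
clumped or textured real nuclei will be harder than these tests imply.

Two generator conventions matter for interpretation:

* `focus_amplitude` is the **realized post-blur peak height** of a
  planted focus. The generator pre-compensates for blur attenuation, so
  `focus_amplitude / noise_sd` is the signal-to-noise ratio of a focus as
  imaged, independent of `blur_sigma`.
* With `blur_sigma = 0` and `noise_sd = 0`, thresholding the DAPI channel
  strictly above `background_level` reproduces the planted
  nucleus-plus-bleb masks pixel for pixel; this exactness anchors the
  segmentation tests.

# Segmentation

`segment_nuclei()` smooths (Gaussian, σ = 1 px by default), thresholds
(global Otsu over the smoothed image's own range — hence invariant to
constant offsets — or a fixed threshold), fills holes (so ring-like lamin
staining segments as a full nucleus), labels connected components,
applies an inclusive area gate (defaults 200–50 000 px²), and drops
objects touching the first/last row/column. Labels are assigned in
raster-scan order of each component's first pixel, making labelings
reproducible. Touching nuclei merge by default; a distance-transform
watershed is available behind `declump = TRUE` but is not part of the
tested defaults. The smoothing, threshold strategy, and area gates are
declared package defaults, not values inferred from any reference
pipeline.

# Morphometry and bleb calling

**Perimeter.** Naive boundary-pixel counting overestimates a circle's
perimeter by ~27%, dragging the form factor of a disk to ~0.63 and
destroying the "circle ⇒ 1" anchor. `perimeter_crofton()` instead uses a
4-direction Crofton (integral-geometry) estimator over 2×2 pixel
configurations; rasterized disks of radius ≥ 20 px stay within ~1% of
`2πr`, and the package tests enforce a ±5% band on the resulting form
factor.

**Bleb calling.** Nuclei are matched across the DAPI and lamin masks by
greedy maximal pixel overlap (ties to the smaller label). The lamin
object is hole-filled before subtraction — the lamina is a rim, and
subtracting an unfilled ring would mark the whole nucleoplasm as bleb.
Candidates (DAPI minus filled lamin) are filtered by
`min_bleb_area` (default 50 px², a declared default: the minimum-area
filter is part of the method but its value is not prescribed anywhere)
and by an `edge_margin` (default 2 px): components lying entirely within
that distance of the lamin boundary are discarded as registration
slivers. Raising `min_bleb_area` can only lower bleb counts (tested
property). A nucleus is *blebbed* if it carries ≥ 1 surviving bleb;
`percent_blebbing()` is the percentage of blebbed nuclei.

# Foci

`enhance_speckles()` is a white top-hat with a disk of radius
`feature_size` (default 5 px): smooth background, gradients, and constant
offsets map to ~0 while puncta survive. Detection then thresholds the
enhanced signal **within each nucleus** at `median + k·σ_MAD` (default
`k = 5`, `σ_MAD` the normal-consistent MAD). Robust statistics are used
deliberately: a handful of bright puncta inflate the within-nucleus mean
and SD enough that a `mean + k·SD` threshold can rise above the puncta's
own peaks, making bright foci paradoxically undetectable; median/MAD are
insensitive to the puncta and restore near-perfect detection at SNR ≥ 10.
Candidates are gated to 2–200 px². Nuclei under 10 px get a missing
count (not 0). Foci closer than the enhancement's resolution merge and
count once — a documented limitation, not an error.

# FRAP

`bleach_correct()` divides the ROI by the unbleached reference
frame-by-frame (cancelling acquisition photobleaching exactly when both
regions fade at the same rate) and then scales so the pre-bleach mean is
1. The second normalization is a package choice: it makes the plateau
`a` interpretable on [0, 1] and is required for a percentage readout of
`a`. `fit_recovery()` runs bounded Levenberg–Marquardt least squares
(`y0, a ∈ [0, 1.5]`, `b > 0`), initialized from the first post-bleach
value, the mean of the last five values, and a log-linear fit of the
residual fraction. `y0` is a free parameter rather than being pinned to
the first measured frame, for robustness to acquisition jitter.
Non-convergence is reported (`converged = FALSE`, derived fields
withheld), and `summarize_frap()` excludes such fits while counting them.

The immobile fraction deserves a caveat: the default
(`immobile_convention = "paper"`) reports `IF% = a·100`, the published
formula for this assay family, even though for a 0→1-normalized recovery
curve the plateau `a` is conventionally the *mobile* fraction.
`immobile_convention = "conventional"` reports `100(1 − a)` instead. The
half-time satisfies `t½·b = ln 2` identically for every converged fit.

# Expression filtering

`size_factors()` implements median-of-ratios literally: per sample, the
median over genes (with all-positive counts) of the ratio to the gene's
across-sample geometric mean. It agrees with the established
implementation of the same estimator to 10 decimal places in the test
suite. Note the estimator is equivariant on factor *ratios*: scaling one
sample's counts by `c` also scales every gene's geometric mean by
`c^{1/n}`, so absolute factors all shift while relative factors behave
as expected.

`per_gene_test()` is a deliberately simple pluggable default (log2 ratio
of normalized group means with pseudocount 0.5; two-sided Welch t test on
log2-normalized counts): the defined computation of this module is the
normalization, the Benjamini–Hochberg adjustment, and the strict
thresholding, all of which accept any externally computed
gene/log2fc/p-value table. `bh_adjust()` validates and applies step-up
BH; a brute-force implementation of the step-up definition serves as the
oracle in tests. `de_subset()` applies `padj < 0.001` and
`|log2FC| > 2` with **strict** inequalities — genes exactly at a
threshold are excluded.

# Statistics

`t_test()` defaults to Student's pooled-variance unpaired test (the test
named in this assay family's reporting), with `paired` and `welch`
options. Degenerate all-constant data resolves by convention (equal
means ⇒ p = 1, unequal ⇒ p = 0) rather than erroring. `anova_tukey()`
wraps one-way ANOVA plus Tukey HSD; all-constant input yields
`valid = FALSE` instead of a crash. Significance stars follow
ns/*/**/***/**** at 0.05/0.01/0.001/0.0001.

`aggregate_replicates()` encodes the replicate-first rule: per-cell
measurements are collapsed to one statistic per (condition, replicate)
and condition-level tests run on replicate values, so the test n is the
number of independent experiments — pooling thousands of cells would
pseudo-replicate. Whether to test replicate means or pooled cells was an
open design choice; replicate-level testing is the declared default
because it is the defensible one.

# Numerical choices and problem sizes

* Otsu operates on a 256-bin histogram of the min–max-scaled smoothed
  image; an all-constant image yields 0 objects, not an error.
* The Crofton estimator zero-pads masks, so objects touching a crop edge
  are still closed curves.
* Bleb and focus component analysis runs on per-object bounding boxes
  (padded by the edge margin) rather than whole frames, keeping hundreds
  of nuclei per run cheap.
* The FRAP fit caps Levenberg–Marquardt at 200 iterations; `b` is bounded
  below at 1e-9 to keep `t½` finite.
* Ties in cross-channel nucleus matching break toward the smaller label;
  label maps are relabeled in raster-scan order for determinism.
* Test and verification problem sizes — 200 planted-bleb nuclei across
  10 frames, 300 nuclei per replicate in the two-condition experiment,
  25-trace FRAP conditions, 5 000-gene count matrices, and 10⁴-replicate
  null simulations for type-I error — were chosen to match the designs
  the package targets while keeping the default suite comfortably
  runnable on a laptop.

# Known limitations

Touching nuclei are merged unless the optional watershed is enabled; the
bleb/foci detectors assume a single focal plane; the default DE test has
no dispersion shrinkage and is underpowered at small n compared to
purpose-built engines (by design — it is a stand-in, not a
contribution); and all geometry is in pixel units, since no physical
pixel size is assumed anywhere.
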