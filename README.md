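# nepheno

Quantitative phenotyping of nuclear-envelope (NE) integrity from
fluorescence microscopy, plus the two companion assays that usually
accompany it: FRAP recovery kinetics and differential-expression
filtering of RNA-seq counts. The package is aimed at cell biologists
quantifying NE deformation, blebbing, and rupture — e.g. in laminopathy
or premature-ageing models — who want the measurement pipeline itself to
be tested against ground truth rather than trusted by eye.

## What it computes

**Imaging readouts** (per segmented nucleus, DAPI + lamin B1 channels):

- *Nuclear form factor* `4πA/P²`, where `A` is the nucleus area and `P`
  its perimeter; 1 for a perfectly round nucleus, < 1 for deformed ones.
  Perimeters come from a 4-direction Crofton estimator, so rasterized
  circles actually score ≈ 1 (naive boundary counting would score ≈ 0.63).
- *Nuclear blebs*: chromatin protruding through lamina gaps, called as
  (DAPI object) \ (hole-filled lamin object), with a minimum-area filter
  and an edge-sliver margin; reported per nucleus and as the percentage
  of blebbed nuclei.
- *Nuclear foci* (cGAS, PLA puncta): white top-hat enhancement, then a
  robust per-nucleus threshold (median + k·σ_MAD); reported as counts
  per nucleus and percentage of foci-positive nuclei.
- *Nuclear marker intensity* inside the DAPI mask, and marker-based
  gating of positive nuclei.

**FRAP**: traces are reference-corrected and pre-bleach-normalized, then
fitted with `y = y0 + (a − y0)(1 − e^{−bx})`; the immobile fraction
(`IF% = a·100` by the published convention, `100(1 − a)` optionally) and
half-time `t½ = ln 2 / b` are derived, with per-condition summaries and
a two-tailed unpaired t test.

**Expression filtering**: median-of-ratios size factors,
Benjamini–Hochberg adjustment, and subsetting of up/down-regulated genes
at `padj < 0.001` and `|log2FC| > 2` (strict).

**Statistics**: Student/paired/Welch t tests, one-way ANOVA with Tukey's
post hoc, significance stars, and replicate-first aggregation (tests run
on per-experiment summaries, not pooled single cells).

Every stage has a matching synthetic-data generator with known ground
truth (`make_nucleus_image()`, `make_foci_image()`, `simulate_frap()`,
`simulate_counts()`), so the whole pipeline is testable end to end.

## Worked example

```r
library(nepheno)

# a ground-truthed two-channel image: 8 nuclei, half carrying one bleb
spec <- nucleus_image_spec(n_nuclei = 8, blebs_per_nucleus = 1,
                           bleb_prob = 0.5, seed = 1)
im  <- make_nucleus_image(spec)
nuc <- segment_nuclei(im$dapi)
lam <- segment_nuclei(im$lamin)
rec <- measure_nuclei(nuc, list(dapi = im$dapi))
bl  <- detect_blebs(nuc, lam)
rec <- merge(rec, bl$nuclei[, c("label", "n_blebs")], by = "label")
head(rec[, c("label", "area", "perimeter", "form_factor", "n_blebs")], 4)
#>   label area perimeter form_factor n_blebs
#> 1     1 2224     181.4      0.8493       1
#> 2     2 1691     159.3      0.8374       1
#> 3     3 1645     156.8      0.8403       1
#> 4     4 1348     141.2      0.8494       1
percent_blebbing(rec)
#> [1] 75   # this seed planted blebs on 6 of the 8 nuclei

# FRAP: simulate one noisy trace and fit the recovery model
fit <- fit_recovery(bleach_correct(simulate_frap(
  frap_sim_spec(y0 = 0.2, a = 0.7, b = 0.1, noise_sd = 0.02, seed = 2))))
fit
#> <frap_fit> y0=0.1929 a=0.6930 b=0.1062 /s  IF%=69.3  t1/2=6.53 s (rss 0.0462)
```

The moderately elliptical nuclei score form factors ≈ 0.84 — round but
not circular — and each planted bleb is recovered. The FRAP fit returns
the planted kinetics (`y0 = 0.2`, `a = 0.7`, `b = 0.1/s`) to within the
noise, and `t½·b = ln 2` holds identically.

A whole experiment can also be driven from one YAML config via
`run_pipeline()` or the wrapper script `inst/scripts/ne-pheno.R`
(stages: simulate, segment, measure, foci, frap, de, report; outputs are
CSVs plus a manifest recording every parameter in force).

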