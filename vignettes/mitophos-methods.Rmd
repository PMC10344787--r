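---
title: "Methods: models, estimators and defaults in mitophos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and defaults in mitophos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophos)
```

mitophos quantifies two complementary readouts of mitochondrial remodelling:
site-level phosphoproteomic changes summarized per protein, and
image-derived morphology, dynamics and contact-site measurements. Every
analysis function has a matching seeded synthetic-data generator with exact
ground truth, so the whole pipeline can be validated end to end without
external data. This vignette documents the statistical models, the estimator
choices, the default parameter values with their units, and the known
limitations.

## 1. Phosphoproteomics

### Data model

`phospho_table()` holds a site-by-sample matrix of positive linear-scale
intensities (missing values are `NA`, never 0), one protein id per site, and
a factor design whose first level is the control group.

### Preprocessing (`preprocess()`)

1. log2 transformation.
2. Per-sample median centring, which removes sample loading differences
   under the usual assumption that most sites do not change.
3. Down-shifted Gaussian imputation of missing values: for each sample,
   draws from a normal with mean `m - shift * s` and standard deviation
   `width * s`, where `m` and `s` are the observed mean and standard
   deviation of that sample. Defaults `shift = 1.8` and `width = 0.3` are
   the convention popularized by label-free proteomics software; they encode
   the assumption that intensity-dependent (MNAR) dropout dominates, so
   missing values are drawn from the low tail. Imputation is seeded and
   therefore reproducible.

A sample with no observed values cannot be imputed and is a hard error.

### Site-level testing and significance calling

`differential_sites()` runs a Welch (unequal-variance) t-test per site,
treatment minus control on the log2 scale, so `log2fc > 0` means higher in
treatment. Degenerate zero-variance cases follow fixed conventions: equal
means give `t = 0, p = 1`; unequal means with zero pooled variance give
infinite `t` and `p = 0`.

`call_significance()` first applies Benjamini–Hochberg correction
(`p_adj < alpha`, default `alpha = 0.05`). Low replication (the default is
n = 4 per group) can leave real signal below the BH threshold. When BH
yields zero calls *and* the raw p-value distribution is anti-conservative —
the fraction of p-values below `alpha` exceeds `factor * alpha` (default
`factor = 1.5`), assessed only when at least 50 p-values are available — a
documented fallback is applied instead: `p < alpha` together with a linear
fold change above `fc_cutoff` (default 1.5). The `procedure` column records
which rule produced every call, so the two regimes can never be confused
downstream.

### Per-protein cumulative score (ΔPs)

`delta_ps()` scores each protein as the sum of log2 fold changes over its
phosphopeptides with raw `p < alpha`. A protein with no such peptide scores
exactly 0 (it contributes no evidence of change), which makes the score
distribution a mixture with a point mass at zero. Proteins are classified
hyper-/hypo-phosphorylated when their score exceeds ±2σ, where σ is the
population standard deviation of the scores across all proteins, zeros
included (default `sigma_mode = "all"`). The zeros shrink σ and therefore
make the 2σ cutoff more liberal; `sigma_mode = "nonzero"` is available when
the analyst prefers the cutoff scaled to changed proteins only.

`report_fractions()` fixes the reporting convention for percentages:
`round(100 * n_sig / n_total, 2)`.

### Synthetic phospho data

`simulate_phospho_table()` draws site-level base abundances
`N(base_mean = 25, base_sd = 2)` on the log2 scale (a typical LFQ intensity
range), plants effects of magnitude `effect_log2fc = 2` with random sign on
a fraction `effect_fraction = 0.1` of sites in every non-control group, adds
multiplicative noise with `cv = 0.2` (converted exactly to a log2-scale SD
via `sqrt(log(1 + cv^2)) / log(2)`), and removes values with a mixed
mechanism: a fraction `mnar_weight` of the target `missing_rate` follows a
logistic weight that preferentially removes low intensities, the rest is
uniform. The generator emulates the *statistical* structure of label-free
phosphoproteomics (effect sizes, noise, MNAR dropout); it does not emulate
peptide identification, chromatography, shared peptides between proteins, or
correlated noise between co-eluting peptides.

One measured property worth knowing: at the default `missing_rate = 0.1`,
down-shifted imputation (which intentionally biases imputed values low)
costs raw-test sensitivity for planted effects, because any site with a
dropout in either group gets a distorted group mean. On complete matrices
the site test recovers essentially all planted `|log2FC| = 2` effects; the
validation suites therefore benchmark the testing stage on complete
matrices and treat missingness as a property of the generator, not of the
test.

## 2. Morphology

`auto_threshold()` implements Otsu's criterion (default) and the IsoData
iterative intermeans rule on a 256-bin histogram; the chosen threshold is
attached as an attribute so it can be logged. `label_mask()` labels
8-connected components (diagonal contact joins particles, matching the
common particle-analysis convention).

Perimeter uses the Crofton formula with 4 directions
(`perimeter_crofton()`): the image is scanned in 2×2 pixel configurations
and each configuration contributes a fixed length increment. This estimator
is consistent for smooth convex shapes under rasterization — the measured
circularity `4πA/P²` of rasterized disks converges to 1 from above/below
within a few percent at radius ≥ 10 px — which is exactly the regime where
circularity is interpreted biologically (fragmented round mitochondria vs
elongated networks). The known trade-off: on axis-aligned rectangles,
Crofton underestimates the perimeter by the factor `(π/4)(1 + 1/√2) ≈
0.942`, so the analytic identity "a square has circularity π/4" holds for
the formula `circularity(area, perimeter)` applied to exact geometric
values, not for the raster estimate. No single local perimeter estimator is
exact for both polygons and disks; we chose the one that is accurate for
the shapes the measurement is about.

`circularity()` clips to ≤ 1 (rasterization can push the raw value slightly
above 1) and defines elongation as its reciprocal. `analyze_particles()`
filters particles below `min_area = 0.05` µm² (sub-resolution specks at the
default 0.1 µm/px calibration) and counts particles by *centroid-in-ROI*,
which makes the count invariant to small translations of the field.
`roi_spec()` builds a centred square ROI of `area = 35` µm², a typical
single-cell footprint at this magnification.

## 3. Time-lapse dynamics

`track_components()` links particles between consecutive frames by greedy
intersection-over-union matching (`iou_threshold = 0.3`, ties broken by IoU
descending then label ascending — fully deterministic). `detect_events()`
declares a fission where one particle maps to ≥ 2 particles in the next
frame, each child having at least `min_frac = 0.5` of *its own* area covered
by the parent; fusion is defined as the exact mirror (each parent covered ≥
`min_frac` of its own area by the child). Because the two rules are
transposes of each other, reversing a movie in time maps every detected
fission to a fusion and vice versa — a property the test suite checks
exactly. Events touching the field border (`border_margin = 2` px) are
discarded because objects entering or leaving the field masquerade as
events, and an event undone within one frame is debounced by default.

`event_rates()` normalizes counts to events · cell⁻¹ · s⁻¹. The default
acquisition cadence of the generator is one frame per 13 s over 600 s
(single-channel live imaging; 27 s is typical when two channels are
interleaved), at 0.1 µm/px.

`interaction_analysis()` measures marker–mitochondrion contacts as maximal
runs of consecutive frames with pixel overlap; duration is
`(end − start + 1) × frame_interval`. A contact is "useful" if that
mitochondrion undergoes fission during the contact or within
`fate_window = 2` frames after it ends, "futile" otherwise.

`simulate_timelapse()` renders capsules (segments dilated by a radius — the
simplest shape with an analytic area `L·2r + πr²`), static except for
scripted events; fission splits a capsule at its midpoint leaving a ~3 px
surface gap, fusion spans the farthest endpoints of the pair. It emulates
resolvable, well-separated organelles with optional Gaussian PSF and
additive noise; it does not emulate Brownian motion, out-of-focus light,
photobleaching, or densely packed networks.

## 4. Contact sites and co-localization

`contact_percentage()` computes, per mitochondrion, the minimum
edge-to-edge distance to the ER via the exact Euclidean distance transform
of the ER complement sampled at the mitochondrion's pixels; centre-to-centre
pixel distance is converted to a membrane gap by subtracting one pixel, so
edge-adjacent objects read 0 nm. A mitochondrion is "in contact" when the
gap lies in the inclusive band 10–30 nm, the conventional
mitochondria-associated-membrane apposition range; gaps *below* the band are
excluded by default (a strict band) and can be swept in with
`include_closer = TRUE`. Pixel distances are not interpolated, so the
sampling must resolve the band (≤ 5 nm/px recommended; the generator errors
when a requested positive distance rounds to a zero-pixel gap).

`coloc_percentage()` is the Manders-style mask overlap: the percentage of
marker pixels inside the reference mask.

## 5. Numerical and reproducibility choices

* All generators and the imputation step are seeded; `run_pipeline()` runs
  are byte-identical given the same configuration (validated in the test
  suite).
* TIFF export rescales frames to [0, 1] and stores 32-bit float pages; the
  original range and the calibration (µm/px, s/frame) live in a JSON sidecar
  because baseline TIFF tags cannot carry a frame interval. Reading without
  any calibration source is an error, never a silent default.
* TSV export writes missing intensities as empty cells and reading maps them
  back to `NA`, never 0; duplicate site ids and malformed headers are hard
  errors.
* BH adjustment wraps `stats::p.adjust`; the test suite verifies it against
  a brute-force step-up written from the definition, and verifies the
  distance transform against all-pairs brute force. Problem sizes in the
  validation suites are ≈ 1,000 sites × 8 samples (phosphoproteomics) and
  ≤ 360² px × ≤ 47 frames (imaging), each running in seconds on one CPU.

## 6. Limitations

* The fallback significance rule is a pragmatic, explicitly-labelled rescue
  for underpowered designs; fold-change thresholds do not control the FDR
  and results under `procedure == "fallback"` should be treated as
  candidate lists.
* ΔPs sums evidence across peptides without weighting by peptide count or
  variance; proteins with many quantified peptides have more opportunities
  to accumulate score.
* Event detection assumes resolvable objects between consecutive frames;
  it will undercount when multiple events involving the same object occur
  within one frame interval.
* Contact percentages depend on segmentation quality of both masks; the
  1-px gap convention is exact for the synthetic geometry but only an
  approximation for anti-aliased real segmentations.

## Worked example

```{r example, eval = FALSE}
cfg <- phospho_sim_config(n_proteins = 200, seed = 7)
sim <- simulate_phospho_table(cfg)
res <- call_significance(differential_sites(preprocess(sim$table, seed = 7)))
dps <- delta_ps(res)
report_fractions(sum(res$significant), nrow(res))
table(dps$klass)
```
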