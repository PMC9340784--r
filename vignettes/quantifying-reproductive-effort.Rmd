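---
title: "Quantifying reproductive effort in oyster gonad sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reproductive effort in oyster gonad sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonadquant)
```

## The measurement problem

The gonad of *Crassostrea gigas* is a seasonal network of gonadal tubules
(GT) embedded in connective tissue that includes a glycogen-storing storage
tissue (ST). Reproductive effort — how much of the animal a cross section
devotes to gametogenesis — is summarised by two area ratios on a
trichrome-stained transverse section:

* **GTI** = 100 · GA / whole section, with the gonadal area GA the region
  around the digestive gland containing GT and ST;
* **TAI** = 100 · GT / whole section.

Both are pure area fractions, so they are invariant to magnification and to
uniform rescaling — the property the synthetic tests exploit. A
complementary per-tubule analysis (count and mean area) is meaningful at
early stages (0–1) when tubules are clearly individualized.

## Pipeline and assumptions

`run_section()` chains the stages; every automatic threshold it chooses is
written to the result log.

1. **Block-mean downsampling** (`downsample()`, default factor 8 on
   0.25 µm/px scans, giving 2 µm/px). Block means are area-preserving, so
   the downstream area indices are unbiased; stride sampling would not be.
   Rounding is half-up to keep 8-bit storage.
2. **Colour normalisation** (`color_normalize()`): Reinhard-style transfer
   of per-channel mean and standard deviation in CIE L\*a\*b\* toward a
   designated reference slide. The reference is a free choice
   (`color_reference()` on any image, or none); normalising an image to its
   own statistics is a no-op up to 8-bit rounding. Channels with zero
   variance are mean-shifted only.
3. **Whole-tissue mask** (`segment_whole()`): threshold on the intensity
   component I = (R+G+B)/765 of HSI space. The intensity histogram of a
   slide scan is typically *trimodal* — white background, pale
   connective/storage tissue, dark tubule stain — and a two-class threshold
   (Otsu or intermeans) can lock onto the wrong valley when the dark class
   is large. The default is therefore the *upper* threshold of a two-
   threshold (three-class) Otsu (`method = "otsu3"`), which always separates
   background from tissue; plain Otsu and Ridler–Calvard ISODATA remain
   available, as does a fixed threshold. Morphological closing (disc radius
   2 px), hole filling and a minimum component size (default 64 px) clean
   the mask; an exclusion mask (e.g. manually outlined gill remnants)
   is forced to background. An empty result is an error.
4. **Tubule mask** (`segment_gt()`): within the tissue, tubule pixels
   satisfy `L* < t_L` and `a* >= t_a` — the blue-violet stain is darker
   and at least as red-shifted as the pink connective tissue. Defaults are
   Otsu per channel computed within the whole mask; both inequality
   directions flip via arguments for other stains. An empty mask is valid
   (stage-0 sections).
5. **Storage mask** (`segment_st()`): a random-forest pixel classifier
   (`ranger`, 100 trees, fixed seed — the same classifier family as
   interactive pixel-labelling tools) over nine features per pixel: R, G, B
   and their 3×3 neighbourhood mean and standard deviation. Training labels
   come from any image with known masks (`st_training_frame()`), e.g. a
   phantom or a hand-annotated slide; the classifier is applied to
   `whole \ GT` only, so GT keeps priority and the masks stay disjoint.
   `run_section()` without a trained model records an empty ST mask and
   logs the fact rather than failing, so storage-free material can be
   processed; `segment_st()` itself requires a model.
6. **Morphometry** (`label_tubules()`, `measure_tubules()`): 8-connected
   components of the GT mask at least `min_area_px` (default 30 px ≈ 120
   µm² at 2 µm/px — suppresses stain specks; discarded pixels are counted,
   never silently lost). Per tubule: pixel area, perimeter by the
   4-direction Crofton estimator, circularity 4πA/P², equivalent-ellipse
   axes (4·√eigenvalue of the second central moments), centroid, a border
   flag, and the Gravelius compactness K = P/(2√(πA)) with the exact
   constant 1/(2√π) ≈ 0.2821 so that a disk gives exactly 1.
7. **Circularity filter** (`filter_circular()`): strictly `K < 1.7` keeps
   tubules cut near-perpendicular to their axis. The filter affects tubule
   counts and mean areas only — GTI and TAI are mask ratios and are never
   filtered. `representativeness()` checks, per animal, that the kept
   share is compatible with the overall share (one-sample t against the
   pooled proportion; zero-variance input is flagged degenerate and
   reported as no difference).
8. **Indices** (`gonadal_area()`, `summarize_section()`): GA is the union
   of GT and ST closed with a disc (default radius 5 px; 0 disables). The
   closing radius is the explicit stand-in for how much interstitial
   connective tissue the gonadal area includes — the source material never
   defines the GA boundary operationally, so the knob is documented rather
   than hidden. TAI ≤ GTI holds by construction.

`run_cohort()` maps the section pipeline over a manifest, then computes
group means ± SEM and all pairwise within-stage pooled Student's t-tests
(`t_test_groups()`, Welch via `var_equal = FALSE`), starred with the
multi-level convention `****` p<0.0001, `***` p<0.0005, `**` p<0.001,
`*` p<0.05. The narrower single-threshold convention (p < 0.01) used in
some texts can be recovered by ignoring the star levels below `**`; the
package computes the full mapping and leaves presentation to the caller.
No multiple-testing correction is applied by default, matching the original
analysis style; `p.adjust` can be applied to the tidy comparison table.

qPCR relative expression is `2^-(Ct_target − Ct_reference)` with EF1α as
reference — the standard reading of expression "by Ct deviation"; a ΔΔCt
against a calibrator sample is a one-line transformation of the returned
table. Mitosis phase counts become percentages with
`phase_frequencies()`.

## The slide phantom: what it emulates, what it does not

`generate_phantom()` builds a synthetic trichrome-like section with exact
ground truth:

* a tissue blob (squircle; up to ~93% of the frame before clipping,
  `tissue_fraction = 1` fills it entirely) on a white background;
* a gonadal area: a concentric scaled copy of the blob whose area equals
  `st_fraction · blob + Σ tubule areas`;
* `n_tubules` rotated ellipses, minor semi-axis log-normal in microns,
  placed fully inside the GA by rejection sampling (1000 attempts per
  tubule, largest first, with a configurable clearance margin) — tubules
  never overlap, mirroring the clearly individualized tubules of early
  stages;
* ST defined as GA minus the tubules, so GT ∪ ST *is* the GA region and
  the true indices are mask ratios by construction;
* colours sampled per class from a Prenant–Gabe-trichrome-like palette
  (white 245/245/245, pale-pink connective 230/180/190, pink-orange storage
  235/160/140, blue-violet tubule 120/90/160) plus independent Gaussian
  noise, clipped to 8 bits. The palette separates in HSI intensity and in
  L\*/a\* — the same separability the real stain offers the thresholds.

`stage_phantom_spec()` encodes the study conditions: the true gonadal
fraction equals the group GTI values reported for the cohort (stage 1:
20 / 17 / 10% for diploid / alpha / beta; stage 3: 85 / 71 / 23%; stage 0:
12.5%, the midpoint of the reported 10–15% band with no class difference).
Where no absolute value exists the preset makes one documented choice: GT
occupies 0.25 of the GA (no absolute TAI is printed; 0.25 keeps the
non-overlap packing feasible at every preset), tubule counts are 10 / 20 /
40 at stages 0 / 1 / 3 (6 for stage-0 triploids, which have fewer tubules),
noise sd 10. Stage 2 has no printed index and deliberately no preset.

What the phantom does *not* emulate: germ cells, mitotic figures and
nuclei inside tubules; gill tissue (removed before the real analysis);
stain gradients and fixation artefacts; tubule clustering around the
digestive gland (placement is uniform within the GA — the source material
does not describe the spatial arrangement, so none is invented). Passing
the phantom suite therefore demonstrates that the estimators recover known
geometry under palette noise, not that they are robust to every histological
artefact of real slides.

## Numerical choices and degenerate inputs

* Automatic thresholds: "otsu3" upper cut for background/tissue (see
  above); plain Otsu within-mask for L\*/a\*; ISODATA available for
  unbalanced histograms. A constant channel returns its single value.
* Morphology uses 8-connectivity throughout; labels are assigned in raster
  order of each component's first pixel, making outputs reproducible.
* The Crofton perimeter uses the four lattice directions with weights
  π/8 · (c0 + c90 + (c45 + c135)/√2); on a radius-50 disk it is within 0.4%
  of 2πr and K converges to 1 from above as the radius grows.
* Zero-variance t-tests are flagged degenerate (p = 1 for equal means,
  p = 0 otherwise) instead of erroring mid-cohort; SEM of a single value is
  an error, and group summaries report SEM as NA when n = 1.
* `predict()` on the random forest is seeded: unseeded prediction breaks
  bit-reproducibility through random tie-breaking.
* Phantom generation under a fixed spec (including seed) is bit-identical
  across calls; failed tubule placement names the failing tubule.
* Border-touching tubules are measured and flagged, not dropped
  (`drop_border = TRUE` drops them) — the choice is a config switch, not an
  inference about the original protocol.

## Problem sizes

The test-suite phantoms are 64–320 px for unit checks and 1024×1024 (the
working size after the by-8 downsampling of a small scan) for the
end-to-end recovery suite: 20 seeds for each of six stage/ploidy
conditions, recovered GTI within ±2 percentage points of truth per seed.
Tubule-count recovery uses 512² phantoms with 5, 12 and 30 well-separated
tubules at noise sd 10 (exact count, mean area within 5%). The
morphometry oracle enumerates 1000+ random small regions; the statistics
oracle replays 100 random t-tests against the closed form at 1e-10. The
full suite and the acceptance script each run in minutes on one CPU.

## Known limitations

* The three-tissue segmentation is colour-threshold-based by design; it
  will not separate tissues whose stain distributions overlap (the ST/GT
  distinction already needs the pixel classifier, and real slides may need
  retraining labels per staining batch).
* GA depends on an explicit closing radius; reported GTI values should cite
  it (the log records it per run).
* The pipeline processes single plane images; whole-slide pyramidal formats
  must be exported to TIFF/PNG first.
* The Crofton estimator is near-unbiased for smooth convex blobs but, like
  every digital perimeter, becomes noisy for regions a few pixels across —
  hence the minimum-area filter before K is interpreted.
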