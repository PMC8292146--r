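---
title: "Quantifying inflammatory infiltrates from multiplex immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inflammatory infiltrates from multiplex immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexquant)
```

## The problem

Multiplex tyramide signal amplification (mTSA) lets a single tissue
section — typically a sparse kidney transplant biopsy — be stained for many
immune markers at once (CD3, CD4, CD8, CD20, CD68, CD163, Tbet, GATA3,
CD34, with a DAPI counterstain). A multispectral microscope records each
field as a tile with many acquisition bands; every band mixes the emission
of all fluorophores present. Turning that raw signal into cell densities,
double-positive fractions and spatial statistics requires a chain of
steps, each of which this package implements and validates:

1. **Spectral unmixing** of each tile into per-fluorophore abundance
   planes, given a spectral library.
2. **Stitching** of tiles into whole-slide planes using their stored
   origins.
3. **Artificial brightfield synthesis**: pairing each marker plane with
   DAPI and rendering a hematoxylin/DAB-like RGB image, so detectors
   developed for chromogenic IHC can run on fluorescence data.
4. **Detection decoding and evaluation**: turning detector outputs into
   point detections and scoring them against dot annotations.
5. **Spatial quantification** inside annotated regions of interest:
   densities, double positivity, nearest-neighbour distances,
   positive-pixel fractions.
6. **Cohort statistics** over per-patient tables.

Because real cohort images and annotations are not distributable, every
stage is validated on synthetic scenes with exactly known ground truth,
generated by the package itself.

## Models and conventions

### Linear mixing and unmixing

A pixel's band vector is modelled as $y = L a + \varepsilon$ with $L$ the
bands-by-fluorophores library matrix and $a \ge 0$ the fluorophore
abundances. `unmix_tile()` solves, per pixel,

$$\hat a = \arg\min_{a \ge 0} \lVert L a - y \rVert_2^2 ,$$

i.e. non-negative least squares. Spectra are max-normalized (peak 1), not
unit-sum, so abundances keep the intensity units of the input. The
unconstrained solution is used where it is already non-negative; only
violating pixels go through the Lawson–Hanson active-set solver. The
autofluorescence channel is unmixed like any other fluorophore and then
simply not used downstream (it is never subtracted from other channels).

Rank deficiency of the library is rejected at construction time: two
collinear spectra make abundances unidentifiable.

### Stitching

Tiles carry a 0-based global pixel origin. `stitch_planes()` writes each
tile at its origin on a zero canvas; for non-overlapping tilings the
result is order-invariant and exact. Overlaps follow last-written-wins
with a warning, since no blending rule is defined for this instrument
output — overlapping tiles do not occur in the synthetic fixtures.

### Brightfield synthesis

`convert_to_brightfield()` applies a Beer–Lambert model per channel
$ch \in \{R, G, B\}$:

$$\mathrm{out}_{ch} = 255 \, e^{-(I_\mathrm{DAPI}\, c_{ch,\mathrm{Hem}}
  + I_\mathrm{IHC}\, c_{ch,\mathrm{DAB}})}$$

with stain vectors $c$ defaulting to the Ruifrok–Johnston hematoxylin
(0.650, 0.704, 0.286) and DAB (0.268, 0.570, 0.776) optical-density
triplets; both are configurable. Zero signal maps to white
(255, 255, 255), and each channel is strictly decreasing in both
intensities wherever the coefficients are positive. Intermediate math is
floating point; quantization (round half away from zero) happens once, at
the end. Because the two stain vectors are linearly independent, the
pre-quantization image can be inverted back to $(I_\mathrm{DAPI},
I_\mathrm{IHC})$ by least squares on the optical densities — the
package's own correctness oracle (`invert_brightfield()`).

Inputs must be normalized to $[0, 1]$ first. The default normalization is
the per-plane 99.9th percentile, which is robust to hot pixels; a fixed
`scale_max` is available when constant scaling across slides matters.
Whether one should clip or rescale before the exponential is a genuinely
open choice; the percentile default is this package's decision and is
recorded as provenance on the image object.

### Detection decoding

Two decoding contracts cover the common detector output shapes:

* `decode_probability_map()` — threshold, label connected components,
  merge components whose centroids are closer than a minimum separation
  (single-linkage), report area-weighted centroids with the component max
  as confidence. Reference operating points from the motivating
  application: threshold 0.7 for strong cytoplasmic staining, 0.4 for
  weaker cytoplasmic and for nuclear markers, at 0.49 µm/px with 4 µm
  separation.
* `non_maximum_suppression()` — for box-grid detectors (21 µm boxes at
  0.98 µm/px, objectness threshold 0.45): greedy descending-objectness
  selection suppressing boxes whose IoU with a kept box exceeds 0.05.
  The suppression parameter is interpreted as an IoU threshold — the
  usual convention — and ties in objectness break by (y, x) order so the
  result is deterministic.

Training of detector networks is out of scope. For synthetic validation
the package provides `reference_blob_detector()`, a scale-normalized
Laplacian-of-Gaussian detector at $\sigma = r/\sqrt{2}$ for cell radius
$r$, with a threshold relative to the maximum response (default 0.15,
comfortably separating rendered cells from background in noise-free
scenes while tolerant to moderate noise).

### Matching and scores

`match_detections()` formalizes the closest-detection rule as global
greedy one-to-one matching over all (detection, annotation) pairs within
the radius, in ascending distance order, with deterministic tie-breaks.
For the canonical two-detections-near-one-annotation case this reproduces
"only the closest detection counts"; against an exhaustive
maximum-cardinality oracle it agrees on all but rare crossing
configurations (where greedy can only be lower, never higher — the test
suite counts these). Distance equal to the radius counts as within; a
`strict` flag flips that. Matching radii are the nominal cell diameters:
4 µm for lymphocytes, 21 µm for macrophages.

Precision, recall and F1 use the standard formulas with every 0/0 defined
as 0; multi-slide evaluation pools summed TP/FP/FN rather than averaging
per-slide scores.

### Spatial quantification

* ROIs are polygon sets (inclusions minus exclusions) with an optional
  capsule polyline; areas are exact shoelace areas in mm². Boundary
  points count as inside.
* The subcapsular band is the ROI within 400 µm *Euclidean* distance of
  the capsule polyline (capsules curve, so perpendicular depth would be
  ill-defined); band areas are measured by rasterizing on the pixel
  grid, so their accuracy is one pixel along the band edge.
* Double positivity pairs detections from two channels one-to-one,
  greedily by ascending distance, strictly below the radius (4 µm
  lymphocytes / 21 µm macrophages, i.e. 8 px and ~43 px at 0.49 µm/px).
  One-to-one pairing prevents a single cell in channel B from validating
  several channel-A cells. `subtract_population()` returns the unpaired
  complement (e.g. CD3⁺CD8⁻), so the two outputs partition channel A by
  construction — a property the tests fuzz.
* `mean_shortest_distance()` is the mean over source cells of the
  nearest-target distance, reported in µm and px; it is directional and
  flagged undefined for empty populations rather than silently zero.
* `positive_pixel_fraction()` thresholds a plane inside the ROI (Otsu on
  the ROI pixels by default — chosen as the conventional automatic
  thresholding method — or a fixed threshold for reproducibility) and
  reports the positive percentage, the capillary-extent readout for
  CD34.

### Cohort statistics

The statistics layer wraps the standard tests (`wilcox.test`,
`cor.test`, `t.test`, `fisher.test`) behind a cohort-table interface:
Mann–Whitney U with exact p-values whenever the combined sample is ≤ 20
without ties (the regime of 9-vs-13 patient groups, where borderline
p-values are sensitive to the approximation) and a tie-corrected normal
approximation otherwise; Spearman with average ranks and the
t-approximation, flagged undefined on constant input; signed-rank with
zero differences dropped and an explicit "no test" flag when all
differences are zero; Welch's t; Fisher's exact. Summaries follow the
field's convention: median (min–max) for densities and percentages, mean
(SD) for ratios. No multiple-testing correction is applied by default,
matching single-comparison reporting; `compare_groups(adjust = TRUE)`
adds Benjamini–Hochberg.

## The synthetic-scene generator

`generate_scene()` plants, with exact bookkeeping:

* point cells per population, placed uniformly inside the ROI (outside
  exclusions) with a minimum center separation of one cell *radius* —
  enough to avoid fully coincident cells while still exercising
  clustered scenes;
* double-positive memberships: a co-localization fraction $f$ for pair
  (A, B) marks exactly `round(f * n_A)` A-cells as B-positive, so planted
  counts are integers known in advance;
* a capillary mask built by thresholding a smoothed Gaussian random
  field at the quantile matching the requested area fraction (achieved
  fraction stored alongside);
* a rectangular cortical ROI with optional circular exclusions
  emulating glomeruli and a capsule polyline along the top edge.

`render_multispectral()` draws each cell as an isotropic Gaussian bump
with σ equal to half the cell radius (1 µm for 4 µm lymphocytes, 5.25 µm
for 21 µm macrophages) — smooth, analytically simple, and matched to what
a blob detector can resolve — routes marker planes to fluorophores
(CD4 → Opal520 and CD68 → Opal540 pinned, emulating the spectrally
adjacent pair through which strong macrophage signal can bleed into the
T-helper channel), applies an optional fluorophore-level cross-talk
matrix, projects through the library into bands, tiles the scene, and
optionally adds band-wise additive Gaussian noise clipped at zero (the
simplest model that still exercises the non-negativity constraint of
unmixing). The default pixel size is 0.49 µm/px, the 20× multispectral
acquisition resolution; tiles are non-overlapping, since instrument tile
overlap is not publicly specified.

Everything is bit-reproducible under a seed (the generator snapshots and
restores the RNG state).

What the generator deliberately does **not** emulate: tissue texture and
autofluorescence structure (only a constant background spectrum is
available), staining gradients, scanner artifacts, and the morphological
ambiguity of real macrophages. Passing the synthetic end-to-end check
therefore demonstrates that the pipeline machinery — unmixing, stitching,
conversion, decoding, matching, quantification — is numerically correct,
not that any particular trained detector will perform equally on real
tissue.

## End-to-end validation conditions

`e2e_validation_scene()` fixes the standard validation conditions: a
900 × 900 µm cortical scene at 0.49 µm/px (1837² px, about 0.74 mm² of
ROI after one glomerular exclusion), 200 CD3⁺ cells (≈ 270 cells/mm², a
realistic cortical T-cell infiltrate), 32 CD20⁺, 20 CD68⁺ and 20 CD163⁺
cells, a planted CD3:CD8 co-localization fraction of 0.25, an 8%
capillary-area fraction, rendered noise-free through the default
13-band Opal library and 256-px tiles. Macrophage densities are kept
below typical clinical medians on purpose: at σ = r/√2 ≈ 7.4 µm the LoG
reference detector cannot separate 21 µm cells closer than ≈ 18 µm, so
denser macrophage scenes measure detector resolution rather than
pipeline correctness. The acceptance checks on this scene are:
per-population F1 ≥ 0.95, densities within 5% of planted truth, planted
co-localization counts recovered exactly from ground-truth coordinates,
and the capillary percentage within one percentage point. On a single
CPU the whole scene runs in about a minute; the remaining validation
(unmixing fidelity at 1e−6, optical-density inversion at 1e−6, exact
stitching, 1000 fuzzed matching instances, exhaustive matching oracle up
to 6×6, Mann–Whitney enumeration and a 2000-replicate type-I-error
simulation) adds a few more seconds each.

## Numerical choices and degenerate inputs

* Unmixing tolerance for switching to the constrained solver: any
  unconstrained coefficient below −1e−10; final abundances are clamped
  at exactly 0.
* Centroid merging cuts single-linkage clusters at the separation
  distance (≤ h), which coincides with the strict "closer than" rule
  except on exact ties of continuous centroids.
* Plateaus in the blob response break toward the top-left pixel so one
  detection per plateau survives; detection coordinates are peak pixels
  (sub-pixel refinement is unnecessary at a 1 px acceptance radius).
* Empty inputs return empty tables, not errors; undefined statistics
  (empty populations, constant correlates, all-zero paired differences,
  zero-count denominators) are flagged (`defined = FALSE` / `NA` with a
  warning), never silently dropped.
* Otsu's threshold is computed on a 256-bin histogram of ROI pixels;
  when the inter-class valley is empty the maximizer is flat there and
  the lowest maximizing bin edge is returned — any threshold in the
  valley induces the same classification.

## Known limitations

* The unmixing model is strictly linear; fluorophore saturation or
  quenching is not modelled.
* Fluorophore-level cross-talk applied before band projection (the
  CD68 → CD4 bleed emulation) is *not* removed by unmixing — by design,
  since the same limitation affects the real instrument's library-based
  unmixing; the downstream guard is the same as in practice
  (double-positivity gating and reporting CD3⁺CD8⁻ as a T-helper
  surrogate).
* Band areas are rasterized, not exact polygon offsets; accuracy is one
  pixel along the band boundary.
* The reference blob detector is a validation instrument, not a
  replacement for trained detectors on real tissue.
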