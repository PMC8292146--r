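# plexquant

Quantitative analysis of multiplex tyramide signal amplification (mTSA)
stained tissue imaged multispectrally — the setting in which a single
kidney-transplant biopsy section is stained for a whole immune panel
(CD3, CD4, CD8, CD20, CD68, CD163, Tbet, GATA3, CD34, DAPI) and each
microscope tile records many spectral bands mixing all fluorophores.

The package implements the full chain from raw multispectral tiles to
cohort-level statistics, for image analysts and renal-pathology
researchers who need reproducible cell densities, double-positive
fractions and spatial statistics from multiplex slides:

* **Spectral unmixing** — per pixel, abundances solve the non-negative
  least-squares problem `min ||L a − y||², a ≥ 0` against a spectral
  library `L` (bands × fluorophores, max-normalized spectra).
* **Stitching** — tiles are placed on a whole-slide canvas at their
  stored global origins; non-overlapping tilings reconstruct exactly.
* **Artificial brightfield synthesis** — each marker plane is paired
  with DAPI and rendered through the Beer–Lambert model
  `out_ch = 255·exp(−(I_DAPI·c_ch,Hem + I_IHC·c_ch,DAB))`,
  `ch ∈ {R,G,B}`, using configurable hematoxylin/DAB stain vectors
  (Ruifrok–Johnston defaults), so detectors built for chromogenic IHC
  can run on fluorescence data.
* **Detection decoding and evaluation** — probability-map decoding
  (threshold + connected components + centroid merging), greedy box NMS,
  a classical Laplacian-of-Gaussian reference detector for synthetic
  validation, and radius matching of detections to dot annotations
  (4 µm lymphocytes / 21 µm macrophages) with the closest-detection
  tie-break, scored as precision / recall / F1.
* **Spatial quantification** — polygon ROIs with exclusions and a
  400 µm subcapsular band, densities in cells/mm², one-to-one
  double-positivity pairing (strict `<` radius), population
  subtraction (e.g. CD3⁺CD8⁻), mean shortest distances, and
  positive-pixel percentages (Otsu or fixed threshold) for capillary
  extent.
* **Cohort statistics** — Mann–Whitney U (exact for small samples),
  Spearman, signed-rank, Welch t, Fisher's exact, and median (min–max) /
  mean (SD) group summaries.

A first-class synthetic-scene generator plants cells with known marker
memberships, exact co-localization counts, a capillary mask with known
area fraction, ROI/capsule geometry, and renders everything through a
known spectral library (optionally with noise and CD68→CD4-style
spectral bleed-through) — so the entire pipeline is testable end to end
with no external data.

## Worked example

Simulate a 400 × 400 µm cortical scene, run the full pipeline, and
quantify:

```r
library(plexquant)

scene <- generate_scene(
  n_cells = c(CD3 = 60, CD68 = 12),
  coloc_fractions = data.frame(a = "CD3", b = "CD8", fraction = 0.5),
  scene_um = 400, capillary_fraction = 0.08, seed = 11)

rendered <- render_multispectral(scene, render_config(), tile_size_px = 256)
res <- run_synthetic_pipeline(rendered)   # unmix -> stitch -> convert -> detect

score_against_scene(res$detections, scene)
#>   marker tp fp fn precision recall    f1 density_detected density_planted
#> 1    CD3 59  0  1         1  0.983 0.992            455.2           463.0
#> 2   CD68 12  0  0         1  1.000 1.000             92.6            92.6
#> 3    CD8 30  0  0         1  1.000 1.000            231.5           231.5

cd3 <- res$detections[res$detections$marker == "CD3", ]
cd8 <- res$detections[res$detections$marker == "CD8", ]
dp  <- double_positive(cd3, cd8, radius_um = 4, pixel_size = scene$pixel_size)
cell_density(dp, scene$roi, population = "CD3+CD8+")
#> CD3+CD8+: 30 cells in 0.1296 mm2 = 231.5 cells/mm2

mean_shortest_distance(res$detections[res$detections$marker == "CD68", ],
                       cd3, pixel_size = scene$pixel_size)
#> mean shortest distance: 34.14 um (69.67 px) over 12 cells

positive_pixel_fraction(res$planes$CD34, scene$roi, method = "otsu")$percentage
#> [1] 7.748847
```

Reading the output: the reference detector recovers 59 of the 60 planted
CD3 cells (one close pair merges into a single detection) and all CD8
and CD68 cells; all 30 planted CD3⁺CD8⁺ cells are found by distance
pairing; the measured CD34⁺ pixel percentage (7.75%) sits within the
planted 8% capillary fraction up to mask-boundary effects.

A command-line wrapper over the same functions is installed at
`inst/cli/plexquant.R` with `simulate`, `unmix`, `convert`, `detect`,
`evaluate` and `quantify` subcommands.

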