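---
title: "Quantifying macrophage extracellular traps and cytoplasmic DNA puncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrophage extracellular traps and cytoplasmic DNA puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Macrophages stimulated with damage signals can release extracellular traps
(METs) — webs of nuclear DNA decorated with myeloperoxidase (MPO) and
citrullinated histone 3 (CitH3) — either by dying (pyroptosis) or, more
subtly, while remaining alive. In the vital route, nuclear DNA appears as
small cytoplasmic puncta that mature in stages (DNA dye only, then the
vesicular DNA dye SYTOX Orange, then MPO, then CitH3), drift toward the
future release site, and end up outside the cell as a CitH3-positive trap.

Quantifying this from fluorescence microscopy requires a chain of image
measurements, each simple on its own but easy to get subtly wrong in
combination: counting nuclei, gating condensed (apoptotic) nuclei, scoring
extracellular CitH3 signal while ignoring the nucleus, counting per-cell
cytoplasmic puncta and their staining combinations, measuring directional
bias of the puncta, restricting colocalization to the cytoplasm, and
extracting death kinetics from time-lapse series. `metquant` implements
this chain as tested, scriptable functions, and ships a synthetic-field
generator with complete ground truth so that every step can be validated
quantitatively rather than by eye.

## The pipeline model

All stages share one segmentation backbone
(`segment_particles()`): threshold, morphological closing, hole filling,
an optional watershed split of touching objects, connected-component
labeling, and per-label measurement (area, centroid, mean fluorescence
intensity MFI, bounding box). Coordinates are 0-based and pixel-centered,
x rightward and y downward.

The individual analyses are thin, explicit compositions of that backbone:

* **Nuclear counting** (`count_nuclei()`) segments the Hoechst channel with
  the watershed forced on; its count is the per-field denominator for every
  per-cell percentage.
* **Condensation gating** (`gate_condensed()`) flags nuclei that are small
  *and* bright: `area < area_max` and `MFI > mfi_min`. The default gate is
  *relative* — thresholds are fractions (0.7, 1.4) of the per-field medians
  — because absolute intensity gates do not transfer between acquisitions.
  The module constants are deliberate defaults, not fitted values, and at
  least 10 nuclei are required before medians are trusted.
* **MET scoring** (`quantify_mets()`) blacks out the nuclear regions of the
  CitH3 image, segments what remains, then dilates the binary mask three
  times with a radius-1 disk so that the several fragments that typically
  surround one releasing cell merge into a single countable object. The
  merged count over the nuclear count gives the MET-positive percentage;
  a fold ratio against an explicit reference percentage (typically the
  untreated control) is available.
* **Puncta analysis** (`find_cell_rois()`, `detect_puncta()`,
  `classify_puncta()`) finds cell bodies from MPO staining, detects DNA
  puncta after nuclear exclusion, assigns each punctum to the cell ROI
  containing its centroid (centroid containment is deterministic; puncta
  outside every cell are kept as "extracellular"), and scores four-channel
  positivity per punctum to produce the staged class fractions
  H / H+S / H+S+M / H+S+M+C.
* **Polarity** (`assign_quadrants()`, `polarity_summary()`) superimposes a
  circle on the nucleus, oriented so that quadrant 1 faces the MET anchor,
  pools z-slices, and tests quadrant 1 against quadrants 2–4 with Student
  t-tests on per-cell counts.
* **Colocalization** (`manders_cytoplasmic()`) computes the one-sided
  Manders coefficient M1 — the fraction of above-threshold cytoplasmic DNA
  intensity lying in protein-positive pixels — after removing the nuclear
  region from both channels. Only M1 is reported by default because a
  control cell with no cytoplasmic DNA makes the reverse coefficient
  meaningless; that same situation makes M1 itself *undefined* (not zero),
  and the function says so explicitly.
* **Kinetics** (`count_sytox_cells()`, `build_death_curve()`,
  `plateau_time()`) counts whole-nucleus SYTOX objects per frame
  (no tracking; frames are independent), normalizes to the nucleus count
  of frame 0 — the only frame in which the UV-excited Hoechst channel is
  acquired — and estimates the plateau of the resulting death curve.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `threshold` | Otsu per image | intensity | manual thresholds are irreproducible; a fixed override exists |
| `close_radius` | 1 | px | smallest closing that bridges single-pixel gaps |
| `watershed_h` | 1 (nuclei), 2 (cell bodies) | px | h-maxima suppression; tolerance scales with object size |
| `min_area_px` | 30 (nuclei), 3 (puncta), 40 (METs), 100 (cells) | px² | object-scale size filters; the punctum floor suppresses shot noise |
| `dilate_iterations` × `dilate_radius_px` | 3 × 1 | – / px | the fragment-merging dilation applied to MET masks |
| gate (`area_max`, `mfi_min`) | 0.7, 1.4 | fractions of medians | acquisition-independent relative gate |
| `nuclear_dilate_px` | 2 | px | guard band so blurred nuclear edges cannot masquerade as puncta |
| `min_fraction` (positivity) | 0.5 | – | a punctum is channel-positive if half its pixels exceed the channel threshold |
| plateau `tol`, `k` | 0.02, 4 | fraction / frames | the level is the mean of the last `k` points; onset is the first time the curve stays within `tol` of it |

Automatic thresholds come in three flavours where the image statistics
demand it: plain Otsu for unimodal-background channels; Otsu restricted to
the *non-excluded* pixels whenever a region has been blacked out
(otherwise the artificial zero mode dominates the histogram); and Otsu in
the log-intensity domain for the MPO channel, whose histogram is trimodal
(background, dim cell bodies, bright granule/trap signal) and defeats a
linear two-class split.

## The synthetic-field generator

`simulate_field()` renders cells as a disk nucleus inside a disk cell
body, METs as ellipse blobs tangent to the cell boundary, and puncta as
small disks in the cytoplasmic annulus, with angles drawn from a von Mises
distribution centered on the nucleus-to-anchor direction. The forward
optical model is Gaussian PSF blur, then constant background, then Poisson
shot noise, then Gaussian read noise; everything is deterministic given
`(config, seed)`.

The default condition emulates the biology the pipeline was built for:
about 20% pyroptotic cells, a few percent condensed nuclei at 0.4× area
and 2× Hoechst intensity, 16% MET-positive cells with one blob each,
negative-binomial punctum counts (mean 5) with staged marker combinations,
and polarized placement (κ = 4). The time-lapse generator uses a logistic
death-onset distribution (midpoint 5 h, scale 1.2 h) over 16 h at 15-min
intervals, reaching a ~20% plateau, with Hoechst rendered only at frame 0.
The punctum-count distribution is an explicit modelling choice — no
empirical distribution is available for it — and is exposed as a
parameter without any claim of fidelity.

Two deliberate simplifications matter when interpreting validation
results. First, puncta are rendered only in fields meant to emulate
high-magnification acquisitions; fields emulating low-magnification
nuclear counting and MET scoring are generated without puncta, because
sub-micrometre vesicles are unresolved at 10×. Second, puncta are placed
with a minimum separation (they model distinct vesicles), yet under
strong polarization they still occasionally merge in the rendered image;
the detector then reports fewer puncta than the truth list while class
*fractions* remain unbiased. Features of real data that the generator
does not attempt: irregular cell and nucleus shapes, intensity gradients
and vignetting, stitching seams, focus drift, photobleaching, and cell
motility between frames. Passing the validation suite therefore
demonstrates the correctness of the measurement chain, not robustness to
every real-world artefact.

## Numerical choices and conventions

* **Pipeline order.** Hole filling precedes the watershed split; the
  alternative order is not distinguishable from the written record of the
  original workflow, so the choice is fixed here and echoed in the run
  manifest.
* **Connectivity.** Components are 8-connected by default (the common
  particle-analysis convention); 4-connectivity is available. Watershed
  label order is normalized to raster order so outputs are deterministic.
* **Quadrant boundaries.** A punctum exactly on ±45° belongs to
  quadrant 1 and exactly on +135° to quadrant 2 (boundaries go to the
  lower-numbered quadrant); ties are measure-zero but must be
  deterministic.
* **Quadrant radius.** The counting circle defaults to the whole cell
  (infinite radius); no specific radius is claimed.
* **MET border objects.** Fragments touching the image border are
  excluded by default before merging, and the choice is logged.
* **M1 denominator.** The DNA channel is thresholded in the denominator
  (the thresholded-Manders convention); setting the DNA threshold to 0
  reproduces the unthresholded variant. Both are one flag apart.
* **z-stacks.** Per-slice punctum detections are linked into 3-D
  components under 26-connectivity; both per-slice and linked counts are
  reported, and per-cell summaries use the linked count so a punctum
  spanning slices is not double-counted.
* **Polarity test input.** Tests run on per-cell quadrant *counts*;
  per-cell fractions are also reported for inspection.
* **Degenerate inputs.** An image with no foreground yields an empty ROI
  table, not an error; a field with zero nuclei makes percentages an
  explicit error; a curve that never settles has an undefined onset with
  a reason; all-constant groups are a refusal, while identical
  non-constant groups give t = 0, p = 1.

## Validation problem sizes

The test suite validates the chain end-to-end on simulated fields chosen
to keep the suite fast while leaving no statistical ambiguity: nuclear
counting on twenty 200-cell fields (ten noiseless — recovered exactly —
and ten noisy, within 2%); condensation gating on one 1000-cell field at
a 4% condensed truth (recovered within one point under the default
relative gate); MET scoring on one 500-cell field at a 16% truth
(within one point, with the merged count non-increasing over dilation
iterations 0–5); class fractions on ~300–400 puncta (each within 0.05 of
the equiprobable truth); polarity calibration with 1000 Monte-Carlo
replicates of 9 cells (type-I error 5% ± 2% at κ = 0, power above 90% at
κ = 4); death curves from 65-frame series of 500 cells (noiseless curves
equal the truth CDF exactly; the noisy plateau is recovered within 0.02);
and 10,000-replicate null calibration of the two-group test (5% ± 0.6%).
Colocalization is checked against brute-force pixel loops to 1e-12 and a
hand-derived four-pixel example equal to 0.7 exactly.

## Known limitations

* Segmentation is classical (threshold + watershed); densely packed or
  highly irregular cells will need externally supplied masks, which every
  function accepts in place of its internally segmented ones.
* MET blobs are not attributed to individual source cells; the percentage
  is a field-level quantity, as in the original workflow.
* The positivity rule for punctum classification scores channels
  independently; strong bleed-through between channels would require
  spectral unmixing upstream.
* Death-curve extraction counts frames independently; a transiently
  mis-segmented frame perturbs single points but not the plateau
  estimate, which averages the final frames.
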