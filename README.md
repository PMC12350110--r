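# metquant

Quantification of macrophage extracellular traps (METs) and cytoplasmic
DNA puncta in multi-channel fluorescence microscopy.

## What it is for

Macrophages can release extracellular traps — webs of nuclear DNA carrying
myeloperoxidase (MPO) and citrullinated histone 3 (CitH3) — either
through pyroptotic death or *vitally*, while the cell stays alive. In the
vital route, nuclear DNA appears as small SYTOX-Orange-positive puncta in
the cytoplasm, acquires MPO and CitH3 in stages, drifts toward the future
release site, and ends up outside the cell. Studying this process means
turning four-channel images (Hoechst 33342, SYTOX Orange, MPO, CitH3) and
time-lapse series into numbers: cells, dead cells, condensed nuclei, MET
percentages, per-cell punctum counts and staining classes, directional
bias, colocalization coefficients, and death kinetics.

`metquant` packages this measurement chain for imaging scientists and
immunologists who want the analysis to be scriptable, deterministic and
testable instead of a sequence of manual GUI steps. A synthetic-microscopy
generator with full ground truth is included, so every stage is validated
against known answers.

## The quantities it computes

* **Nuclear count** `N` from watershed-split Hoechst segmentation — the
  denominator of every per-cell percentage.
* **Condensed (apoptotic) nuclei**: a nucleus is condensed iff
  `area < a·median(area)` and `MFI > m·median(MFI)` (defaults
  `a = 0.7`, `m = 1.4`).
* **MET-positive percentage**: nuclear signal is blacked out of the CitH3
  image, remaining fragments are segmented and merged by three radius-1
  binary dilations, and `% = 100 · n_merged / N`, optionally as a fold
  ratio over a control.
* **Per-cell DNA puncta**: detected after nuclear exclusion, assigned by
  centroid containment to MPO-derived cell ROIs, and classified into the
  staged combinations H, H+S, H+S+M, H+S+M+C by per-channel positivity.
* **Quadrant polarity**: puncta are counted in four 90° sectors of a
  circle on the nucleus with sector 1 facing the MET anchor; sector 1 is
  tested against sectors 2–4 (Student t on per-cell counts).
* **Cytoplasm-restricted Manders coefficient**

  ```
  M1 = Σ D_i [D_i > t_D][P_i > t_P] / Σ D_i [D_i > t_D]
  ```

  summed over extranuclear pixels only — the fraction of cytoplasmic DNA
  signal residing in protein-positive pixels. A field with no
  DNA-positive cytoplasmic pixel yields an explicit *undefined* result,
  not zero.
* **Death curves**: per-frame SYTOX-positive counts normalized to the
  frame-0 Hoechst count, with plateau level and onset estimation.

## Worked example

Simulate a noiseless 200-cell field under the default conditions (20%
pyroptotic cells, 2% condensed nuclei, 16% MET-positive cells with staged,
polarized puncta) and run the full analysis:

```r
library(metquant)

cfg <- sim_config(n_cells = 200, noise_poisson = FALSE, noise_gaussian_sd = 0)
sim <- simulate_field(cfg, seed = 1)
sim$truth
#> FieldTruth: 200 cells (40 pyroptotic, 4 apoptotic), 32 METs, 164 puncta

hoechst <- get_channel(sim$stack, "hoechst", 1)
nuc <- count_nuclei(hoechst)
nuc$count
#> [1] 203

quantify_mets(get_channel(sim$stack, "cith3", 1), nuc, reference_percent = 5)
#> METs: 32 raw fragment(s) -> 32 merged; 203 cells; 15.76% MET-positive
#>   fold vs reference: 3.15

gate_condensed(nuc, gate_spec())
#> Condensed nuclei: 4 / 203 (2.0%)

cells <- find_cell_rois(get_channel(sim$stack, "mpo", 1))
det <- detect_puncta(hoechst, nuc$labels > 0, cells)
cl <- classify_puncta(det, sim$stack, cells)
round(cl$class_fractions, 3)
#>       H     H+S   H+S+M H+S+M+C   other
#>   0.226   0.179   0.264   0.330   0.000
```

Reading the output: the simulator planted 32 MET blobs among 200 cells
(16%); the pipeline recovers all 32 and reports 15.76% because three
tight clusters of sub-resolution puncta in the crowded Hoechst channel
were counted as extra nuclei (203), slightly inflating the denominator —
exactly the kind of bias the ground-truth comparison is there to surface.
The four condensed nuclei are recovered exactly (2.0%), and the staged
class fractions track the truth mix of the 164 planted puncta. Detection
undercounts overlapping puncta (the `other` class stays empty; fractions
remain unbiased).

A thin command-line front end is included for shell use:

```sh
Rscript inst/scripts/metquant simulate --config cfg.yaml --seed 7 --out out/
Rscript inst/scripts/metquant mets --config cfg.yaml --tiff out/field.tif --out res/
```

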