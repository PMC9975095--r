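# gliamorph

Fully automated morphometry and activation scoring of microglia (and other
cells with complex, dynamic cytoarchitecture) in stitched 2D brain-section
images — fluorescent (IBA-1 / DAPI / CD68) or chromogenic (DAB).

Microglia move along a morphological continuum as they activate: from small
somata with long, ramified processes (surveilling) to compact amoeboid bodies
(phagocytic). `gliamorph` quantifies that continuum for every cell in a
high-content field:

* **Segmentation** by hysteresis (strong/weak) double thresholding combined
  with Sobel edge detection and morphological closing — only structures
  containing a strong-threshold pixel count as valid glia;
* **Soma extraction** by partial morphological thinning, opening, and
  dilation, so that only the thick cell body survives;
* **Single cell vs. cluster sorting** by overlap with the nucleus position
  matrix (DAPI centroids; soma centroids in chromogen mode) — structures
  covering no nucleus are discarded as out-of-layer process fragments;
* **Eleven per-object parameters**: percent fill, soma area, process length,
  morphology ratio, cell count, cell area, CD68 sum intensity, endpoints,
  branch points, span ratio, perimeter;
* **Continuous activation scoring** via the morphology ratio

  $$\mathrm{MR} \;=\; \frac{\text{total process (skeleton) length } [\mu m]}
  {\text{soma area } [\mu m^2]},$$

  with three-way classification (activated < t_low ≤ intermediate ≤ t_high <
  non-activated), colour-coded overlays, and a seeded **validation mode** that
  exports random single-cell crops plus agreement scoring against manual
  4-point ratings;
* **Optical-fractionator arithmetic** (`N = ΣQ⁻ / (ssf · asf · hsf)`) for
  benchmarking automated counts against stereology;
* A **synthetic scene generator** with exact ground truth, so the entire
  pipeline is testable without any external data.

## Worked example

```r
library(gliamorph)

# a synthetic field with known composition: 4 ramified, 3 intermediate,
# 3 amoeboid cells, rendered with realistic blur and noise
scene <- generate_scene(c(ramified = 4, intermediate = 3, amoeboid = 3), seed = 42)

thr <- calibrate_activation_thresholds()   # tercile calibration on the
                                           # bundled reference scene
res <- analyze_channels(scene$channels, list(thresholds = thr))
table(res$records$activation_class)
#>     activated  intermediate non_activated
#>             3             3             4
round(sort(res$records$morphology_ratio), 3)
#>  [1] 0.000 0.029 0.046 0.187 0.305 0.376 1.009 1.128 2.292 2.520
```

The ten detected cells partition exactly into the planted phenotypes: the
three amoeboid cells sit at ratios ≤ 0.05 (few or no processes — activated,
below the calibrated cutoff t_low ≈ 0.094), the three intermediate cells at
ratios ≈ 0.19–0.38, and the four ramified cells above 1 µm of process per
µm² of soma (non-activated, above t_high ≈ 0.75). The same run yields the full
eleven-parameter table (`res$records`), per-stratum ratio histograms
(`res$histograms`), and components for overlay/crop export.

File-based runs (`run_analyze()`, `run_validate()`) read TIFF channels, write
the four result CSVs (`single_cells`, `clusters`, `combined`, `histograms`),
a colour-coded overlay PNG, 10%-scale previews and a machine-readable
provenance log. A thin command-line wrapper with `analyze`, `validate`,
`synth` and `stereo` subcommands ships in `inst/cli/gliamorph.R`.

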