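---
title: "Automated microglia morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated microglia morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorph)
```

## The problem

Microglia shift along a morphological continuum as they activate: a
surveilling cell has a small soma and long, thin, branched processes; a
phagocytic cell is compact and amoeboid, with few or no processes. Manual
scoring of this continuum on a 4-point scale is slow and subjective.
`gliamorph` implements a fully automated alternative for stitched 2D
brain-section images: it segments every IBA-1-immunoreactive structure in a
field, separates single cells from clusters using nucleus overlap, measures
eleven morphometric and intensity parameters per object, and places each cell
on a continuous activation scale — the **morphology ratio**, total process
(skeleton) length divided by soma area, in µm/µm². The smaller the ratio, the
more activated the cell.

Both fluorescence (IBA-1 with DAPI nuclei and optionally CD68) and chromogenic
DAB labelling (dark stain on a bright transmitted-light background) are
supported; the chromogen image is inverted once at the start and everything
downstream is identical.

## Pipeline and its assumptions

1. **Hysteresis binarisation.** Candidate pixels are the union of a weak
   intensity threshold and a Sobel edge mask (edges recover faint thin
   processes that an intensity threshold misses). After morphological closing,
   only 8-connected structures that contain at least one *strong*-threshold
   pixel are accepted. This assumes glia somata are clearly brighter than
   background while processes may be faint. By default the weak threshold is
   the Otsu level of the channel and the strong threshold sits halfway between
   the weak level and the image maximum (`strong_scale = 0.5`); both can be
   given as absolute values when a batch has been calibrated externally. Edge
   pixels are admitted only above an intensity floor (half the weak threshold)
   because the gradient is strong on *both* sides of a boundary — without the
   floor every object would grow a one-pixel halo of background, biasing every
   area measurement upward by the object's perimeter.
2. **Mask correction.** Structures smaller than `min_structure_um2` (default
   10 µm²) are deleted, then holes up to `max_hole_um2` (10 µm²) are filled.
3. **Bridge separation.** A set pixel whose removal splits its component into
   two or more parts, each at least the small-structure minimum, is deleted
   (iterated to a fixed point). The area guard is what keeps thin processes
   intact: cutting a one-pixel-wide process strands a fragment below the
   minimum, so such cuts never qualify.
4. **Soma extraction.** Partial morphological thinning (3 iterations; each
   peels about one pixel off a convex boundary) followed by opening removes
   everything thinner than the opening element, leaving the thick central
   parts — the somata. The survivors are dilated back toward the original
   extent and intersected with the mask.
5. **Nucleus assignment.** Nuclei are detected in the DAPI channel (Otsu
   threshold, hole filling, small-object removal, distance-transform watershed
   for touching nuclei); their centroids form the nucleus position matrix.
   Each glia structure is annotated with the number of centroids it covers:
   zero means a process fragment from a cell body in another focal layer
   (discarded), one is a single cell, two or more a cluster. In chromogen mode
   there is no nucleus channel; soma-region centroids act as nucleus
   surrogates.
6. **Morphometry.** Per object: percent fill, soma area, process length,
   morphology ratio, nucleus count, cell area, CD68 sum intensity (raw
   values, never rescaled), endpoint count, branch-point count, span ratio,
   and perimeter — each physical quantity in both pixels and µm.
7. **Classification and reporting.** Three-way classification on the
   morphology ratio (`activated < t_low ≤ intermediate ≤ t_high <
   non_activated`), the ≤ 15-cell cluster filter, ratio histograms for single
   cells / clusters / all cells, colour-coded overlays (activated red,
   intermediate green, non-activated blue), CSV tables, and a seeded
   validation mode that exports per-cell crops for manual review.

## Parameters that matter

| Parameter | Default | Unit | Why this value |
|---|---|---|---|
| `pixel_size_um` | 0.334 | µm/px | Plausible for a 20× high-content objective; always a required user input, never read from metadata. |
| `strong_scale` | 0.5 | — | Strong threshold halfway from the weak (Otsu) level to the image maximum; robust to staining intensity differences between batches. |
| `closing_radius_um` | 0.5 | µm | Closing repairs sub-resolution staining gaps along thin processes. Much larger radii start fusing distinct processes running within a micrometre or two of each other, which corrupts skeleton topology. |
| `min_structure_um2` | 10 | µm² | Small-debris floor; also the minimum part size for bridge separation. |
| `thinning_iters` | 3 | iterations | Partial thinning depth before the soma opening; full thinning would erase the somata entirely. |
| `soma_opening_um` | 1.7 | µm | Must sit *below* the smallest expected soma radius minus the thinning erosion (≈ 3.2 − 1 µm) — otherwise small somata vanish — and *above* the half-width of the thickest process. |
| `soma_dilation_um` | 1.5 | µm | Slightly more than the thinning erosion (3 iterations × 0.334 µm ≈ 1 µm). The overshoot is intentional: the mask intersection caps the soma at the true cell boundary, and the margin prevents one-pixel mask rims surviving around the soma and skeletonising into spurious rings. |
| `min_spur_px` | 4 | px | Thinning a curved tube leaves staircase side-spurs up to ~3 px that would count as false branch points and endpoints; genuine side branches are much longer. |
| `thresholds` | calibrated | µm/µm² | See below. |
| `max_cluster_cells` | 15 | cells | Clusters above this are extreme outliers that dominate log-scale summaries and are removed from the reported tables. |

## Numerical choices

* **Coordinates.** In memory everything is a 1-based R matrix index, the
  idiomatic choice for R; the ROI JSON interchange format uses 0-based
  pixel-centre coordinates, converted only at the I/O boundary.
* **Connectivity** is 8-neighbour for foreground and 4-neighbour for
  background (hole semantics) throughout.
* **Skeleton length** uses link weights (orthogonal 1, diagonal √2) rather
  than pixel counts, which would understate diagonal runs by up to 29%. A
  diagonal link is skipped when the two pixels share an orthogonal skeleton
  neighbour — the path already runs through it, and counting both would
  overstate every staircase corner.
* **Skeleton cleanup.** Thinning a thick tube that bends sharply can produce
  a pixel-scale loop (read as two false junctions) and redundant staircase
  corner pixels (read as one false junction each). Sub-tube-sized skeleton
  holes (≤ 12 px) are filled and re-thinned, and corner pixels whose two
  neighbours are mutually adjacent are removed.
* **Endpoints are process tips.** A skeleton endpoint within 4 px
  (Chebyshev) of the soma is a retracted process *root*, not a tip — thinning
  pulls the blunt soma-side end of a skeleton a few pixels away from the
  boundary — and is excluded from the endpoint parameter. Junction candidates
  in the same zone are root artifacts and excluded from the branch-point
  count. Skeleton fragments lying entirely inside that zone are rim residues
  of the soma extraction and are dropped.
* **Root bridging.** Because of the same retraction, the bare skeleton length
  systematically understates process length; for every root-side skeleton end
  the straight-line gap to the nearest soma pixel (minus the one-pixel
  adjacency, capped at 7 px) is added back.
* **Degenerate cases.** A component with zero soma area is flagged
  `degenerate`, its ratio reported as missing, and it classifies as
  `activated` (a processes-free fragment sits at the terminal end of the
  scale). A collinear mask has an undefined minor axis; `span_ratio` returns
  a configurable cap (100) with a `degenerate` attribute. Histogram bins are
  half-open with a right-inclusive last bin; out-of-range ratios are clamped
  into the edge bins so counts always sum to the number of records.
* **Ties and rounding.** Replicate manual scores are averaged and rounded
  half-up ("closest whole number"). Spearman correlations use average ranks
  for ties and a Fisher-z interval with the Fieller–Hartley–Pearson variance
  1.06/(n − 3).

## Activation thresholds

The cutoffs between activated / intermediate / non-activated on the
morphology-ratio scale are a study-specific calibration, not universal
constants, so `classify()` takes them as explicit configuration. To keep the
tool runnable out of the box, `calibrate_activation_thresholds()` derives
defaults by tercile calibration on a bundled synthetic reference scene: a
balanced scene (25 cells per phenotype, seed 20230208) is analysed with the
standard pipeline and the terciles of the measured single-cell ratio
distribution become `(t_low, t_high)`. With a balanced reference the terciles
fall in the gaps between the phenotype distributions; because amoeboid cells
put a point mass at ratio 0, each cutoff is placed halfway between the
tercile and the next distinct observed ratio, which keeps the boundary inside
the gap rather than on the tie. For agreement scoring the 4-point manual
scale maps to the 3-class scheme as 4 → activated, 2–3 → intermediate, 1 →
non-activated.

## The synthetic-data generator

Every pipeline stage is testable without external data because the package
bundles a scene generator with exact ground truth. A cell is a rasterised
soma disc plus persistent random-walk processes with per-step branching;
processes are rendered as 3-px-wide tubes, nuclei as discs at the soma
centres, and CD68 as a phenotype-dependent intensity over the soma. Scenes
are rendered with Gaussian point-spread blur (0.4 µm), additive noise and a
constant background by default; with all three at zero the rendered glia
channel equals the geometric mask exactly. Every truth quantity — soma area,
total process length, endpoint and branch-point counts, CD68 total — is
computed from the constructed geometry, never from rendered pixels.

The default phenotypes emulate the activation continuum: ramified (soma
radius 3.2–4.5 µm, 4–6 processes of 15–30 µm, branching), intermediate
(4.2–6 µm, 2–4 × 8–15 µm), amoeboid (5.5–8 µm, at most one 5–8 µm stub, high
CD68). Monotonicity of soma size and CD68 across the continuum is built in.

The generator enforces geometric invariants so that drawn truth and measured
skeleton agree: distinct branches keep a centreline separation of 8 px
(closing can bridge tube-surface gaps up to ~4 px, and more where a rounded
tip cap faces another tube), walkers that cannot escape the soma
neighbourhood or their parent's corridor are erased from both canvas and
truth, and a walker ending within 12 px of its last branch point is trimmed
back to it (the stub would be swallowed by the junction blob and spur
pruning). Process lengths below ~5 µm are avoided by the defaults because
the ±2 px discretisation of skeleton ends would dominate shorter processes.

What the generator deliberately does **not** emulate: photorealistic tissue
texture, staining gaps along processes, vascular artifacts, out-of-focus
cells from other layers, or anisotropic PSFs. Passing the bundled tests
therefore demonstrates the pipeline's geometric and statistical correctness
on well-formed fields, not robustness to every real-tissue pathology; on real
sections the thresholds and structuring-element radii remain the user's
calibration responsibility.

## Problem sizes used in the tests

The bundled suite closes the loop between generator and measurement on a
20-cell noise-free scene (component count recovered exactly, endpoint counts
exact, process lengths within 15%, soma areas within 20%); orders the median
morphology ratio across 100 cells per phenotype; and recovers a planted
60/30/10 phenotype mix within binomial sampling error at n = 500 cells using
the reference-calibrated thresholds. The acceptance script repeats the same
computations at slightly smaller sizes (n = 250 for the mix) with scenes
derived from the caller's seed.

## Known limitations

* 2D only: morphology of maximum-intensity projections, not volumetric
  morphometry; no Sholl analysis or fractal dimension.
* Cluster cell counts rely on nucleus detection; heavily overlapping nuclei
  beyond what the watershed separates will undercount.
* The group-level statistics stop at descriptive geometric mean ratios and
  Spearman correlations. Repeated-measures random-effects modelling (animal
  random intercepts, covariate adjustment) is intentionally out of scope;
  export the per-cell tables and fit those models in dedicated software.
* The stereology module implements the optical-fractionator point estimate
  only; Gundersen coefficient-of-error machinery is not included.
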