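---
title: "Quantifying neurite networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurite networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromorph)
```

## The measurement problem

Cultured neurons — here, iPSC-derived spinal motor neurons — form dense
two-dimensional networks of neurites. A standard way to quantify network
morphology from fluorescence microscopy is to image two channels (a nuclear
stain such as DAPI, and a neurite marker such as Map2), segment the
neurites, thin the segmentation to one-pixel centerlines, and summarize the
skeleton per acquisition: number of somata, branches, junctions and
endpoints, and total and average branch length. Comparing these summaries
between genotypes (e.g. wild-type vs. a knockout line) with a one-way ANOVA
and a post-hoc multiple-comparison test gives the group-level readout.

`neuromorph` implements this whole chain, plus a synthetic two-channel
image generator with exact graph-level ground truth so that every stage of
the measurement can be validated quantitatively — something impossible with
real images, where no ground truth exists.

## The segmentation model

The pipeline follows a dual-mask design:

1. **Nuclei / soma mask.** The nuclear channel is thresholded with the
   Huang minimum-fuzziness algorithm; connected components with
   equivalent-circle radius below 20 px are discarded as debris; the
   surviving nuclei are expanded by 5 px (exact Euclidean dilation) to
   cover the thin cytoplasmic rim of mature motor neurons. The
   *pre-expansion* mask is kept for soma counting; the *expanded* mask is
   subtracted from the neurite mask.
2. **High-intensity mask.** The marker channel is contrast-enhanced
   (0.1% of pixels saturated, half per tail), Gaussian-blurred
   (σ = 2 µm) and thresholded with Tsai's moment-preserving algorithm.
   This captures somata, axon hillocks and bright neurite cores.
3. **Ridge (LoG) mask.** An independently contrast-enhanced copy is
   filtered with a Laplacian-of-Gaussian and thresholded with the Moments
   algorithm. This recovers the thin, faint distal neurite segments the
   blurred branch misses.
4. **Combination.** Final neurite mask = (high ∪ ridge) \ expanded soma
   mask, followed by removal of components below 50 px (see below).

All thresholds are functions of the gray-level histogram only, computed on
native integer levels, with the fixed convention *foreground = strictly
above threshold*.

### Numerical choices in the masking stage

* **Pixel calibration.** The default calibration is 0.207 µm/px with a
  nominal 212.3 µm field. The default field is trimmed to 1024 px
  (211.968 µm) so the raster has a convenient power-of-two side; any other
  size uses `floor(field/pixel)`.
* **LoG scale (0.6 µm ≈ 3 px).** The workflow this package automates
  names no LoG scale, so the choice is ours and it matters. We calibrated
  it on synthetic scenes with known ground truth: at σ well below the
  PSF-broadened neurite width the response contour is ragged and the
  skeleton sprouts spurious junctions; at σ ≈ 1 µm neighboring branches
  merge and branch counts collapse. σ = 0.6 µm maximized recovery
  fidelity of branch and junction counts (both under 10% median relative
  error) and is exposed as `masking_params(log_sigma_um=)`.
* **8-bit quantization of the LoG response.** The signed response is
  min-max rescaled to 256 levels before thresholding, exactly what an
  interactive workflow does when converting a float filter result for
  display and thresholding. This is not a cosmetic detail: on a
  16-bit-resolution histogram the background-noise lobe of the band-pass
  response spreads over thousands of levels and the moment-preserving
  split can land inside it, flooding the mask with speckle. At 256 levels
  the lobe collapses into a few bins and the split lands at its edge. As a
  second guard, the ridge threshold is floored at the modal response level
  — neurites are sparse, so the histogram mode is background by
  construction.
* **Despeckle (50 px).** Shot noise that survives the ridge threshold
  forms blobs of a few dozen pixels, while real neurite fragments live in
  components hundreds to thousands of pixels large (the two distributions
  are separated by more than an order of magnitude in our simulations).
  Components below 50 px (~2 µm²) are therefore removed from the final
  mask. This step is not part of the original interactive workflow — where
  an operator would visually reject speckle — and can be disabled with
  `neurite_min_component_px = 0`.
* **Contrast enhancement** saturates half the stated fraction at each
  tail, with clip bounds taken as order statistics of the sorted pixel
  values; ties at the threshold go to background everywhere.

## Skeleton analysis

The neurite mask is thinned with a Guo–Hall-type two-sub-iteration
algorithm. Candidate pixels are selected in parallel against a snapshot
(the classical directional conditions), then deleted *sequentially* in
column-major order with a connectivity re-check against the current image.
The re-check makes every deletion a simple-point deletion, so the number of
8-connected components is preserved exactly — the purely parallel variants
can delete an isolated 2×2 block or a 2-px-wide diagonal outright. Thinning
iterates to a fixed point, which makes the operator idempotent.

Skeleton pixels are classified by their 8-neighbor count: endpoint (1),
slab (2), junction (≥ 3); isolated pixels (0 neighbors) are excluded from
branch statistics. Mutually adjacent junction pixels merge into one
junction *cluster*, counted as a single junction. A branch is a maximal
slab path between two terminals; its length accumulates 0.207 µm per
orthogonal step and √2 × 0.207 µm per diagonal step, including the steps
onto its terminal pixels. Note that a cluster absorbs the pixels adjacent
to a meeting point, so e.g. a symmetric "+" of two 11-px bars yields four
arms of 4 steps each — the analytic values in the test suite are computed
under exactly this convention. Isolated closed loops are reported as single
branches of their cycle length. Spur branches are *not* pruned (the
workflow we automate describes no pruning); per-image average branch length
is total length / branch count, reported as 0 with a flag when an image has
no branches.

Soma counting is automated as 8-connected component counting of the
pre-expansion nuclei mask, replacing the manual multipoint counting of the
original protocol. On synthetic scenes this is exact whenever nuclei do not
touch, which the generator's placement constraint guarantees.

## The synthetic-data generator

`generate_acquisition()` emulates a single confocal field:

* **Geometry.** `n_cells` = 10 non-overlapping nuclei (9–15 µm diameter)
  are placed uniformly with a 2 µm clearance. Each cell sprouts 2–4
  primary neurites. The 9 µm floor keeps every nucleus above the 8.3 µm
  equivalent diameter implied by the 20 px mask cutoff, whose role is to
  remove debris, not nuclei.
* **Growth model.** Each neurite elongates in steps of exponential length
  (mean 14 µm, clamped to [1, 42] µm) with Gaussian angular jitter
  (σ = 0.25 rad). After each step the tip bifurcates with probability
  `branching_prob` (default 0.22, up to depth 5; daughters diverge by
  ±0.6 rad), else terminates with probability 0.2, else keeps growing;
  growth also stops at the field border. `branching_prob` is the single
  density knob: halving it emulates the sparser knockout phenotype while
  leaving somata counts untouched.
* **Rendering.** Nuclei are anti-aliased disks; somata render in the
  marker channel at 1.3× the neurite signal; neurites are anti-aliased
  polylines 1–3 px wide whose intensity decays exponentially with arc
  distance from the soma (length scale 150 µm). Both channels are
  convolved with a Gaussian PSF stand-in (σ = 0.25 µm, the lateral
  resolution of a high-NA confocal), then Poisson shot noise
  (0.05 photons/ADU) and Gaussian read noise (σ = 60 ADU) are applied, and
  the result is quantized to 16 bits over a 400 ADU background with
  8000 ADU peak signal. No published intensity statistics exist for the
  experiments that motivated these defaults; they are our choices and are
  stated as such.
* **What it does not model.** 3-D growth (z-stacks are only repeated
  planes for projection tests), photobleaching, optical aberrations beyond
  the Gaussian PSF, fasciculation, or varicosities. Passing recovery tests
  on these scenes therefore shows the measurement chain is correct for
  clean, resolvable networks — not that it is robust to every real-data
  pathology.

### Ground truth is the *apparent* network

The generator knows the biological forest it grew, but a measurement of the
image cannot: everything inside the expanded soma disks is erased, and two
neurites crossing in 2-D projection form a visible four-way junction. The
`true_metrics` therefore describe the **apparent planar network**: the
forest clipped against each soma disk grown by the downstream 5 px
expansion margin, then planarized at every inter-polyline crossing (each
crossing becomes a degree-4 junction node splitting both edges). At the
default density roughly a third of apparent junctions are crossings. Both
representations are returned (`nodes`/`edges` for the apparent network,
`tree_nodes`/`tree_edges` for the grown forest), and the self-consistency
of `true_metrics` with the exported graph is enforced by an independent
recomputation in the test suite. Endpoint counts exclude soma-attachment
nodes; the measured skeleton reports those as endpoints too, which is why
endpoint counts are emitted but not compared against truth.

## Statistics

`anova_multicompare()` fits a one-way ANOVA across groups and runs all
pairwise post-hoc comparisons, Tukey HSD by default (Bonferroni-adjusted
pooled-variance t tests as the alternative — the reporting convention we
mirror does not name its correction, so the method is configurable and
always recorded in the report). Significance stars follow *, **, ***, ****
at p ≤ 0.05, 0.01, 0.001, 0.0001. Boxplot summaries use linear-interpolation
quantiles (R type 7) and Tukey fences (1.5 × IQR) for outliers, so every
reported number is bit-reproducible. `two_group_ttest()` is the classical
two-tailed Student t test (pooled variance when unpaired). On two groups
the ANOVA F equals t² exactly; this identity and the driver's type-I error
calibration are both asserted in the test suite. Images are the units of
analysis within groups, as in the per-acquisition boxplots we mirror;
replicate ids are carried as a column but no mixed-effects structure is
fitted. Metrics with no within-group variance anywhere (somata counts when
both groups fix `n_cells`) yield a flagged degenerate record instead of an
error.

`run_experiment()` streams a simulated cohort — generate, measure, discard
— so memory stays flat, and derives every per-image seed from one master
seed; the whole report, including the JSON serialization, is bit-identical
across reruns.

## Problem sizes used in the checks

The test suite and the acceptance script validate recovery on 20 clean
full-size acquisitions (1024² px) and the phenotype direction on a cohort
of 10 acquisitions × 3 replicates × 2 groups with the knockout emulated by
halving `branching_prob` — the acquisition counts and replicate structure
of the experimental design we mirror. Threshold-oracle, skeleton-golden,
topology and calibration checks run on small rasters and take seconds.

## Known limitations

* Junction counts are the least robust metric: shallow-angle crossings
  split into two nearby junction clusters, and near-tangent passes merge
  mask ribbons; at the default density the median relative error against
  the apparent-network truth is ~6–10%, not zero.
* The Moments threshold on a band-pass response is only stable thanks to
  the 8-bit quantization and the mode floor; images whose structure
  occupies well over half the field would violate the sparsity assumption
  behind the mode floor.
* Ground-truth branch lengths are clipped at an idealized disk around each
  soma, while the measured mask subtracts the thresholded, expanded
  nucleus; the residual disagreement in total length is a few percent and
  is why length recovery is validated at the cohort level, not per edge.
* The per-cell positivity rule (≥ 50% of region pixels foreground,
  `scoring_params(positive_fraction=)`) is our operationalization of
  particle-based double-positive counting; the original protocol does not
  state one.
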