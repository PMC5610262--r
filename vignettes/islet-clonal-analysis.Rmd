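---
title: "Methods: clonal, volumetric, calcium and spatial analysis of multicolor-labeled islets"
author: "isletrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal, volumetric, calcium and spatial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletrace)
```

# The problem

Multicolor (Brainbow-style) lineage tracing marks zebrafish beta-cells
with stochastic combinations of red, green and blue fluorophores. A cell
carries several independent Cre-lox cassettes; each expresses red by
default and can recombine once to green or blue. Trichromatic cells —
expressing all three colors at once — require at least two independent
recombination events, so they are rare, and their continuous (R,G,B)
intensity mix forms a heritable color barcode. Descendants of one
trichromatic founder share its barcode; clones can therefore be read out
years of cell divisions later by asking which cells carry statistically
indistinguishable color signatures.

`isletrace` implements the downstream quantitative machinery of such an
experiment: clone calling from per-cell color measurements, cell-number
estimation from 3D volumetry, leaky-recombination probability
arithmetic, glucose-responder classification from GCaMP calcium traces,
and anterior/posterior (A/P) islet asymmetry statistics. A synthetic-data
generator with complete ground truth makes every stage testable without
any imaging data.

# Clonal analysis

## From raw intensities to signatures

Input is one row per manually selected cell nucleus: per-channel pixel
mean and standard deviation, ROI pixel count, and the 3D centroid
(`readCellTable()` schema). Processing follows four steps:

1. **Background subtraction** (`subtractBackground()`): the mean green
   and blue intensities of at least three unlabeled cells are subtracted
   from each labeled cell's green and blue means, clamping at zero. The
   red channel is *not* background-subtracted — red is the default,
   unrecombined state and the original procedure used it as measured.
   This asymmetry is deliberate and preserved.
2. **Triple-positive gate** (`isTriplePositive()`): a cell enters clonal
   clustering only if `C_mean − 2.58 · C_sd > 0` in every channel
   (strict). 2.58 is the two-sided standard-normal critical distance at
   p = 0.01, so a channel with zero true signal passes at most about 1%
   of the time; the acceptance suite verifies both the constant and the
   calibration on simulated dark channels.
3. **Normalization** (`normalizeSignature()`):
   `C_normalized = C_mean / (R_mean + G_mean + B_mean) × 100`. The three
   percentages sum to 100 (checked to 1e-9); a zero channel sum is a
   degenerate-signal error, not a silent NaN.
4. **Ternary coordinates** (`ternaryCoordinates()`, `plotTernary()`):
   barycentric map onto the unit equilateral triangle for visual clone
   assessment.

## Equivalence testing and clustering

Two triple-positive cells are "the same barcode" when a two one-sided
tests (TOST) procedure declares their normalized signatures equivalent
in all three channels (`tostPair()`). Per channel, the difference of
normalized means is tested against an equivalence margin with two
one-sided Welch-type t tests; equivalence requires both one-sided
p-values below `alpha` in every channel.

Numerical choices worth knowing:

* **sd propagation.** Pixel sds are recorded on the raw channel scale
  but the test runs on the normalized scale, so the variance of each
  normalized mean is obtained by the delta method on
  `C/(R+G+B)`, treating channels as independent and using
  `sd² / n_pixels` as the variance of each raw channel mean. The test
  suite checks the resulting decisions against an independently coded
  oracle that uses numeric gradients and the confidence-interval
  formulation of TOST.
* **Degrees of freedom** are Welch–Satterthwaite with `n_pixels − 1` per
  cell. `n_pixels < 2` is an error: an sd needs at least two pixels.
* **The margin is a free analysis parameter.** The default is
  `marginPct = 10` percentage points per channel at `alpha = 0.05`. No
  principled universal value exists — the margin trades splitting clones
  (too small) against merging distinct barcodes (too large) — so it is a
  mandatory, prominently echoed field in every clone table and manifest.
* **No multiple-testing correction by default**: each pair is tested at
  p < 0.05, matching the original per-pair procedure. A Bonferroni
  option (`bonferroni = TRUE`) divides alpha by the number of pairs for
  users who prefer family-wise control.
* **Noise-free channels** (sd exactly 0 on both sides) cannot support a
  t test; the decision falls back to comparing the raw difference with
  the margin.

Clones are the connected components of the pairwise equivalence graph
(`clusterClones()`): if a cell is equivalent to members of two groups,
all of them merge into one clone. Clustering never crosses islet
boundaries. `clonalitySummary()` reports the percentage of tracked
events (clones, not cells) that stayed single versus formed
multicellular clones, and `compareClonality()` compares two stages with
a two-sided Fisher exact test — the all-zero table returns p = 1 by
documented convention.

The transitive-union rule makes equivalence behave non-transitively in
an important way: A~B and B~C can hold while A~C fails, and all three
still form one clone. Enlarging the margin only adds edges, so it can
merge clones but never split them (verified as a property test).

# Volumetry and cell-number estimation

`labelObjects3d()` thresholds a grayscale stack (Otsu's method on the
8-bit-converted histogram by default, manual cutoff supported) and
labels foreground voxels into connected components, 26-connectivity by
default (6 available). Labels are assigned in raster-scan order of each
component's first voxel, so output is deterministic. Per object it
reports voxel count, volume (`voxel_count × voxelSize³`), a 0-based
half-open bounding box, and the centroid. Volume is conserved exactly:
the per-object volumes sum to the thresholded foreground voxel count
times the voxel volume.

Cell number is estimated as a volume ratio (`estimateCellNumber()`):
total beta-cell volume (all-channel composite, `totalBetaVolume()`)
divided by the mean single-cell volume. Single cells are measured on the
green+blue composite only — cells with distinct recombination labels
separate there, while red is common to all — and an isolation window
excludes fused objects that the threshold cannot split
(`singleCellVolumes()`, default window 50–500 µm³ around the ~185 µm³
single-cell scale). For synthetic stacks, where the generating volume
distribution is known exactly (mean 185, sd 35 µm³), the analyses in
this package use the matched window mean ± 3 sd = [80, 290] µm³: a
touching pair of ~185 µm³ cells yields a ~370 µm³ fused object that the
wide window would wrongly admit into the single-cell pool. On ten
rendered islets spanning 30–300 cells this keeps the mean relative
cell-count error around 2% (recomputed by `scripts/acceptance.R` and the
acceptance tests; the mirrored validation bound is 10%).

`backgroundRecombination()` implements the leaky-recombination
arithmetic: `p_single = events / (cells_per_islet × islets)`, and the
probability of a spontaneous trichromatic cell (two independent events)
is its square. Following the published convention, `p_single` is rounded
to one significant figure *before* squaring — 4 events over 10 islets of
~820 cells gives 0.0005 and hence 2.5e-7 — and the unrounded variants
are reported alongside.

# Calcium responder classification

Traces follow the standard ex vivo protocol (`glucoseRampProtocol()`):
basal 5 mM glucose, glucose steps (10, 20 mM), and a final 30 mM KCl
depolarization. `normalizeTrace()` computes `F0` (mean raw F over the
basal phase, at least 3 samples) and rescales as
`(F − F0)/(Fmax − F0)`; flat traces are flagged, not fatal.

Three thresholds govern classification, all expressed in basal standard
deviations of the raw trace and all echoed into outputs:

* `qcKcl()` (`kSd = 3`): a cell must raise its KCl-phase mean more than
  3 basal sds above the basal mean, otherwise it is excluded from all
  quantification — KCl depolarizes every healthy beta-cell, so failure
  indicates a sick cell or a segmentation artifact.
* `classifyResponder()` (`kSd = 3`, `dwell = 0.1`): a responder exceeds
  basal mean + 3 sd for at least 10% of the samples within some glucose
  phase. No numeric criterion was available to inherit, so both
  constants are explicit configuration with these defaults.
* The basal-activity exclusion ("responding" already at 5 mM glucose
  disqualifies a cell) uses a *fixed* multiplier `kSdBasal = 3`,
  independent of `kSd`. Coupling it to `kSd` would make the responder
  count non-monotone in the threshold: lowering `kSd` would
  simultaneously admit more responders and disqualify more cells at
  basal. With the fixed basal gate the responder set shrinks
  monotonically as `kSd` grows (property-tested), and the call is
  invariant to affine rescaling of the raw trace since every threshold
  derives from the trace's own basal statistics.

`regionalResponderStats()` aggregates per-cell calls into per-islet
anterior/posterior responder percentages (mean ± SEM across islets) and
the posterior/anterior responsiveness ratio; across stages the ratios
are compared with Kruskal–Wallis followed by pairwise two-sided Wilcoxon
tests. Islets with zero anterior responders yield an infinite ratio,
which is flagged and excluded from the rank tests with a warning.
`classifyH2bStatus()` makes the label-retention call: a cell is
H2B-negative when its mean intensity is within `k = 2` background sds of
the background mean ("similar to background").

# A/P partition

`splitAp()` places the islet center at the midpoint of the segment
joining the anterior and posterior tips on the (x,y) projection plane
and divides with the perpendicular line through it. Points exactly on
the divider go anterior — the tie-break is arbitrary but fixed and
documented, and with continuous coordinates it is measure-zero. Tips
are user-supplied (the original procedure placed them manually on a
maximum-intensity projection) or estimated as the most distant centroid
pair, with the smaller-x tip called anterior by convention to match the
simulator's geometry. The partition is invariant under rigid motions
and anti-symmetric under tip exchange (both property-tested).
`labelingRatio()` sums green+blue intensity per half (posterior over
anterior); `regionalCounts()` counts predicate-satisfying cells per
half, compared across islets with a paired two-tailed t test. One known
divergence from the manual procedure: the original outlined each
half-area by hand before integrating intensity, so pixels at the islet
boundary could be assigned differently there than by the automated
side-of-divider rule.

# The synthetic-data generator

The generator produces the statistical structure the analyses assume,
with complete ground truth:

* **Recombination** (`simulateRecombination()`): independent cassettes,
  default 3 per cell (a "multiple cassettes" construct without a
  published count; configurable), each recombining with probability
  `pRecomb` during induction plus `pLeaky` spontaneously, switching to
  green with probability `pGreen`. Color class follows from the
  expressed-color set; the trichromatic frequency matches exhaustive
  enumeration of the cassette outcome space (tested within 3 binomial
  sds at n = 1e5).
* **Growth** (`simulateIslet()`): a quiescent fraction of founders never
  divides; the rest follow a discrete-generation branching process —
  each proliferative cell gains `Poisson(divisionRate)` daughters per
  inter-stage interval, daughters inheriting cassette states and
  expression levels exactly. This reproduces the qualitative clone-size
  shape (singletons plus multicellular clones) without claiming real
  division kinetics, which are not identifiable from endpoint clone
  sizes. Per interval, `Poisson(neogenesisRate)` unrecombined red-only
  cells join the islet.
* **Geometry**: positions fall in a prolate ellipsoid whose long axis is
  the A/P axis (anterior = negative x); embryonic-lineage cells are
  biased posterior and post-embryonic cells anterior with probability
  `apBias = 0.9`, emulating the hourglass age polarity. Packing uses
  `fillFraction = 0.12` of the ellipsoid volume — enough crowding for
  occasional touching cells without routinely fusing the whole islet.
* **Barcodes**: each founder cassette carries a lognormal expression
  level; channel intensity is the summed level of cassettes expressing
  that color. Signatures are therefore continuous and heritable. For
  recovery benchmarks, `minSignatureSep` instead assigns trichromatic
  founders well-separated signature targets chosen by greedy
  farthest-point selection on the color simplex (every channel ≥ 10%),
  because independent lognormal draws essentially never separate three
  or more clones by 40 percentage points.
* **Measurements**: ROI pixel count is uniform on
  `pixelsPerCellRange = [30, 80]`; channel means and sds are the
  empirical statistics of `n_pixels` Gaussian draws around the true
  intensity plus channel background. This supplies exactly the
  `(mean, sd, n)` triple the TOST needs.
* **Rendering** (`renderStack()`): each cell becomes a compact blob of
  `round(volume/voxel volume)` voxels grown from its centroid voxel;
  cells are mutually exclusive in space, a crowded blob deforming into
  the nearest unclaimed voxels, so total foreground volume equals total
  true volume to within a voxel per cell. 16-bit intensities: foreground
  ~3000, background ~200, Gaussian noise sd 100 — cleanly bimodal for
  Otsu. No point-spread function, no optics.
* **Calcium traces** (`simulateCalciumTraces()`): phenomenological —
  baseline plus a sustained plateau during glucose phases for true
  responders and a large KCl peak for all cells except a configurable
  QC-fail fraction, plus Gaussian noise. No biophysical calcium model,
  no oscillations.
* **Growth defaults** are free parameters (no published per-stage count
  trajectory exists beyond a ~820-cell estimate at 30 days
  post-fertilization): 30 founders, quiescent fraction 0.4 (the
  single-cell fraction observed at 30 dpf), division rate 0.5 per
  interval, 50 neogenesis cells per interval, cell volume 185 ± 35 µm³
  around the published 184.70 µm³ single-cell mean, stages 3.5/15/30
  dpf.

What passing tests on this generator do *not* show: robustness to
segmentation errors, spectral bleed-through between channels, spatially
correlated background, photobleaching within calcium recordings,
oscillatory (rather than plateau) glucose responses, or anisotropic
voxels. The pipeline starts from per-cell measurements and treats all of
those as upstream problems.

# Reproducibility and problem sizes

Every stochastic entry point takes an explicit seed, scopes it (the
caller's RNG state is untouched), and reproduces byte-identical tables.
`runPipeline()` writes a JSON manifest with the full configuration,
seed, package version and MD5 checksums of all inputs and outputs;
identical config and seed give identical checksums.

The shipped validation analyses use deliberately desk-sized problems:
ten rendered islets of 30–300 cells for the volumetric benchmark, 20
simulated islets of ~10 founders for clone recovery (mean adjusted Rand
index ≥ 0.9), cohorts of 200 traces for responder-fraction recovery
(within 3 binomial sds), random stacks up to 20³ voxels against the
flood-fill oracle, and brute-force clustering oracles up to 50 cells.
The published biological percentages themselves (single-cell fractions
per stage, regional responder percentages, fold-growth) derive from raw
imaging data that was never deposited, so they are validated here as
recovery properties on synthetic ground truth rather than as numbers to
reproduce.
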