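# isletrace

Quantitative analysis of multicolor (Brainbow-style) lineage tracing in
the zebrafish pancreatic islet, for researchers who study beta-cell
development with clonal color barcoding, 3D volumetry, GCaMP calcium
imaging and regional (anterior/posterior) comparisons.

In these experiments each beta-cell carries several independent Cre-lox
cassettes that express red by default and can each recombine once to
green or blue. Trichromatic cells — expressing R, G and B together —
require at least two independent recombination events, so they are rare
and their continuous color mix is a heritable clonal barcode. The
package turns per-cell fluorescence measurements, image stacks and
calcium recordings into clone calls, cell counts and responder
statistics:

* **Clonal analysis** — background subtraction (green/blue only, as in
  the original procedure), the triple-positive gate
  `C_mean − 2.58·C_sd > 0` per channel, signature normalization
  `C_norm = C_mean/(R+G+B) × 100`, pairwise equivalence by a two
  one-sided tests (TOST) procedure with delta-method error propagation
  and Welch degrees of freedom, transitive-union clustering into clones,
  ternary plots, and Fisher-exact stage comparisons.
* **Volumetry** — Otsu threshold + 3D connected components
  (26-connectivity), beta-cell number as
  `total volume / mean single-cell volume`, and the
  leaky-recombination arithmetic
  `p_single = events/(cells × islets)`, `p_trichromatic = p_single²`.
* **Calcium** — `(F − F0)/(Fmax − F0)` normalization against the basal
  phase, a KCl depolarization quality gate, threshold-based
  glucose-responder calls, and posterior/anterior responsiveness ratios
  with Kruskal–Wallis / Wilcoxon stage comparisons.
* **Spatial** — anterior/posterior half-split perpendicular to the tip
  axis at its midpoint, labeling ratios and paired regional counts.
* **Synthetic data** — a simulator for cassette recombination, clonal
  growth, voxelized islet stacks and calcium traces with complete ground
  truth, so every stage is validated against known answers.

## Worked example

Simulate a small islet with well-separated clonal barcodes, cluster its
trichromatic cells into clones, and summarize clonality:

```r
library(isletrace)

isl <- simulateIslet(
  growthConfig(nFounders = 10, quiescentFraction = 0.3,
               divisionRate = 0.8, stages = c(3.5, 15),
               neogenesisRate = 0),
  recombinationConfig(pRecomb = 0.65),
  noiseConfig(), seed = 1, minSignatureSep = 40)

cs <- clusterClones(isl$cells, tostParams(marginPct = 10, alpha = 0.05))
cs
#> CloneSet for islet islet_1
#>    4 clones ( 2 single-cell, 2 multicellular ), 6 cells
#>    8 cells excluded (not triple-positive)
#>    margin = 10 pct, alpha = 0.05

clonalitySummary(cs)$pct_multi
#> [1] 50
```

Of the 14 simulated cells, 6 are trichromatic and pass the
triple-positive gate; TOST clustering groups them into 4 clones (2
quiescent single cells, 2 two-cell clones), and every call matches the
simulator's ground-truth clone labels. The non-trichromatic cells are
excluded, mirroring the restriction of clonal analysis to trichromatic
events.

The worked volumetric and probability examples:

```r
est <- estimateCellNumber(151337.80, 184.70)
round(est$raw, 1); round(est$raw, -1)
#> [1] 819.4
#> [1] 820

backgroundRecombination(4, 820, 10)[c("p_single", "p_trichromatic")]
#> $p_single
#> [1] 5e-04
#> $p_trichromatic
#> [1] 2.5e-07
```

And responder-fraction recovery on a simulated cohort of 200 traces with
a true responder probability of 0.6:

```r
pr <- glucoseRampProtocol()
sim <- simulateCalciumTraces(calciumCohortTruth(200, 0.6, seed = 2),
                             pr, noiseSd = 2, seed = 3)
calls <- classifyTraces(sim$traces, pr)
mean(calls$call[calls$qc_pass] == "responder")
#> [1] 0.5945946
```

185 of 200 cells pass the KCl quality gate (the simulated QC-fail
fraction is 5%) and the estimated responder fraction of 0.595 recovers
the true 0.6 well within binomial error.

Command-line runs of the same stages (`simulate`, `clones`, `volumes`,
`calcium`, `spatial`) are available through `runPipeline()` or the thin
wrapper in `inst/cli/isletrace.R`; every run writes a JSON manifest with
the configuration, seed and file checksums.

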