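---
title: "Pulse-shape morphology of filamentous fungi: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-shape morphology of filamentous fungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsemorph)
library(dplyr)
```

## The measurement model

A large-particle flow cytometer records, for every particle transiting the
laser, a sampled intensity curve per channel — the *pulse shape*. Spatial
position along the particle maps to sample index, so a long hyphal
aggregate produces a long pulse. Three channels matter here: forward
scatter (FWS, size/opacity; clipped at a saturation level of $10^4$ a.u. on
dense material), sideward scatter (SWS, surface and internal structure) and
green fluorescence (FL_GREEN, fluorescein-diacetate viability stain).

From each pulse we compute five curve parameters. With samples
$v_1,\dots,v_n$, calibration $u$ µm/sample, and trigger level $t$:

* **maximum** $= \max_i v_i$;
* **total** $= \sum_i v_i$, a unit-width Riemann sum in a.u. (the gating
  thresholds for totals are quoted in a.u., so no µm weighting is applied);
* **length** $= n\,u$, the full recorded extent;
* **sample length**: the extent of the *envelope* from the first to the
  last sample with $v_i > t$, in µm — the method's primary size measure;
* **fill factor**: mean of the envelope samples divided by the maximum,
  clipped to $[0,1]$.

The fill factor is only verbally specified in the field ("similarity to a
block, 0–1"); the mean/maximum ratio is the simplest statistic satisfying
both anchors — exactly 1 for a rectangular pulse, small for spiky pulses —
and is what this package uses. Interior dips below trigger are kept inside
the envelope, which makes sample length robust to noise dips; a pulse
entirely below trigger has sample length 0 and fill factor 0. The trigger
default is 0 and always explicit, since the instrument's internal trigger
is not recorded in the data files.

The instrument calibration `um_per_sample` has no universal default — it
depends on flow speed and sampling rate — so it is a required metadata
field; the simulator uses 1 µm/sample.

## The gating tree

Viable particles (FL_GREEN total strictly greater than 30 a.u.; everything
else is medium background) pass a three-stage decision tree with the
published thresholds as defaults, all inequalities strict:

1. **small vs large**: large iff SWS total > 2·10⁴ *and* sample
   length > 100 µm;
2. **large → pellet vs large clump**: pellet iff SWS total > 4·10⁴, sample
   length > 120 µm, FWS saturated (dense core), FWS max / FWS fill
   factor > 7.5·10³ and SWS total / sample length > 8·10²;
3. **small → small clump vs hyphae**: small clump iff sample length in
   (10, 150) µm, SWS total in (1.8·10⁴, 9·10⁴) and FWS length > 18 µm;
   otherwise hyphae iff sample length in (10, 150) µm, SWS total < 4·10⁴
   and FWS length < 190 µm.

Design choices worth stating explicitly:

* *Sample-length channel.* The size gates read the SWS sample length (the
  published scatter plots pair "sample length" with SWS total, and SWS is
  never saturated); this is configurable to FWS.
* *Overlap resolution.* The hyphae and small-clump SWS intervals overlap in
  (1.8·10⁴, 4·10⁴); the small-clump gate takes precedence there. Small
  elements matching neither gate go to `fallback_small` —
  `"unclassified"` by default, because the published hyphae definition has
  explicit bounds; setting `fallback_small = "hyphae"` reproduces the
  alternative reading in which everything outside the small-clump gate is
  hyphae.
* *Rectangles vs polygons.* The original gates are polygons drawn on
  scatter plots and never published numerically; the rectangular envelopes
  above approximate them, and explicit polygons can be supplied in the
  configuration (`large_gate$polygon` on (sample length, SWS total);
  `small_clump$polygon` on (FWS length, SWS total); point-in-polygon via
  `mgcv::in.out`).
* *Redundancy.* Inside the pellet gate the SWS-total bound is implied:
  ratio > 8·10² with sample length > 120 µm forces SWS total > 9.6·10⁴.
  It is still checked, and still strict at the boundary.
* *Degenerate inputs.* A zero fill factor or zero sample length leaves a
  gating ratio undefined; such particles are `unclassified`, never silently
  dropped: class counts always partition the viable set.

`refine_gates()` reproduces the cluster-assisted workflow used to sharpen
gate boundaries: z-scored features, k-means (Hartigan–Wong with 10
restarts and an explicit seed — base R has no k-means++ initializer, and
restarts serve the same reproducibility purpose) or average-linkage
hierarchical clustering, restricted to 2–5 clusters. Scatter intensities
span orders of magnitude, so features are log10-transformed before scaling
by default; with that transform a 2-cluster average-linkage cut reproduces
the small/large split, while raw magnitudes (`transform = "identity"`)
make 3-means isolate pellets and large clumps — the two regimes reported
for this kind of data.

## Pellet descriptors

A pellet's dense core saturates FWS. Scanning the FWS pulse, the core
interval runs from the first to the last saturated sample (half-open, in
0-based sample units); the flanks on either side are the annular region:

$$\mathrm{RAD} = \frac{\text{annular diameter}}{\text{particle length}},
\qquad
\mathrm{compactness} = \frac{\text{saturated FWS in core}}{\text{core diameter}}.$$

Two conventions are deliberate. The *particle length* is the above-trigger
envelope of the FWS signal (not the padded record length), so RAD is
invariant to sub-trigger padding. And *interior unsaturated dips belong to
the core*: a degraded, vacuolized center reduces compactness but not RAD —
only after such a pellet physically breaks at its weak point do the dip
samples become flank material, which is why RAD jumps upward on breakage
while compactness flags the degradation beforehand. A saturation tolerance
(`sat_tol`, default 0) exists for re-scaled data; acquisition-clipped data
saturate exactly.

## Aggregation

Concentrations are `count / (pump_speed × duration) × dilution_factor`,
with the default regime 15 µl/s × 80 s = 1200 µl of 1:1000 diluted broth.
Replicates pool by volume-weighted mean with the between-replicate SD
reported; `replicate_error()` gives mean/SD/%CV per parameter.

SWS fractions divide each class's summed SWS total by the sum over *all
classified viable elements* — a biomass-volume-weighted class
distribution. Whether sub-threshold or unclassified particles belong in the
denominator is not decidable from the published definition; the default
excludes them (fractions over the four named classes sum to exactly 100)
and `include_unclassified = TRUE` switches the behavior.

Size distributions are relative frequencies of the SWS sample length
(configurable), with 20 equal bins up to the 99.5th percentile by default
and fixed edges available for cross-run comparability; the predefined
unions `hyphal_aggregates` (small + large clumps + pellets) and
`large_elements` (large clumps + pellets) mirror the standard reporting
groups.

## Microscopy-side metrics

On binary masks, `measure_element()` computes area (pixel count × µm²),
perimeter, convex area, `roughness = perimeter²/(4π·area)` and
`fullness = area/convex area`, plus the skeleton-loop criterion.

* *Perimeter.* Pixel-edge counting makes a disk's roughness 1.62, so a
  geometric estimator is required. The boundary is traced as an
  8-connected Moore contour and measured as the closed polygon through the
  boundary pixel centers after a circular moving-average smooth whose
  window grows with contour length (≈ 1/50th, capped at 21, minimum 5);
  staircase jags then measure as the edges they rasterize. Digitized disks
  land within 2 % of $2\pi r$ (roughness ≈ 0.99 at r = 50 px) and the
  estimate is stable under integer upscaling. The known bias: smoothing
  cuts sharp corners slightly, so a filled square's roughness converges
  ≈ 4 % below the exact block limit $4/\pi$. Components too small to smooth
  fall back to a corner-corrected chain-code estimator
  (Vossepoel–Smeulders weights).
* *Convex area.* The hull is taken over the *corners* of the foreground
  pixels (each pixel a unit square), not their centers: the corner hull
  always contains the pixel area, so fullness ≤ 1 holds exactly and a
  filled rectangle scores exactly 1. Center hulls would make convex shapes
  score above 1. Small convex shapes still lose a little fullness to
  rasterization (≈ 0.92 for a radius-10 disk, ≥ 0.95 from about radius 20).
* *Skeleton loops.* A connected region's topological skeleton contains a
  cycle exactly when the region encloses a hole, so the loop criterion is
  evaluated as hole detection (background components not connected to the
  border) — equivalent to skeletonizing and cheaper than a thinning pass.
* *Cores.* On binary input `has_core` is always `FALSE`; with a graylevel
  image the core is the largest dark region (below a configurable
  intensity threshold — binarization thresholds are a known source of
  variation in this assay) fully interior to the element.

The microscopy classification applies the published area rules: pellet iff
area > 7500 µm² with a core > 7000 µm²; else large clump iff
area > 3500 µm²; smaller elements in (100, 3500] µm² are small clumps when
the skeleton loops (and area > 1000 µm²) and hyphae when it does not.

## The simulator

`simulate_run()` is the package's test bed: it draws classes from a
mixture and generates per-class pulse shapes with exact, sample-unit
ground truth. Default study conditions:

* mixture 40 % hyphae, 30 % small clumps, 20 % large clumps, 7 % pellets,
  3 % background — dispersed classes dominating the counts and pellets
  rare, the situation in which per-class statistics are hardest;
* hyphae: 30–90 µm single-lobe pulses, SWS totals 3·10³–1.5·10⁴;
  small clumps: 40–88 µm, 2–4 lobes, totals 2.2·10⁴–7.2·10⁴;
  large clumps: 120–250 µm irregular multi-lobe pulses with FWS peaking at
  30–85 % of saturation (no core); pellets: 150–280 µm ramp–plateau–ramp
  FWS with the plateau generated 1.5–2.5× above saturation and clipped,
  annular fraction 0.15–0.5, and with probability 0.3 a degraded core
  (contiguous central dip, target compactness 0.55–0.95);
* multiplicative lognormal sample noise (σ = 0.05) applied *before*
  clipping, so plateaus sit exactly at the saturation level as at
  acquisition; additive baseline 0 so the above-trigger envelope equals the
  generated extent;
* FL_GREEN totals 200–5000 a.u. for viable classes, 1–20 for background —
  far to both sides of the threshold 30.

All geometry priors must sit inside their gates by a relative margin
(default 10 %); `sim_params()` validates this and rejects incompatible
priors at construction. Because lengths, flanks and dips are drawn in
integer sample units, the analyzer recovers RAD and compactness exactly to
within one sample width, and label recovery on margined mixtures is ~100 %.

What the simulator does *not* emulate: correlated optics (Mie scattering),
instrument drift, coincident particles, size-dependent detection loss, and
the tails of real morphology distributions that straddle gate boundaries.
Passing tests therefore certify the pipeline's correctness — formulas,
conventions, determinism — not classification accuracy on real broth,
where boundary-straddling particles make label recovery intrinsically
lower.

`simulate_pellet_mask()` provides the image-side fixture: a rasterized
disk with radial one-pixel hairs; hairless masks are convex
(fullness ≥ 0.95), hairy ones drive roughness ≫ 1.

## Problem sizes and determinism

The shipped tests and the acceptance script use 10⁴ particles for label
recovery, 1.2–2·10³ per run elsewhere, 8-timepoint time courses at 1200
particles per timepoint, and masks up to ~200 px — sizes at which every
check runs in seconds while estimates are far from their decision
thresholds. All stochastic steps take explicit integer seeds; fixed-seed
runs are bit-identical, and list-mode files round-trip losslessly (doubles
written at 17 significant digits in the CSV dialect, natively in Parquet).

## Known limitations

* The exact published gate polygons are not numerically available; the
  rectangular defaults approximate them, and real-instrument use should
  load calibrated polygons from the configuration.
* The biological headline numbers of any specific cultivation (absolute
  concentrations, SWS-fraction time courses, measurement-error tables)
  depend on instrument data that is not distributable; the package
  reproduces the *framework* — formulas, gates, error propagation — and
  demonstrates it on simulated conditions.
* FWS saturation makes FWS totals useless for biomass weighting (pellet
  signal is clipped); SWS fractions are the supported weighting, matching
  the method's own choice.
* Orange/red fluorescence channels are stored and passed through but not
  analyzed.
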