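---
title: "Models and methods behind rtplanscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rtplanscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rtplanscore` implements the computational back-end of a tutoring system for
lung/mediastinum IMRT treatment planning: a DVH/metric engine, a 164-point
plan scoring rubric, a knowledge-based achievable-DVH prediction model, a
beam-efficiency-index beam selector, and a synthetic thorax phantom with a
simplified plan-dose synthesizer so that everything is testable without
clinical data.  This vignette explains the models, the assumptions they
make, the tunable parameters, and the design choices taken where the
problem was genuinely open.

## Containers and geometry

All fields live on an axis-aligned voxel grid in DICOM patient (LPS)
coordinates.  The grid origin is the *center* of the first voxel, indices
are 1-based in R, and voxel extents are half-open.  Structure volumes are
reported as voxel count times voxel volume.  Dose is always in Gy; DICOM
RTDOSE objects declaring any other dose unit are rejected at the door,
because every scoring threshold downstream is in Gy.

The native `.rtcase` container is a single file with a 4-byte header
length, a JSON header (format tag, version, geometry, prescription,
structure names) and the raw little-endian arrays: `uint8` per mask voxel
and `float64` for the dose.  Doses are stored at full double precision so
that a save/load cycle is bit-exact; this is what the I/O tests assert.
DICOM-RT support (RTDOSE, RTSTRUCT, explicit VR little endian) is an
adapter layer at the boundary -- all internal computation and all tests run
on the native format, so no clinical download is ever required.

## The DVH engine

DVHs are exact full-voxel cumulative histograms: the curve value at a bin
edge is the percent of structure voxels whose dose is at least that edge.
There is no partial-volume weighting; instead, contour rasterization
supersamples each voxel in-plane (4x4 subcenters by default, even-odd rule,
a voxel counts when at least half its subcenters are inside) so that
boundary effects are compensated where they arise.  This choice makes the
brute-force voxel-list oracle *exact*, which the test suite exploits:
min/mean/max and V(d) at bin-edge-aligned doses must agree with the sorted
voxel list identically, and D(v) to within one bin width (0.05 Gy by
default).  Doses within a relative `1e-9` of a bin edge are counted as on
the edge, so queries such as V20 Gy on integer-valued fields are exact
despite binary floating point.

Metric conventions:

* **Dx%** is the dose received by at least x% of the structure volume
  (largest `d` with cumulative volume >= x), linearly interpolated between
  bin edges.  D98% is therefore a near-minimum dose.
* **Minimum dose** is the plain voxelwise minimum.  No 0.03-cc smoothing is
  applied; the clinical convention for near-minimum reporting varies, and
  the voxel minimum is the simplest verifiable choice.
* **CI 50%** is the isodose-spill ratio: volume (within the body) receiving
  at least half the prescription, divided by the PTV volume.  Lower is
  better; values near 1 indicate a tight 50% isodose.
* **CN 95%** is the Paddick conformation number at the 95% prescription
  isodose: `overlap^2 / (TV x PIV)`, in [0, 1].
* Both isodose levels are *prescription*-relative, not max-dose-relative,
  and both fractions are parameters rather than constants.
* **Max-dose location** reports whether the hottest body voxel lies inside
  the PTV; ties are broken by the lowest linear voxel index for
  determinism.

## The scoring rubric

The default rubric has 18 metrics totalling exactly 164 points: target
metrics (PTV D98% 21, PTV min 10, GTV min 10, CN95 12, CI50 12, max-dose
location 10 -- 75 points), lung (max 5, mean 5, V20 10, V5 15 -- 35),
heart (max 5, mean 7, V30 5, V40 5 -- 22), esophagus (max 7, mean 5 -- 12)
and spinal cord (cord max 10, cord+3 mm max 10 -- 20).

The published allocation fixes only the maxima; the award function is this
package's design: points ramp *linearly* from the zero-credit threshold to
the full-credit threshold and are clamped outside, the simplest monotone
award.  The thresholds are package defaults informed by RTOG-style lung
constraints (e.g. cord max full credit at 45 Gy, none at 50.5 Gy; lung V20
full at 20%, none at 37%) and live in an editable YAML
(`inst/extdata/rubric_default.yaml`), not in code.  Because the original
system's thresholds are unpublished, absolute raw scores of specific
clinical plans are *not* reproducible from dose data, and nothing in the
package pretends otherwise; what is reproducible -- and tested -- is the
arithmetic around scores: the percentage normalization `100 x raw / 164`,
plan-to-plan differences, and cohort means, validated against the bundled
five-trainee study score tables (`benchmark_score_table()`,
`training_score_table()`).

A missing GTV is skipped with a warning and zero points by default
(configurable to a hard failure), since not every case delineates a GTV.

## Achievable-DVH prediction

The knowledge-based model predicts, per organ at risk (cord, cord+3 mm,
lungs, heart, esophagus), the prescription-normalized cumulative DVH that
should be achievable given the case anatomy.  The anatomical features are:

* the first *k* principal-component scores of the **distance-to-target
  histogram** (DTH): the cumulative distribution of the signed Euclidean
  distance from OAR voxel centers to the PTV surface (negative inside),
  computed with an exact anisotropic distance transform on a fixed bin grid
  (-50 to 300 mm, 2 mm steps) so DTHs are comparable across cases;
* OAR volume, PTV volume, OAR-PTV overlap volume;
* the out-of-field OAR fraction, operationalized as the fraction of OAR
  volume outside the PTV's superior-inferior extent plus a 20 mm margin --
  a proxy for what coplanar fields can avoid entirely.

Training performs PCA on the DTHs and on the DVHs (3 components each by
default; DVHs on a fixed relative-dose grid 0--1.2 in steps of 0.01 so
cases with 40--62 Gy prescriptions share one basis), standardizes the
features, and fits ordinary least squares from features to DVH PC scores.
OLS was chosen over any stepwise or regularized scheme because it is
deterministic, order-invariant and exactly recoverable in tests.
Prediction reconstructs mean-plus-components, clips to [0, 100], projects
onto the nearest monotone non-increasing curve by pool-adjacent-violators,
and anchors the curve at 100% at zero dose.  PC signs are canonicalized
(largest loading positive) so refits are comparable.

The published ancestor of this model is re-interpreted here in simplified,
configurable form; no claim is made of reproducing its exact features,
selection procedure or clinical accuracy.

**Validation design.**  Because no clinical cohort ships with the package,
model correctness is established on a constructed cohort
(`simulate_kbp_cohort()`) in which each OAR's target DVH is an exact affine
function of two model features (measured PTV volume and out-of-field
fraction): a convex combination of three fixed monotone anchor curves,
painted into the OAR voxels by inverse-CDF assignment.  Painted OAR masks
are made pairwise disjoint (and PTV-free) so every voxel belongs to exactly
one target curve; cord+3 mm is therefore not painted (it contains the
cord), and the validation models four OARs.  On this cohort the
feature-to-DVH-PC map is exactly linear, so the fitted model must recover
held-out DVHs to within painting resolution -- the acceptance suite
requires a maximum pointwise error below 1 volume-% with 60 training and 15
held-out cases, and checks graceful degradation (bounded RMSE, improving
with n) when 2 volume-% bin-wise noise is injected.  Passing these tests
shows the estimator is correct and stable; it does not show that real
anatomy satisfies a linear model, and accuracy claims on clinical data are
out of scope.

## Beam selection

Candidate coplanar gantry angles (every 5 degrees, IEC convention, source
at 1000 mm SAD, isocenter at the PTV centroid) are ranked by an efficiency
index.  For each angle, divergent rays are cast from the source to every
PTV voxel and marched through a two-density body (unit soft tissue, 0.25
lung) at 1 mm steps until they exit:

* benefit: `sum over PTV voxels of exp(-mu x WED)` with `mu = 0.005/mm` --
  the attenuated fluence actually reaching the target;
* penalty per OAR: the attenuation-weighted path length of those rays
  through the OAR, combined with configurable weights (defaults: cord 1.0,
  heart 0.5, esophagus 0.4, lungs 0.3);
* index = benefit / (1e-6 + weighted penalty).

The published index this emulates has learned weights that are not
available; the weights here are explicit configuration.  The index needs
only *relative* geometry, not dosimetric accuracy, hence the single
effective attenuation coefficient and the absence of scatter.

Bouquet selection is greedy with forced separation: repeatedly take the
highest-index angle at least 20 degrees (circular, configurable) from every
already-selected angle; ties go to the smaller angle.  Clinical mode
restricts bouquets to 7--11 beams.  Greedy selection with forced separation
is not globally optimal in general -- one can construct profiles where two
mid-valued angles beat the greedy second pick -- but on the smooth profiles
produced by real geometry it matches the brute-force best separated triple,
which the test suite verifies by enumeration on a 36-angle grid.

A note on symmetry testing: a voxelized cylinder is not rotationally
symmetric at arbitrary angles, so the index over the full 5-degree grid
varies at the discretization level (about 1%, asserted < 2% in tests).
Exact symmetry assertions (relative 1e-6) are made where the grid itself
supports them: 90-degree rotations, and left-right mirror pairs
`index(theta) = index(360 - theta)`.

## Synthetic phantoms and dose synthesis

The thorax phantom is deliberately schematic: an elliptic-cylinder body,
two lung ellipsoids, a heart ellipsoid, esophagus and cord tubes, a
spherical or ellipsoidal PTV solved analytically for a requested volume,
GTV = PTV eroded 5 mm, cord+3 mm = cord dilated 3 mm (both via the exact
distance transform).  The goal is the *statistical structure* of
lung/mediastinum cases -- volumes, distances, overlaps spanning an
easy-to-hard spectrum -- not anatomy.  Ellipsoid voxelization uses 3x3x3
subcenter supersampling (include at >= half), which keeps voxelized volumes
well within 2% of the analytic value at the default 2.5 mm grid; the
six bundled reference presets mirror the training-program spectrum
(benchmark 762.8 cc / 62 Gy; easy pair 113.8 cc / 40 Gy; intermediate
453.0 cc / 60 Gy; hard pair 845.7 cc / 60 Gy, pair members sharing the
pair-average volume and differing in location/shape).

Dose synthesis replaces the treatment planning system's fluence
optimization, which is external to this package: per beam, a divergent
field collimated to the PTV beam's-eye view plus 5 mm, exponential
attenuation along the water-equivalent depth, equal beam weights, a 3 mm
Gaussian penumbra, zero dose outside the body, and a final rescale so PTV
D95% equals the prescription.  Aperture cells are anchored at the beam axis
so mirrored geometries produce exactly mirrored doses (a property the tests
assert).  The synthesizer is geometrically faithful and deterministic; it
is not a dose calculation, and scores computed on synthesized plans
characterize the pipeline, not clinical plan quality.

Cohort generation (`generate_cohort()`) samples PTV volumes log-normally
around the reference volumes per difficulty (sdlog 0.25 / 0.15 / 0.10 for
easy / intermediate / hard), prescriptions per difficulty (40 / 60 / 60
Gy), and jitters the PTV centroid within the feasible envelope.  All
randomness flows from the single integer seed in the cohort spec; the seed
is recorded in each case's metadata, and the whole pipeline is bit-for-bit
reproducible, which the end-to-end determinism test asserts.

## Numerical choices and degenerate inputs

* Distance transforms use the exact Felzenszwalb--Huttenlocher algorithm
  with anisotropic spacing (written in C++; a large finite sentinel avoids
  `Inf - Inf` in the parabola intersections) and are verified against a
  brute-force pairwise oracle.
* Ray marching steps at 1 mm with nearest-voxel lookups; the dose
  synthesizer's closed-form attenuation test tightens the step to 0.25 mm
  and allows 1% for discretization.
* Empty masks, missing required structures, empty apertures, infeasible
  phantom geometry, version-mismatched files and non-GY dose units all
  fail fast with messages naming the offender.
* Rank-deficient feature matrices in the DVH model (e.g. a constant
  feature) have their aliased coefficients set to zero rather than NA.
* `isoreg` provides the pool-adjacent-violators projection; monotonicity
  tolerances in tests are `1e-12`.

## Problem sizes

Default test and validation sizes were chosen desk-scale: phantoms at
2.5 mm (about 1.2M voxels) for volume-accuracy checks, 4--5 mm grids for
pipeline and model tests, 75-case constructed cohorts (60 train / 15 test)
for model validation, and 36--72 angle grids for beam selection.  The full
suite runs in a few minutes on one CPU.

## Known limitations

* Phantom difficulty is encoded through volume, prescription and location
  only; shape complexity and OAR abutment are not modelled.
* The dose synthesizer has no scatter, no heterogeneity correction beyond
  the two-density model, and no inverse optimization; beam weights are
  equal.
* The scoring thresholds are defaults, not the (unpublished) clinical
  ones; absolute scores are comparable only within this package.
* The DVH model is a simplified re-interpretation; PTV DVH prediction and
  non-coplanar beams are out of scope.
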