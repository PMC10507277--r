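---
title: "Quantifying the architecture of scale-built shells from labeled volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the architecture of scale-built shells from labeled volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Testate amoebae such as *Paulinella micropora* build an egg-shaped
extracellular shell from ~50 individually secreted silica scales.  Volume
electron microscopy (FIB-SEM) of such cells yields segmented label volumes:
3D integer images in which each scale, and optionally the cytoplasm of the
shell-building pseudopodium, carries its own label.  `shellmorph` turns such
label volumes into quantitative statements about the shell: per-scale
morphometrics, the helical column arrangement (count, twist, handedness),
volume-profile outliers, and the two-fold symmetry between a mother shell
and the daughter shell under construction.  Because raw image stacks of this
kind are rarely deposited, the package also contains a fully parametric
phantom generator whose ground truth drives the validation suite.

## Conventions

All functions share three conventions, fixed once:

* voxel arrays are indexed `(z, y, x)`, and the center of voxel
  `(k, j, i)` lies at world coordinates
  `((i - 0.5) sx, (j - 0.5) sy, (k - 0.5) sz)` micrometres;
* after alignment the shell's long axis is +Z with the aperture (the shell
  opening) at high Z and the posterior pole at low Z;
* angles in the plane perpendicular to the long axis are measured
  counter-clockwise as seen from +Z, so a *left-handed* helical column —
  one whose angular position decreases from posterior to aperture — has a
  negative twist.

## Morphometrics by exact face counting

Volume is voxel count times voxel volume; the centroid is the unweighted
mean of member voxel centers.  Surface area counts voxel faces whose
6-neighbor is a different label, background, or outside the volume; the
contact area between a scale and the cytoplasm counts faces shared by the
two labels.  Face counting overestimates the area of smooth surfaces (up to
a factor 1.5 for oblique planes) but is exact on the voxel grid,
deterministic, and the bias cancels in the contact/surface *ratios* that the
contact classification uses.  Contact is strict 6-adjacency with no distance
band: the parameter-free choice.  All morphometrics require isotropic
voxels; anisotropic acquisitions (e.g. 20 nm sections at 7.3 nm pixels) are
first resampled with `resample_isotropic()`, which interpolates each label's
indicator trilinearly and rethresholds at 0.5, resolving conflicts by the
larger interpolated value (ties to the smaller label id).

A scale is classified `none` / `partial` / `full` by its contact/surface
ratio with the ratio clamped to 1 and a full-coverage threshold of 0.99:
measured contact can marginally exceed the measured surface when the two
come from independent segmentations, and the packaged 25-scale reference
table indeed contains such a row.

## Long-axis alignment

`align_long_axis()` mirrors the classical two-projection procedure: project
the foreground onto the XZ plane, fit an ellipse by second-order image
moments (`0.5 atan2(2 m11, m20 - m02)`), rotate about Y so the fitted major
axis is parallel to Z, repeat with the YZ projection and a rotation about X,
and iterate to a tolerance of 0.5 degrees (at most 10 passes; convergence is
fast for prolate bodies).  Labels are re-voxelized by nearest neighbor under
the *accumulated* rotation, always from the original volume, so label
identity never erodes through repeated resampling.  Moment-based
orientation rather than a conic least-squares fit is the parameter-free
reading of "elliptically fitted"; the two agree for solid elliptical masks.
An independent oracle, `principal_axis()` (dominant eigenvector of the
voxel second-moment tensor), is used by the test suite to verify the
procedure to within 2 degrees on prolate phantoms.

After convergence, the aperture is normalized to high Z by the sign of the
third central moment of foreground mass along Z: an egg carries more mass
near its wide (aperture) end, so a correctly oriented shell has negative Z
skewness.  The heuristic can be forced or suppressed (`flip_z`), since a
strongly truncated or damaged shell could defeat it.

## Helical architecture from centroids

Centroids are converted to cylindrical coordinates about a Z axis through
their mean.  The plain radius-weighted angular spectrum
`S(m) = |sum r exp(i m theta)| / sum r` detects the column count C of an
*untwisted* arrangement perfectly: all harmonics that are not multiples of C
vanish identically.  Under twist, however, the column harmonic decays: for a
full single revolution across ~10 rows the phase `m * omega * z` sweeps
several turns and the power of `m = C` migrates to `m = 2C` (on the default
phantom, `S(10) ≈ 0.83` versus `S(5) ≈ 0.06`).  A five-petal pattern is
nevertheless plainly visible in the XY plot — it lives in the joint
`(r, theta)` distribution, not in the marginal angular density.  The
package therefore counts petals on the *rate-compensated* spectrum

`S(m) = max_beta | sum r exp(i (m theta - beta z)) | / sum r`,

which allows each harmonic a linear angular drift along Z.  For an exact
C-column helix every multiple of C reaches 1 under compensation, and the
smaller-harmonic tie-break selects C itself; any angular jitter damps the
higher multiples faster, making the choice strict.  For untwisted data the
compensated and plain spectra coincide at the maximizing rate zero.

Twist is estimated at the column harmonic: multiplying all angles by C
collapses the C columns onto a single phase ramp in z, whose rate is found
by a dense scan plus local refinement; columns are then read off the
detrended angles, each column's angles are unwrapped onto the model, and a
per-column least-squares slope is fitted.  The reported twist is the mean
slope times the centroid Z range, in revolutions, with a 95% half-width
across columns; handedness is `left`/`right` for twist beyond ±0.05
revolutions and `none` within.

One identifiability caveat is worth recording: if all rows sit at exactly
equally spaced heights, the centroid set cannot distinguish a twist of
`Phi` from `Phi + (K - 1)/C` revolutions (the helix aliases on the row
comb).  Real shells do not have perfectly equal rows, and neither do the
phantoms (below); the estimator resolves the ambiguity through exactly this
row-height variation.

## Volume profile and outliers

Scale volumes along an egg-shaped shell are small near the aperture and the
posterior pole and largest near the equator.  `volume_profile_outliers()`
fits `V(z) = a exp(-(z - mu)^2 / (2 sigma^2))` by nonlinear least squares
(Levenberg–Marquardt, initialized from the maximum and the volume-weighted
mean and SD of z; a singular fit falls back to a quadratic and is flagged),
and reports scales whose absolute residual exceeds `k = 3` robust standard
deviations (1.4826 × MAD of the residuals).  Robust scaling prevents the
outliers from masking themselves; a zero or numerically negligible MAD
degrades the threshold to a pure rounding-noise floor so that constant
profiles yield no outliers.

## The phantom generator

`shell_spec()` describes an ovoid of mid-surface radius
`r(u) = R sqrt(1 - u^2) (1 + a u)`, `u = z / L` — the simplest
two-parameter egg with a single equatorial maximum — carrying C helical
columns of K curved rectangular plates each (plus optional extra aperture
scales), with twist applied linearly in z and calibrated over the span of
row centers so that the twist *estimator* recovers the nominal value.
`paulinella_shell_spec()` is the study-scale preset: 5 columns × 10 scales
+ 2 aperture scales = 52 labels, twist −1 revolution (left-handed),
asymmetry 0.35, L = 6.5 µm and R = 4 µm (a ~13 µm cell), scale thickness
0.35 µm, voxelized at 0.08 µm on a 192³ grid so the ovoid spans ~85% of the
grid.  Generation takes a few seconds and is deterministic given the seed.

Several design choices in the generator are consequences of making the
ground truth *recoverable*, and are worth stating explicitly:

* **Row heights vary** (±15%, drawn once from the seed).  Perfectly equal
  rows are unrealistic and create the twist-aliasing comb described above.
* **Per-scale volumes track a Gaussian in z by construction**: the angular
  width of each row is sized so that `arc × thickness × height` follows a
  bell profile (center 0.15 L, SD 0.7 L).  A constant angular span would
  give a compact-support profile whose tails systematically misfit a
  Gaussian and masquerade as outliers.
* **Placement jitter moves scales without resizing them**: the angular span
  compensates radial displacement so arc length is preserved, and row
  bands are snapped to the voxel grid so that a row's rendered height never
  jumps by a whole voxel layer from scale to scale.
* **Size variation is bounded**: per-scale thickness multipliers are drawn
  from a symmetric distribution with support ±6%, so an uninflated phantom
  stays strictly inside the k = 3 robust outlier threshold while a planted
  ×1.8 volume inflation stands far outside it.  (Inflation multiplies the
  thickness: for a thin shell, volume is proportional to thickness, and
  radial thickening cannot collide with neighboring scales.)  This design
  region was chosen by simulation before the validation suite was frozen.

Cytoplasm is added as a blob of fused balls inside the aperture end of the
cavity (touching no scale) plus per-scale coverage: `full` converts every
background voxel 6-adjacent to the scale, `partial` converts a contiguous
angular sector of them sized to a target contact/surface fraction, `none`
leaves the scale untouched.  Realized classes are re-measured and written
back into the ground truth.

Mother/daughter pairs are generated by rotating the *continuum* scale model
180° about a chosen axis before voxelization, so the two-fold symmetry is
exact in the continuum: the midpoint of each homologous centroid pair is the
projection of the mother centroid onto the axis, hence exactly collinear.
Voxelization adds at most about a voxel of scatter.

What the phantom deliberately does not emulate: imbricate (overlapping)
stacking of scales along a column (rows are disjoint bands with gaps), scale
porosity and surface ornamentation, and realistic pseudopodium shapes.
Passing the validation suite therefore demonstrates the correctness of the
measurement and recovery machinery on shells with the stated architecture,
not segmentation robustness on raw micrographs.

## Symmetry analysis

`symmetry_analysis()` is deliberately literal: midpoints of homologous
centroid pairs (matched strictly by the integer suffix of `M*`/`D*` names),
a total-least-squares line through the midpoints, the RMS perpendicular
distance of midpoints to that line (collinearity), and the RMS distance
between the 180°-rotated daughter centroids and their mother partners
(overlap).  The rotation is about the fitted *affine* line.  No joint
optimization over axis and rotation is attempted — the midpoint construction
is the procedure being reproduced.  `max_pair_index` restricts the analysis
to the first n pairs (the published analysis used pairs 1–14, the scales
already placed at the time of imaging).

## Problem sizes and determinism

The test suite validates morphometrics against brute-force voxel scans on
≤16³ volumes, runs recovery tests on 64³–96³ phantoms, and exercises the
study-scale 192³ preset for the headline statistics (52 labels, 5 petals,
twist −1.0 ± 0.05 left-handed, outlier recovery of planted ×1.8
inflations).  Every randomized step takes an explicit integer seed; pipeline
products (`morphometry.csv`, `alignment.json`, `architecture.json`,
`contact_summary.json`, `symmetry.json`, `report.txt`) are byte-identical
across reruns with the same configuration and echo the resolved
configuration.

## Known limitations

* Face-count areas overestimate smooth-surface areas; only ratios and
  within-method comparisons should be interpreted, not absolute areas.
* Nearest-neighbor re-voxelization under rotation changes individual label
  volumes by up to a few percent for thin objects; per-label volume is
  conserved to <5% for objects ≥5 voxels across.
* Petal counting assumes an approximately linear angular drift; strongly
  non-linear twist would require a generalized rate model.
* The aperture-orientation heuristic (Z-skewness) assumes an egg-like mass
  distribution; use `flip_z` to override for unusual shells.
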