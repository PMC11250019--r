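---
title: "Methods: semiautomatic field-in-field planning for whole-brain irradiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semiautomatic field-in-field planning for whole-brain irradiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `fifwbi`. The package automates field-in-field (FIF)
forward planning for whole-brain irradiation (WBI) with two opposed lateral
photon fields: it finds hotspot regions in the 3D dose of an original plan,
blocks their beam's-eye-view (BEV) projections with automatically shaped
MLC sub-beams, and reassigns beam weights in closed form.

## Coordinate frames and beam geometry

All volumetric data live in the DICOM patient coordinate system (DCS): LPS
axes, millimetres, head-first supine, voxel-centre origin, isotropic
spacing. The projection chain is

1. **DCS → ICS**: translation by the isocenter.
2. **ICS → BCS**: a rigid rotation into the collimator-fixed beam frame.
   At zero gantry and collimator angles the triad is X′ = patient right,
   Y′ = anterior (toward the source), Z′ = superior; this choice makes the
   frame right-handed with the beam axis along +Y′. The gantry rotates the
   frame about the fixed patient longitudinal axis and the collimator about
   the frame's own Y′, both in the IEC 61217 sense (gantry 90° puts the
   source at the patient's left).
3. **BCS → BEV**: central projection from the source at (0, SAD, 0) onto
   the isocenter plane Y′ = 0, `X_BEV = X′·SAD/(SAD − Y′)` and likewise for
   `Z_BEV`. Points at or beyond the source plane raise a degenerate-
   projection error.

The defining contract — source at (0, SAD, 0) in the BCS for every angle
pair, plus the zero-angle axis identification — fixes the rotation
uniquely; the test suite verifies the implementation against an independent
Rodrigues-formula composition on 10^4 random points to 10^-9 mm.

## The simplified dose engine

The engine replaces a clinical convolution/superposition algorithm with a
primary-only divergent pencil model. Per voxel `v`:

$$ d(v) = w \cdot A(v) \cdot \left(\frac{SAD}{r(v)}\right)^2
          \cdot e^{-\mu_{\mathrm{eff}}\,\ell(v)} $$

with `r(v)` the source-voxel distance, `ℓ(v)` the radiological path from
the surface to the voxel centre (Siddon-style traversal of the density
grid, one ray per voxel centre), and `A(v)` equal to 1 when the voxel
centre's BEV projection is open in the aperture and to the MLC/jaw
transmission fraction `T_mlc` otherwise. Dose is zero outside the patient.

The model is chosen for two properties the FIF algorithm actually needs:

* **monotone thickness→dose response**, which reproduces the clinical
  phenomenology (hotspots where the head is laterally thin), and
* **exact linearity in beam weights** before normalization (verified to
  machine precision), which is what makes the closed-form weight assignment
  exact: with `T_mlc = 0`, unblocked doses are invariant under Step-1
  re-weighting and blocked doses scale by `1 − f`.

Plan doses are renormalized to 100% of prescription at the isocenter voxel
after every computation, so all thresholds stay in percent of prescription.
With a non-zero `T_mlc` the sub-beam leaks `T_mlc · f · d` into blocked
regions, so the post-FIF maximum sits a few hundredths of a percent above
`D_th`; this is physical (real MLCs transmit) and far below the half-percent
discretization allowance used in the tests.

### The effective attenuation default

`mu_eff` is deliberately *not* the narrow-beam attenuation coefficient of a
10 MV beam (≈ 0.0035/mm): in broad opposed fields, scatter largely
compensates the missing-tissue excess near thin regions, so the net
sensitivity of dose to lateral thickness is several times shallower than
primary attenuation. Since the generator defines the study conditions, the
default `mu_eff = 0.0014`/mm (1.4%/cm) was fixed once so that the default
phantom's original plan shows the clinically reported hotspot magnitude —
a maximum near 108–110% of prescription with a percent-level `V105%` in the
PTV, as observed for plain opposed-lateral WBI plans. With the textbook
primary value the ellipsoid's poles would reach ≈ 128%, a regime no
clinical opposed-lateral head plan occupies and in which a single uniform
reduction by `f` would be meaningless. The two-step escalation is exercised
with a thicker effective attenuation (0.0018/mm), under which Step 1 costs
more than 1 pp of `D95%` and the four-sub-beam plan recovers most of it.

Other engine parameters: `T_mlc = 0.015` (typical combined MLC/jaw
transmission), inverse-square on by default, SAD 1000 mm.

## The synthetic phantom

`make_head_phantom()` builds an axis-aligned water ellipsoid (default
semi-axes 70 × 95 × 80 mm lateral/AP/SI) in air on a 2.5 mm grid — the
planning-grid resolution of clinical WBI practice — with the PTV obtained
by 5 mm morphological erosion of BODY (spherical structuring element). The
erosion stands in for the brain-plus-margin contour: there is no anatomy in
a synthetic ellipsoid, and excluding the surface layer keeps build-up-free
rim voxels out of the coverage statistics. An optional seeded smooth
surface perturbation (low-order sinusoids on the unit sphere, amplitude in
mm) diversifies test geometries; it defaults to 0 so that the standard
conditions are exactly reproducible.

What the phantom emulates: the lateral chord of an ellipsoid shrinks toward
the anterior/posterior poles, so opposed lateral beams overdose exactly
where real heads do (frontal/occipital). What it does not emulate:
heterogeneous tissue, skull and air cavities, build-up, penumbra, scatter
kernels. Passing tests therefore demonstrate the *algorithmic* behaviour
(projection, MLC fitting, weight algebra, scheme selection) under a
faithful geometry, not dosimetric accuracy on patients.

`make_original_plan()` places the isocenter at the PTV centroid (snapped to
a voxel centre so normalization is exact), uses gantry 90°/270° with
collimator 0°, equal unit weights, and rectangular MLC/jaw openings
enclosing the projected PTV with a 7 mm margin (a typical clinical block
margin; configurable).

## Hotspot projection and MLC fitting

* A hotspot is `dose > D_th`, strictly: "above the threshold" is read as
  exclusive, so a plan driven exactly to `D_th` has no hotspots.
* Projection is conservative: all 8 corners of each hot voxel are
  projected and the filled convex hull rasterized (union over voxels) on a
  1 mm raster — finer than both leaf widths — covering the jaws plus
  10 mm. Corner projection guarantees the fitted block shadows the full 3D
  region; no margin is added around the projection.
* The centre-line rule is applied independently per leaf row, using that
  row's hotspot extent. The technique is usually described per hotspot
  region; per-row application is the natural MLC-level reading (leaves move
  independently) and covers regions of any shape. Two disjoint runs on
  opposite sides of the centre line are each covered by their own leaf;
  when a run crosses the line, the leaf on the side with the larger outer
  distance travels across. A tie goes to the left (X1) leaf by default
  (configurable). The "vertical centre line" is X_BEV = 0 of the
  collimator frame, i.e. the beam axis, not the geometric centre of an
  asymmetric field.
* Leaf tips are quantized to 0.1 mm (typical machine resolution), always
  rounding in the covering direction; jaws are never moved, and leaves
  never retract behind the duplicated main-beam field.

## Weight assignment and the two-step scheme

Step 1 uses `f = (D_max − D_th)/D_max`, `w_main,FIF = w_main·D_th/D_max`,
`w_sub,FIF = w_main − w_main,FIF`, applied independently per main beam.
The complementary form makes weight conservation exact in floating point
(`w_main,FIF + w_sub,FIF == w_main` bitwise).

Step 2 runs when the Step-1 `D95%` reduction strictly exceeds the criterion
(default 1.0 pp, deliberately easy to change). Stage one repeats Step 1
with the intermediate threshold `D_ith = (D_max + D_th)/2` against the
original dose; stage two blocks what remains above `D_th` in the resulting
*normalized* two-sub-beam dose, whose maximum `w_ithmax` takes the role of
`D_max`: `w_main,FIF2nd = w_main,FIF · D_th / w_ithmax`, with the second
sub-beams taking the complement. Evaluating `w_ithmax` on the normalized
intermediate dose is a deliberate choice (the alternative, pre-
normalization evaluation, differs only at order `T_mlc · w_sub`); it keeps
every threshold in percent of prescription. If the intermediate plan
already has no dose above `D_th`, the second pair is skipped with a notice.
When `D_max ≤ D_th` the planner returns the original plan with scheme
`"none"` rather than erroring.

Clinically reported average weight splits for this technique serve as
consistency anchors: the Step-1 form gives 0.979/0.021 at
`D_max = 107.3`, and the Step-2 reconstruction reproduces a
0.973/0.013/0.014 four-sub-beam split at `D_max ≈ 107.8`,
`w_ithmax ≈ 106.5` (checked as a toleranced unit test, not asserted as
ground truth, since those inputs are not known exactly).

## DVH conventions

The DVH is voxel-exact (sorted samples, no binning): structures here are at
most ~10^6 voxels and exactness removes bin width as a hidden parameter.
`D_V` is the largest dose `d` such that at least the fraction `V` of the
structure receives ≥ `d` (lower-quantile convention on the voxel
distribution); `V_D` counts voxels with dose ≥ `D` (inclusive). The
homogeneity index is `(D2% − D98%)/D50%`, in percent. Clinical TPSs
interpolate DVHs in system-specific ways, so absolute index values can
differ slightly from any given TPS at the same dose grid.

## Problem sizes and determinism

The standard conditions use the full 2.5 mm grid (61 × 81 × 69 voxels,
≈ 140k inside BODY); a complete `autofif` run takes on the order of a
second, the full test suite tens of seconds. Unit tests that only need
structure, not resolution, use a 5 mm version of the same phantom. All
computations are deterministic: identical inputs give bit-identical dose
grids, and the only randomness anywhere (the optional phantom surface
noise, synthetic test fixtures) is seeded.

## Known limitations

* Primary-only dose model: no scatter, build-up, penumbra or heterogeneity
  corrections beyond radiological depth; no MU calculation. Aperture
  testing uses the voxel-centre ray only, so dose at aperture edges is
  aliased at the voxel scale.
* One ray per voxel and no sub-voxel anti-aliasing; the post-FIF maximum
  can exceed `D_th` by a discretization allowance (≤ 0.5 pp on the default
  grid, typically far less).
* No interdigitation or leaf-gap constraints, no tongue-and-groove or
  rounded-leaf-end modelling; leaf overtravel is unlimited by default.
* Couch rotation, non-isocentric setups and orientations other than
  head-first supine are out of scope.
* DICOM RT import/export is not provided; interchange is JSON + NRRD.
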