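---
title: "From voxel anatomy to a filled phantom: the ground-truth pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From voxel anatomy to a filled phantom: the ground-truth pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomforge)
```

Validating a molecular-radiotherapy (MRT) dosimetry system requires imaging
data whose underlying activity distribution is *known*. A practical way to
obtain such data is to 3D-print hollow organ shells derived from a reference
voxel anatomy, fill them with Lu-177 solution at concentrations prescribed
by a pharmacokinetic model, and image the assembly at clinical timepoints.
`phantomforge` implements the digital side of that workflow end to end:
geometry, kinetics, dispensing metrology, and verification reporting. This
vignette records the models, the tunable parameters, and the design
decisions behind each stage.

## Phantom geometry

A `voxel_phantom` is a 3-D integer label volume with voxel spacing in mm
and an organ table mapping each label to a compartment role (liver, spleen,
tumour, kidney cortex/medulla left and right, body). The world convention
is fixed: voxel `(i, j, k)` (0-based) has its center at
`((i + 0.5) sx, (j + 0.5) sy, (k + 0.5) sz)` mm. Raw little-endian label
volumes with a YAML sidecar are the on-disk format; masks and activity maps
go to NIfTI.

**Label cleanup.** Before a region can be meshed it must be one connected
piece. `clean_label_region()` enforces a single 6-connected component
(detached voxels are reassigned to a neighbouring compartment) and absorbs
enclosed cavities of other labels smaller than 27 voxels — one 3×3×3
pocket — into the region. The threshold is deliberately small: genuinely
nested compartments (the tumour inside the liver, the medulla inside the
cortex) are far larger and must survive cleanup. Manual voxel reassignment,
the obvious alternative, is not reproducible; the automatic morphological
rule is a stand-in, not a reconstruction of any particular manual edit.

**Surface extraction.** `extract_surface()` returns the 0.5 iso-surface of
the binary mask under nearest-neighbour interpolation: the exact boundary
of the voxel set, quads on the voxel-corner grid split into triangles.
This choice has three properties worth the staircase it initially carries:
the mesh is watertight whenever the region is 6-connected without
checkerboard edge contacts, its enclosed volume equals the voxel-count
volume *exactly*, and rasterizing it back (`voxelize_mesh()`, vertical
ray-crossing parity at voxel centers) reproduces the original mask — the
Dice ≥ 0.99 round-trip guarantee the tests enforce. The staircase is then
removed by smoothing, mirroring the established voxel-phantom-to-STL
workflow.

**Laplacian smoothing.** `laplacian_smooth()` moves each vertex toward the
uniform-weight centroid of its edge neighbours by a factor λ per iteration.
Defaults are 20 iterations with λ = 0.5: enough to flatten 1–2 mm voxel
steps while keeping the organ-scale volume change under 5% (the liver
loses about 1%; small high-curvature organs shrink more, which is why the
spherical tumour insert is generated analytically as an icosphere rather
than extracted from voxels). Uniform-weight Laplacian smoothing always
shrinks a closed convex-ish surface; both parameters are exposed.

**Shells and assembly.** `extrude_shell()` offsets every vertex outward
along its area-weighted vertex normal by the wall thickness — 2 mm for
organ shells, 1 mm for the medulla compartments, matching the physical
design. A true Minkowski offset is not attempted: after smoothing, the
curvature radii are large against the wall thickness, and the
normal-displacement approximation keeps topology and yields a mean wall
distance within a fraction of a percent of the nominal thickness (verified
by nearest-point distance from outer vertices to the inner surface). Face
fold-over (normal reversal) is detected and reported as an extrusion
error; note that an annular compartment such as the kidney cortex should
be extruded from the *whole-kidney* outer surface (merge the medulla label
first), since its internal cavity boundary is not a printed wall.
`resolve_overlap()` translates one part along a direction in 0.1 mm steps
until the minimum vertex-sampled surface separation reaches a 0.5 mm
clearance; `assemble_scene()` verifies pairwise non-overlap. Filling
ports, interlocking joins and caps are recorded as part metadata only;
cutting them into the mesh adds CSG fragility without changing any
quantity this package is meant to certify.

**STL.** Both dialects are supported, with the binary layout (80-byte
header, uint32 count, 50-byte little-endian records) written exactly.
Vertices are quantized to float32 before writing so that
write–read–write cycles are bit-identical after the first write. STL has
no unit field; coordinates are mm by package convention.

## Pharmacokinetic model

The kinetics are a linear compartmental system `dA/dt = K A` over six
compartments — central ("rest of body"), kidneys, liver, spleen, tumour,
excreted — with first-order transfer rates in 1/h and all activity in the
central compartment at `t = 0` (administered activity 7400 MBq by
default). Off-diagonal `K[j,i]` is the rate i→j; diagonals close the
balance so every column of `K` sums to zero and total biological activity
is conserved identically.

The published rate constants behind the original phantom study are not
public, so the package ships an *illustrative* default set: organ uptake
rates of 0.005–0.08 1/h, return rates of 0.01–0.03 1/h, and a 0.15 1/h
renal clearance from the central compartment. These produce the
qualitative shape expected of Lu-177 DOTATATE kinetics — organ
concentrations peaking within hours, effective washout half-lives of tens
of hours — and every value is config-overridable; no quantitative claim is
attached to them.

**Solver.** The system is integrated by classical fixed-step RK4 with
ΔT = 1 min over 100 days (both configurable). Because the system is linear
and autonomous, the four RK4 stages collapse algebraically into a single
per-step update matrix `Φ = I + hK + h²K²/2 + h³K³/6 + h⁴K⁴/24`, applied
once per step — identical arithmetic to stage-by-stage RK4, two orders of
magnitude faster in R, and exactly mass-conserving because the column sums
of `Φ` are exactly 1. The tests verify fourth-order convergence against
the closed-form exponential and conservation to 1e-9 relative at every
stored step.

**Decay handling.** The solved series is biological (decay-corrected); the
Lu-177 decay constant is attached and the physical series is derived by
multiplication with `exp(-λ t)`. This is equivalent to adding λ to every
diagonal of `K`, and makes `decay_correct()`/`decay_apply()` exact
inverses (`2^(±Δt/T½)`). The half-life default, 6.6443 d, is external
nuclear data, not a fitted quantity, and is configurable. Both decay
conventions are exported side by side, since plotted concentration curves
in the field are ambiguous on this point.

**Derived concentrations.** The kidney is one kinetic compartment split
across four anatomical regions under two constraints: medulla
concentration = cortex concentration / 3, and left/right cortices share
one concentration. With total cortex volume `Vc` and medulla volume `Vm`,
`c_cortex = A_kidneys / (Vc + Vm/3)`. Background concentration is the
central-compartment activity divided by the housing volume (8297 mL).
Between grid points concentrations are interpolated linearly; at a 1-min
step the interpolation error is negligible against curve curvature, and
grid-point queries return stored values exactly.

**Time-integrated activity.** The trapezoidal integral over the solved
grid plus an analytic mono-exponential tail; the tail rate is fitted by
log-linear least squares over the last 10% of the horizon, by which point
a linear system is mono-exponential to high accuracy. A non-decaying tail
raises a divergence error rather than returning a number.

## Filling metrology

The dispensing protocol is planned backwards from the scan: the activity
required at scan time (target concentration × compartment volume) is
decay-corrected to dispensing time; 110% of it is drawn from the
calibrated stock; the draw is pre-diluted to 105% of the compartment
volume and topped up, to within 0.01 mL, to the volume at which the
solution concentration equals the target — which is 110% of the
compartment volume when exactly 110% was drawn. Dispensing the compartment
volume from that solution reproduces the modelled concentration *by
construction*; the closed-loop identity (plan → exact simulated weighing →
achieved ≡ target to 1e-10 relative) is an acceptance-tested invariant.

Uncertainty bookkeeping is first-order quadrature throughout. Balance
readability `d` becomes a rectangular-distribution standard uncertainty
`d/√12` per reading, two independent readings per volume; solution density
defaults to 1.000 g/mL (0.04 M HCl is within 0.1% of that); the
radionuclide-calibrator chain contributes a configurable relative standard
uncertainty (default 3%, as no published figure accompanies the primary-
standard traceability). Values render in concise parenthesis notation —
uncertainty in units of the last displayed digit, one significant figure,
keeping a second digit only when the uncertainty leads with 1 and
truncation would be lossy (so `409(14)` but `100.08(1)`); rounding is
half-even, and parsing inverts formatting at displayed precision.

## Verification reporting

`deviation_report()` compares achieved against modelled concentrations per
(compartment, scan): percent deviation, its uncertainty, and a coverage-
factor agreement flag. The summary quotes the arithmetic mean of the
deviations with the *sample standard deviation* as its uncertainty — the
convention consistent with a quoted mean deviation whose uncertainty
exceeds the mean; the standard error is available by dividing by √n.
`underfill_range()` reports `100 − fill%` extrema rounded half-even to two
decimals, excluding overfilled scans from the range and listing them
separately, since an overfill is a different failure mode (cap seating)
than the systematic underfill of a slightly oversized housing.
`export_activity_map()` writes the labelled grid with per-compartment
concentrations — the digital ground truth of the filled phantom — on the
phantom's own voxel grid, with no resampling and deliberately no
SPECT-resolution blurring.

## The synthetic phantom

`generate_synthetic_phantom()` provides a self-contained stand-in for a
licensed reference voxel anatomy: an elliptical-cylinder body (internal
axes 258 × 198 mm, height 268 mm, matching the physical background
housing), an ellipsoidal liver containing a 15.9 mL spherical tumour, an
ellipsoidal spleen, and two kidneys as nested ellipsoids (inner medulla,
cortex shell between). Target volumes default to the design STL volumes
(liver 1306.7, spleen 124.9, tumour 15.9, cortices 90.9/75.7, medullas
42.9/35.7 mL); semi-axes are derived analytically from the targets with
fixed anatomy-like axis ratios, so voxel-count volumes converge to the
targets as spacing shrinks (within 0.6% at the 2 mm default). Placement is
fixed and anatomy-like — liver right-superior, spleen left-superior,
kidneys posterior-inferior — and fully deterministic; the seed is recorded
for provenance but no randomness is consumed. Generation asserts the
geometric contract (organs inside the body with margin, tumour inside the
liver, medullas nested, liver/right-kidney and spleen/left-kidney
disjoint) and fails with a feasibility error otherwise.

What the synthetic phantom does *not* emulate: real organ shapes and their
surface detail, inter-subject variability, printing artifacts (layer
ridges, wall-thickness tolerances), air bubbles, or the baseplate and
support hardware. Tests passing on it certify the pipeline's geometry and
bookkeeping — watertightness, volume fidelity, wall thickness, activity
conservation — not anatomical realism.

## Problem sizes and numerical choices

The default test and verification workload uses the 2 mm grid
(133 × 103 × 138 voxels), with a single 1 mm generation to demonstrate
volume convergence; the PK solve covers 144 000 one-minute steps; meshes
run to ~47 000 faces (liver). Tie-breaks and tolerances that matter:
6-connectivity everywhere components are counted; 27-voxel cavity
threshold; round-half-even wherever results are rounded for display;
0.5 mm assembly clearance in 0.1 mm steps; watertightness defined as every
directed half-edge matched exactly once; ray-parity queries nudged by a
sub-nanometre irrational offset so rays never pass through vertices.

## Limitations

Printed-part post-processing (ports, joins, sealing), SPECT/CT
acquisition and reconstruction, partial-volume correction and absorbed-
dose computation are all out of scope. The default transfer rates are
illustrative. The shell offset is a normal-displacement approximation, not
an exact offset surface; for walls much thicker than the local curvature
radius it would self-intersect (the package detects and refuses this).
Fill fractions of a *physical* phantom depend on bubbles and manufacturing
tolerances that no desk computation reproduces; the package's reference
fill-fraction dataset is a packaged transcription used to exercise the
reporting, not a prediction.
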