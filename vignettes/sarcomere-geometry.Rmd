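---
title: "Geometry of the cardiac thick filament: models, conventions, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of the cardiac thick filament}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcgeom)
```

## The measurement problem

Cryo-electron tomography of relaxed cardiac muscle resolves the thick
filament as a three-fold-symmetric lattice of myosin interacting-heads
motifs (IHMs) arranged in "crowns": levels of three double heads repeating
axially with a 430 Å (43 nm) pseudo-repeat that contains three structurally
distinct crown classes. Around this core run titin chains (the α
conformation spanning the filament, the β conformation ending at crown A1),
nine cMyBP-C stripes whose C-terminal domains anchor on crown-2 tails, and
flexible N-terminal links reaching the neighbouring thin filaments at 43-nm
intervals. `sarcgeom` implements the geometry that turns such models and
their particle-table bookkeeping into numbers: crown poses, coiled-coil
sinuosity, lattice censuses, axial periodicity, and link angles.

## Crown poses

Each IHM is reduced to a triangle of three landmark sites: the ATP-binding
site of the free head, the same site of the blocked head, and the head–tail
junction. The filament is modelled as a cylinder — by default the
total-least-squares line through the supplied points (the principal axis of
the centered covariance). At the triangle centroid we erect the local
cylinder frame with **x** tangential, **y** radial outward and **z** along
the axis, and define the triangle's own frame canonically: **e1** from the
centroid toward the free-head vertex, **e3** the unit normal of the ordered
vertex loop (free → blocked → junction), **e2** completing a right-handed
set. The pose is the rotation from the local frame to the triangle frame.

Euler conventions are never self-evident, so they are fixed once,
repo-wide:

* crown poses use **intrinsic Z-Y-X**: `R = Rz(α) Ry(β) Rx(γ)`, angles in
  degrees normalized to (−180, 180]. β is the rotation about the radial
  **y** axis. Near gimbal lock (|β| within 0.1° of 90°) only α+γ is
  determined; γ is set to 0 and the pose is flagged.
* particle orientations use **Z-Y-Z** (`R = Rz(psi) Ry(tilt) Rz(rot)`), the
  common subtomogram-averaging convention; a filament tangent determines
  tilt and psi while rot (spin about the tangent) stays undefined.

The centroid's cylindrical coordinates (φ, r, z) complete the pose; sorted
by z, consecutive same-class crowns yield the per-class axial rise (Δz) and
twist (Δφ). When several C3 copies share one level, copies are paired
across levels by nearest azimuth. One consequence worth knowing: under an
*n*-fold rotational symmetry a lattice twist is only identifiable modulo
360/*n* degrees, and nearest-azimuth pairing reports the representative
closest to zero. The relaxed-filament case (twist 0°) and single-crown
helical extensions are recovered exactly.

Two practical notes on the axis. A straight total-least-squares axis is the
default; for curved filaments a per-segment tangent frame from a traced
polyline is more appropriate. And the principal axis of a *finite* helix is
slightly tilted from the true cylinder axis (the tilt decays like
r/(2π·turns·length)); over the ten-plus repeats of a typical filament
segment this is far below other error sources, but it is why the axis-fit
tests use helices several turns long.

## Sinuosity and the SCP

The midline of a two-chain coiled coil is the polyline through the
midpoints of index-paired α-carbons (an optional pairing offset handles
staggered numbering; heptad-register estimation is deliberately out of
scope). Arc length is the plain polyline sum over the traced midpoints —
no spline is fitted, matching the construction the statistic is defined on.
Sinuosity is S = C/L and SCP = (S − 1) × 100; S is scale- and
rigid-motion-invariant by construction, and refusing windows with
end-to-end distance below 1 Å keeps the ratio stable. A sliding-window
profile (`scp_profile`) and a circumscribed-circle curvature profile after
equal-arc resampling (`curvature_profile`) localize bends and kinks; the
whole-tail value is the default report because the per-crown published
statistics are one number per class.

The superhelical winding of the chains leaves a small residual wobble in
the traced midline, so a perfectly straight coiled coil traces to an SCP
slightly above zero (below 0.05% at the canonical ~5 Å superhelix radius);
this is the floor of the statistic, not a bug.

## The synthetic benchmark

`scene_spec()` fixes the study conditions: 430 Å repeat, three crowns per
repeat, C3 symmetry, layer plan P1–P3 + A1–A28 (31 levels → 93 IHMs), three
titin-α plus three titin-β chains with β ending at A1 (six chains crossing
a C-zone section, three in the P zone), nine stripes at 430 Å spacing (27
anchors), hexagonal thin neighbours, links every 430 Å with angles drawn
from Normal(40°, 10°) and 3–4 domains each, and per-class tails of
**prescribed** sinuosity (SCP 3.05 / 4.44 / 2.53% for crowns 1/2/3, the
undulation amplitude solved by root-finding at build time) with a kink at
fraction 0.556 of the crown-1/2 tails. Crown-class pose presets (radii
125–140 Å, distinct β offsets, ~100 Å landmark triangles) are arbitrary
but distinct conventions chosen so classes are distinguishable; they are
generator parameters, not measurements. The M band sits at z = 0, +z is
Z-ward, and scenes are mirrored about the M plane unless
`half_sarcomere = TRUE`.

Determinism: one integer seed; per-filament substreams are derived
arithmetically from (seed, filament index), so regeneration is
bit-identical and adding filaments does not reshuffle existing ones.

What the generator does *not* emulate: atomic-detail myosin, realistic
tomographic noise or missing-wedge anisotropy, lattice disorder beyond
isotropic Gaussian pose noise, and the genuine axial irregularity of the
P zone. Passing tests therefore demonstrate correctness of the geometry
under known truth, not robustness to every artefact of real tomograms.

## Bookkeeping conventions

* Coordinates are Å everywhere internally; degrees for angles. The native
  particle dialect is a TSV with 1-based segment indices; STAR import maps
  `rlnCoordinateX/Y/Z` (pixels, converted with a mandatory pixel size) and
  `rlnAngleRot/Tilt/Psi` unchanged.
* Axial propagation (±43 nm) walks **arc length along the trace**, not a
  chord, since positions are propagated along traced filaments; records
  whose shift exits the trace are dropped *and counted* — silent loss is
  forbidden. A straight-chord mode is not provided because the trace walk
  reduces to it on straight traces.
* Duplicate removal is greedy by descending score (deterministic for fixed
  input); the threshold is configurable with half the resampling spacing as
  the sensible default. The kept set always satisfies the min-distance
  postcondition, which is asserted in tests against a brute-force oracle.
* Symmetry expansion composes orientations with the same rotation applied
  to positions; D*n* requires the perpendicular two-fold axis explicitly.

## Spectra and link angles

Impulse positions are binned at ≤2 Å, mean-subtracted, zero-padded
(default ×8) and Fourier-transformed; the dominant period comes from the
largest non-DC peak with periods above half the box excluded, refined by
three-point parabolic interpolation in log-power. Pixel-size calibration
is the one-liner `reference / measured`; the round trip through a sampled
profile recovers the pixel size to well under 0.5%.

Link angles are measured from the C7 pivot to the terminal
(thin-filament-proximal) domain point against the filament z axis,
unfolded in [0, 180] by default with optional folding to [0, 90] — the
published plotting convention is not stated, so both are available. In a
mirrored sarcomere the two halves are supplements of each other; analyses
of the distribution should either fold or restrict to one half.

## Numerical choices

* Angles are normalized to (−180, 180], with −180 mapped to +180.
* The classification tie-break (z exactly midway between class offsets)
  goes to the lower class index and is flagged ambiguous.
* `amplitude_for_scp` inverts the midline SCP by `uniroot` at 1e-8
  tolerance; with a kink already exceeding the target it returns amplitude
  0 rather than failing.
* Problem sizes in tests and drivers are desk-scale by design: single
  filaments (93 crowns), 7-filament scenes (~750 links), 500-record
  deduplication, 30-repeat spectra — each stage runs in seconds while
  keeping estimator errors well below the tolerances being checked.

## Known limitations

The deposited experimental models are not bundled, so the per-crown SCP
reproduction on the real C-zone model requires the user to supply the
mmCIF and a chain-pair mapping (see `tail_scp_by_crown`). Twist is
identifiable only modulo the rotational symmetry, as noted. The density
renderer is a Gaussian-blob sketch for spectra and quick looks, not a
simulator. And the circular-statistics treatment of angle summaries is
first-order (deviations from the circular mean), adequate for the few-degree
spreads of crown poses but not for broad distributions near the wrap.
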