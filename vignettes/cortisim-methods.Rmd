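---
title: "Modelling cortical microtubule self-organization in 3D cell volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortical microtubule self-organization in 3D cell volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortisim)
```

## The model

Interphase plant microtubules form a cortical array just beneath the plasma
membrane that guides cellulose deposition and hence cell shape. `cortisim`
simulates this array as an agent-based system of filaments inside a closed
3D cell volume rather than on an abstract 2D surface, which lets cortical
localisation *emerge* (or fail to emerge) from filament dynamics instead of
being imposed.

A microtubule is an ordered chain of unit vectors, each representing a ring
of tubulin of height $\ell = 8$ nm. Chains grow at the plus end by one
vector per time step, and treadmill: after a random onset (probability
$n_s = 10^{-3}$ per step), one vector is removed from the minus end per
step. A time step corresponds to 0.1–0.2 s of real time (plus-end growth
of 3–5 µm/min); the package reports 0.12 s per step by default, so the
standard 50,000-step protocol spans roughly 100 minutes.

### Growth rule and persistence length

In free space the new direction is a normalised weighted average of the
previous direction and a fresh isotropic unit vector $\mathbf{u}$:

$$\mathbf{r}_{n+1} =
\frac{(1 - r_d)\,\mathbf{r}_n + r_d\,\mathbf{u}}
     {\lVert (1 - r_d)\,\mathbf{r}_n + r_d\,\mathbf{u} \rVert},$$

with noise weight $r_d = 0.025$ by default. With a directional cue
$\mathbf{b}$ of weight $b_d$ the average gains a third term $b_d\mathbf{b}$
and the first weight becomes $1 - r_d - b_d$.

Two conventions relate $r_d$ to a persistence length. The defaults were
chosen through the planar-filament mapping $p = 2\ell/r_d^2$, which gives
$p \approx 26$ µm, inside the 20–30 µm range measured in vivo;
`persistence_length()` reports this mapping. The empirically exact 3D
behaviour of the rule is slightly stiffer than the planar formula suggests:
expanding the normalised average for small $r_d$ (with
$E[\mathbf{u}\cdot\mathbf{r}_n] = 0$ and
$E[(\mathbf{u}\cdot\mathbf{r}_n)^2] = 1/3$ for $\mathbf{u}$ uniform on the
sphere) gives a per-step tangent correlation

$$\langle \mathbf{r}_{n+1}\cdot\mathbf{r}_n\rangle
 = 1 - \tfrac{1}{3} r_d^2 - \tfrac{2}{3} r_d^3 + O(r_d^4),$$

verified by Monte-Carlo to within its standard error. Because the azimuth
of the perturbation is symmetric about the current direction, the
correlation is exactly multiplicative, $\langle \mathbf{r}_0 \cdot
\mathbf{r}_s\rangle = c^s$, so free filaments decay exponentially with
per-step rate $-\log c \approx r_d^2/3$ (a 3D-convention persistence length
of $3\ell/r_d^2 \approx 38$ µm). The test suite asserts this verified rate;
both conventions are reported here so that the parameter's provenance and
its actual 3D behaviour are both on record. At cell dimensions of ~10 µm,
either value means filaments are straight on the scale of the cell, which
is the property that matters for the results.

### Encounters: zippering and catastrophe

When a plus end comes within 25 nm of a segment of another (or its own,
non-adjacent) filament, the angle between the two *lines* decides the
outcome: below the threshold $\alpha = 40°$ the tip zippers — its direction
becomes the encountered segment's direction, with the sign chosen to give
the acute angle, so antiparallel shallow encounters bundle too — and at or
above $\alpha$ the plus end switches to catastrophe: it shrinks by one
vector per step, without rescue, until the filament disappears. Because
directional noise is intrinsic to every growth step, zippering replaces
the previous direction with the host's and the noisy update applies on
top; while a tip stays within the interaction distance of its partner it
re-zippers each step ("permanently" following the host), yet bundles
remain dynamic rather than frozen in lock-step — partners drift laterally,
and bundles can dissolve. An earlier variant that copied the host
direction exactly on every re-zipper produced immortal rigid bundles and
unbounded network growth; the noisy form is both the stated reading of the
rule and the dynamically sensible one. The
tip's own three trailing segments are excluded from its collision test to
avoid self-capture immediately after zippering; ties between equidistant
candidates break by lower filament id, then lower segment index. Because
the filament interaction radius (25 nm) exceeds the membrane interaction
distance (10 nm), filament encounters take precedence over the membrane
rule within a step.

### Membrane interaction

The cell surface is a closed triangulated mesh with outward per-vertex
normals. The membrane at a point is approximated by the tangent plane at
the nearest surface point, with the normal interpolated barycentrically.
Two anchoring modes are modelled:

* **Strong anchoring** — growth is confined to the local tangent plane:
  the proposed direction is projected onto the plane, and the step is then
  re-aimed at the nearest surface point of the projected target so the tip
  tracks the curved surface without secular drift (each segment keeps
  exact length $\ell$; residual off-surface error is second order,
  $\sim\ell^2/2R$, and does not accumulate).
* **Weak anchoring** — filaments may grow through the cytoplasm. When the
  tip is within 10 nm of the membrane, the angle between the filament and
  the tangent plane is computed: steeper than $\alpha$ triggers a
  catastrophe (a "head-on" membrane collision); shallower, the noisy
  proposal is accepted if its endpoint stays inside the cell, redrawing
  the noise vector up to 32 times otherwise and finally falling back to a
  step pressed against the membrane (aimed 2 nm inside the surface at the
  nearest point). Endpoints therefore never leave the cell; the fallback
  also recovers a tip that touches the surface to within numerical
  tolerance. Following the dynamics as written, the angle test uses the
  current filament direction (the new vector is what gets redrawn).

A zippered direction near the membrane is subject to the same containment
guard: if adopting the host direction would carry the tip out of the cell,
the membrane rule applies to that direction instead. Without this guard a
single escaped tip recruits its bundle partners outside the volume and the
array delocalises — containment is a hard invariant of the weak mode.

### Nucleation

Filaments nucleate on the cell surface at a constant rate, uniformly per
unit area (area-weighted triangle choice, uniform barycentric point). The
rate parameter $n_p = 4.7\times10^{-7}$ is interpreted per $\ell^2$ of
surface per step, giving circa 3 events per step on the standard cube; an
`events_per_step` override is available where an absolute rate is wanted.
Newly nucleated filaments are visible to collisions immediately but first
grow on the following step.

The initial direction is *uniform tangential* by default. The
`nucleation_direction = "isotropic"` switch instead draws uniformly over
directions pointing into the cell. The choice matters: with isotropic
nucleation every filament begins as a chord crossing the cell interior,
and at steady state these chords hold so much tubulin that the mean
segment–membrane distance rises to ~500 nm on the 8.8 µm cube and the
bundled fraction falls to ~15%, far from the observed cortical arrays.
With tangential nucleation the array is cortical (mean distance
~70–90 nm) and heavily bundled (~50–70%), matching the behaviour this
model family is known for; the tangential rule is also consistent with
nucleation from membrane-associated complexes. This is the package's
resolution of a genuinely open modelling choice, and the switch makes the
comparison a one-line experiment.

### Cell shapes

Standard shapes are rounded boxes built as the Minkowski sum of a shrunken
box and a sphere of the corner radius — so the minimal radius of curvature
equals the corner radius by construction, with analytic normals — and
ellipsoids of revolution triangulated from a projected subdivided cube (no
pole degeneracy). The registry covers the cube (8.8 µm side), "square"
(9 × 9 × 4.7 µm) and "long" (4.8 × 4.8 × 15.6 µm) boxes, each sharp
(corner radius 1.3 µm) or smooth (4.7 µm where the thickness allows;
clamped to half the smallest dimension for the square and cube, whose
thinness caps the feasible radius), and the 10.3 × 16.8 µm ellipsoid used
for cue experiments. The default mesh edge of 0.4 µm keeps at least ten
triangles per smallest curvature radius; surface area changes by under 1%
on refinement, and nearest-point queries are exact with respect to the
mesh by construction (verified against an all-triangle scan). Meshes can
also be read from ASCII OBJ/PLY files, with normals recomputed when
absent.

### The directional cue

The circumferential cue is the hoop direction around a declared axis of
revolution: at position $\mathbf{x}$,
$\mathbf{b} = \hat{\mathbf{a}} \times \mathbf{x}_\perp / \lVert
\mathbf{x}_\perp\rVert$. Microtubules are nematic, so the cue is an
orientation rather than a signed vector; the kernel picks the sign with
non-negative dot product with the current tip direction, reinforcing
hoop-wise growth of either handedness. On the axis itself the cue is
undefined and the growth rule falls back to its cue-free form.

## The engine

Each discrete step applies, in creation order: (1) nucleation, (2)
minus-end updates, (3) plus-end updates, (4) removal of empty filaments.
Segments added earlier in a step are immediately visible to later
collision tests (a serial update, reproducible by construction); removed
segments leave the index immediately. Collision candidates come from a
spatial hash with 50 nm buckets — twice the interaction radius, so a query
touches at most eight buckets. Membrane probes go through a
uniform-grid triangle index with warm starts from the previous nearest
triangle, and are skipped entirely while the last measured distance
guarantees the tip cannot have reached the membrane (the tip moves at most
$\ell$ per step), which removes most mesh queries for interior filaments.

All randomness flows from one deterministic counter-based stream
(xoshiro256++ seeded by splitmix64) consumed in a fixed order, so a given
(mesh, parameters, seed) triple yields bit-identical trajectories on the
same floating-point platform. Segment bookkeeping is exact: per step, the
change in total segment count equals additions minus removals, asserted in
the tests.

The within-step operation order is a modelling decision (the dynamics are
specified per filament, not per network). The declared order matches a
serial implementation; summary statistics are insensitive to it because
per-step changes are tiny compared with network turnover.

## Quantification

* **Nematic order parameter.** For the $N$ directions in a region,
  $M = D^T D / N$ is diagonalised and
  $A = \sqrt{\tfrac{3}{2}\sum_i(\lambda_i - \bar\lambda)^2 / \sum_i
  \lambda_i^2} \in [0, 1]$. The cell average splits the bounding box into
  3 × 3 × 3 cubes and averages $A$ over non-empty cubes (empty corner
  cubes outside a rounded shape carry no information); a 6 × 6 × 6 grid
  gives the same trends with globally higher values, as expected from
  averaging over smaller regions.
* **Bundled fraction.** The dynamics do not define "a bundle", so the
  metric reuses the interaction geometry that creates one: a segment is
  bundled when a segment of another filament lies within 25 nm with line
  angle ≤ 40°. Both thresholds are arguments; the fraction is monotone in
  each.
* **Membrane distance.** Mean nearest-surface distance over segment
  endpoints (the endpoint of each unit vector), reported in nm. A
  per-filament variant (mean of per-filament means) is available; the
  per-segment form is the default since tubulin mass is the quantity of
  interest.
* **Orientation histograms.** Near-face histograms select segments within
  0.5 µm of the extreme mesh planes along a face normal (the band is an
  argument; the reference data do not state one), project directions onto
  the face and fold angles to (−90°, 90°]. Axis-alignment histograms bin
  $|\mathbf{r}\cdot\hat{\mathbf{a}}|$ over all segments — the absolute
  value because filaments are nematic.

## Rendering

Snapshots voxelise into confocal-like stacks: each segment endpoint adds
1.0 to its voxel and 0.3 to each face-adjacent neighbour (switchable to
the 26-neighbourhood); the z voxel extent is typically ten times the
lateral one, mimicking a confocal point-spread anisotropy, and sum
projections along z conserve total intensity exactly. No optics (PSF,
noise) are modelled; the rendering is a density visualisation.

## Problem sizes, tolerances and degenerate inputs

The full protocol is 50,000 steps with five replicates per condition. The
package's standard experiment scale ("desk", 10,000 steps, three
replicates) sits past the initial transient: membrane distance and network
size stabilise within ~3,000–5,000 steps on the standard shapes, and the
cortical-band, bundling-band, anchoring-contrast and cue tests in the
suite run at this scale. One behaviour needs the full protocol: the
orientation read-out of global cell shape (diagonal modality on square
faces, the long-axis extremum in elongated cells) develops over tens of
thousands of steps — at 10,000 steps each replicate still carries an
arbitrary global orientation — so the orientation checks run one
full-protocol replicate per shape. Simulation seeds derive arithmetically
from a base seed so replicate sets are reproducible.

Numerical choices worth recording: containment uses a 10⁻⁹ µm on-surface
tolerance on the signed offset along the interpolated normal; degenerate
weighted averages (measure-zero antiparallel combinations) redraw the
noise vector; a direction exactly parallel to the local normal under
strong anchoring falls back to a uniformly drawn tangential direction;
encounter angles exactly at $\alpha$ are catastrophes (zippering is
strict); empty direction sets are an error for the order parameter, and
empty cells return zero-filled summaries rather than NaN.

## What the synthetic conditions do and do not show

All inputs are synthetic: the shapes idealise plant cell geometry, and the
dynamics compress microtubule biochemistry into six parameters. Passing
tests show that the implemented rules reproduce the emergent behaviours of
this model family — cortical localisation under weak anchoring, stable
bundled arrays, shape-read-out of orientation, hypersensitivity to weak
directional cues — at the stated parameter values. They do not validate
the parameter values against new experimental data, and the model omits,
by design: severing, branching nucleation, nucleation at the nuclear
envelope, a limiting tubulin pool, rescue events, GTP-cap mechanics,
curvature-dependent catastrophe, and any mechanical-stress feedback (cues
enter only as an abstract vector field). Non-convex or deforming cells are
out of scope; the containment logic assumes a convex, watertight surface.

## Behaviours that do and do not reproduce

Within this reconstruction the canonical emergent behaviours hold: cortical
localisation under weak anchoring (mean segment–membrane distance of tens
to low hundreds of nm across the standard shapes), heavy spontaneous
bundling, higher bundling and anisotropy under strong anchoring, lower
anisotropy for sharper cell edges, face-diagonal orientation on square
faces, long-axis alignment in elongated cells, and reorientation by
circumferential cues of weight down to 10⁻³.

One reported comparison reproduces only in part. Weak anchoring is
reported to increase both microtubule number and mean length (by ~20%)
relative to strong anchoring. The number effect reproduces here, but the
length effect is consistently reversed: strong-anchored filaments end up
longer. The event traces show why: strong-anchored survivors bundle so
heavily (~75% of tubulin) that steep encounters — their only death
channel — become rare, so the filaments that do survive keep elongating,
while weak-anchored filaments additionally die on steep membrane
approaches and are replaced by young, shorter ones. The length-sign
assertion in the test suite is kept as stated and fails, so the
discrepancy stays visible rather than being papered over.

## Known limitations

* The serial update order is part of the model definition; reordering
  filament updates changes individual trajectories (not summary
  statistics).
* Strong-anchoring tips sit on the *mesh*, so "distance to the membrane"
  under strong anchoring reflects mesh faceting (sub-nm at the default
  resolution) rather than biology.
* The bundled-fraction metric is a geometric proxy; absolute values shift
  with its thresholds (trends do not).
* Without a limiting tubulin pool (deliberately unmodelled), total tubulin
  does not strictly plateau: past the initial transient the segment count
  still drifts upward by a few percent per thousand steps as bundling
  slowly shelters filaments from encounter death. Snapshot-level
  comparisons therefore always score a fixed step count.
* At very high cue weights ($b_d$ comparable to $1 - r_d$) the growth rule
  leaves the small-noise regime in which the persistence-length mapping
  holds.
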