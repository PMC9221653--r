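---
title: "Differential static magnetic tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential static magnetic tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magtrack)
```

`magtrack` simulates and evaluates tracking of a permanent magnet — a
stand-in for a magnet-bearing capsule endoscope — with an external
magnetometer array, using sensor-pair differencing to cancel the
geomagnetic background. This vignette explains the models, every tunable
parameter that matters, the numerical choices, and what the simulation
does and does not establish about a physical system.

## The forward model

A cylindrical magnet with radius $k$, length $l$ and axial magnetisation
$M_0$ is modelled as a point dipole with moment $m = M_0 \pi k^2 l$
(magnetisation times volume). At displacement $R$ from the magnet centre,
with unit orientation $o$,

$$B(R) \;=\; \frac{\mu_0 m}{4\pi}\,
  \frac{3\langle o,\hat R\rangle \hat R - o}{\lVert R\rVert^{3}},$$

with $\mu_r = 1$ fixed: human tissue is magnetically transparent, which is
the reason magnetic localisation works through the body at all. The
approximation assumes the observation distance is much larger than the
magnet's largest dimension. `finite_volume_field()` quantifies the error
by integrating the same kernel over an equal-volume partition of the
cylinder (equal-volume radial shells × angular sectors × axial slabs);
with one cell it collapses to `dipole_field()` identically, and the
deviation falls off as the square of dimension/distance. A caution learned
from measuring this: the relevant scale is the *largest* dimension. For
the flat 3 × 10 mm magnet, five magnet *lengths* (15 mm) is deep inside
the near field of its 10 mm diameter; at five *diameters* the
worst-direction deviation is still slightly above 1%, and only around
7–8 diameters does it drop comfortably below. The sensors in the default
geometry sit ≥ 100 mm from the workspace, where the dipole approximation
is excellent for all three catalog magnets.

## Differential localisation

Each equally oriented sensor pair $(i, j)$ contributes the residual
$\Delta B_{pair} = (B^{meas}_i - B^{model}_i) - (B^{meas}_j -
B^{model}_j)$. Because both sensors see the same homogeneous background,
it subtracts out *exactly* — the method estimates the background nowhere.
The pose minimises $\epsilon_{diff} = \sum_{K} \lVert \Delta B_{pair}
\rVert^2$ over six unknowns: three position components plus a free
orientation 3-vector that is normalised inside the field model and on
output. The free-vector parameterisation keeps the problem smooth and
unconstrained; the cost is flat along the vector's length, which
Levenberg–Marquardt damping handles without special treatment.

Sign of the orientation: under the dipole model $B(-o) = -B(o)$, so the
magnetisation sign *is* identifiable from data and the solver never flips
an estimate to match its initialisation — flipping would strictly worsen
the fit. The axis-angle error metric $\arccos\lvert\langle e,
r\rangle\rvert$ is nonetheless the default, because downstream uses
(movement direction, rotation tracking) care about the axis, and because
it stays meaningful for solvers or hardware that cannot resolve the sign.

### Solver settings

* Levenberg–Marquardt via `minpack.lm::nls.lm`, relative cost and
  parameter tolerances $10^{-10}$, at most 200 iterations per start
  (`localizer_control()`, all configurable). The convergence flag is the
  solver's own info code; non-converged frames are reported, excluded
  from orientation means, and carried through distance accumulation at
  the last converged position so they add no fictitious length.
* Cold starts score the differential cost on a coarse grid — $5^3$
  positions spanning 75% of the ellipse semi-axes and the full ring span,
  crossed with the six axis-aligned orientations — and refine the six
  best candidates by LM, keeping the lowest cost. During tracking only
  the first frame is cold; every later frame warm-starts from the
  previous converged estimate.
* `grid_search_pose()` is a brute-force argmin over an explicit pose grid,
  kept as an independent cross-check: LM refined from the grid argmin can
  only descend.
* A trial pose closer than 1 mm to a sensor, or a vanishing orientation
  vector, returns a large constant residual, steering the optimiser away
  from the singular set instead of evaluating it.

`locate_pose_standard()` implements the non-differential baseline
(per-sensor residuals minus an *assumed* background). It exists to
demonstrate the method's point: with a wrong assumed background the
baseline is biased by tens of millimetres while the differential estimate
is unchanged — bit-for-bit, see below.

### Exactness of the cancellation

Mathematically the cancellation holds for any homogeneous field. In IEEE
arithmetic, adding a background to already-rounded readings perturbs them
by up to half an ulp each, so residuals computed from shifted readings can
differ in the last bits. Whenever readings and background lie on a common
binary-representable grid — e.g. quantised to a power-of-two LSB such as
$2^{-25}$ T ≈ 29.8 nT, the same order as the reference device's 32 nT —
every addition is exact and the entire LM iterate path is bit-identical
with and without the background. The test suite verifies this
bit-identity; under the default 32 nT decimal grid the discrepancy is
instead at the $10^{-20}$ T level, physically nil.

## The sensor array and measurement chain

The default geometry follows the reference setup: 12 three-axis sensors,
four per ring at parametric ellipse angles 0°/90°/180°/270° (the exact
angular placement is not documented for the physical array; symmetric
coverage is the natural default and the angles are configurable), on
three 400 × 330 mm elliptical rings at $z = -100, 0, +100$ mm. All
sensors share one global orientation frame, so *every* pair is equally
oriented; the default pairing uses all $\binom{12}{2} = 66$ pairs
(198 equations for 6 unknowns), with a `"disjoint"` mode (6
diametrally-opposite pairs) for ablation. Whether the original experiments
used 6 or 66 pairs is not documented; maximising the equation count is
the natural default and both are available.

The measurement chain per sensor and frame: add the background field, draw
`n_average = 3` raw samples with per-axis Gaussian noise, clip each to
±800 µT, round each to the nearest 32 nT LSB, then average — the order a
physical ADC front end imposes. The noise figure $\sigma = 0.3$ µT per
axis before averaging is a representative magnetometer value (the
reference experiment does not state one) and is freely configurable; the
suite checks that averaging delivers the expected $\sigma^2/3$ variance
and that quantisation error stays within LSB/2.

## Calibration

`fit_ellipsoid()` implements hard-/soft-iron correction: readings of a
constant-magnitude field taken over all orientations lie on an offset
ellipsoid; an algebraic quadric least-squares fit (nine parameters, rank
check against coplanar input, positive-definiteness check against
non-ellipsoid quadrics) yields the centre (hard-iron offset) and, via the
unique symmetric positive-definite matrix square root, the soft-iron
correction scaled to a reference radius. The reference radius defaults to
the local geomagnetic magnitude (48 µT) since the true field magnitude is
the only physically meaningful normalisation available; the symmetric
root resolves the rotational ambiguity inherent in ellipsoid fits.
Calibration is per-sensor; samples are scaled to unit mean radius
internally for conditioning. The forward distortion simulator
(`simulate_distortion()`) closes the loop for testing: fitting distorted
sphere points must invert the distortion to sub-0.1% radius error.

## The synthetic trajectory and what it emulates

The reference path is known only by summary numbers: 487.5 mm arc length,
15° tilt, 49 mm vertical displacement, roughly 180 × 180 mm footprint,
traversed by hand in 40 s. The generator realises these as a named preset
(`serpentine-v1`): a three-half-lobe sinusoid in a plane tilted 15°, with
the run along the tilted direction fixed by displacement/sin(tilt) and the
transverse amplitude solved by root-finding so the *true curve* arc length
is exactly 487.5 mm. Two consequences are worth knowing:

* The three stated numbers over-determine the footprint: a 15° tilt with
  49 mm displacement forces a 189.3 mm run (182.9 mm after projection),
  slightly over the "approximately 180 mm" footprint. Tilt and
  displacement are kept exact — both are directly testable — and the
  footprint constraint is applied to the transverse extent (145 mm).
* A sampled polyline is always shorter than the curve; at the default 100
  samples per traversal the shortfall is about 0.14%. The tracking result
  therefore reports the relative distance error against the ground-truth
  *sample polyline* (same sampling, isolates estimation error) as the
  primary metric, and against the nominal 487.5 mm (the physical
  procedure's reference) secondarily.

Hand movement is emulated by jittering the arc-length increments between
samples (relative SD `speed_jitter`, default 0.2 — visibly non-uniform
spacing, as reported for the physical runs) while timestamps stay uniform
over 40 s. The default 100 samples per traversal keeps a batch affordable
while leaving ~4.9 mm between samples, comfortably above the sub-mm
per-sample position noise. Magnetisation is perpendicular to the moving
direction by default, realised as tangent × global z (horizontal,
guaranteed non-degenerate here); `parallel` mode aligns it with the
tangent and is restricted to the 10 mm magnet unless overridden,
mirroring the physical protocol where shorter magnets could not be moved
parallel. Because the perpendicular convention keeps the orientation
horizontal, the secondary "tilt-plane" metric (angle between the estimate
and the horizontal plane minus the 15° tilt) is reported for fidelity to
the original procedure but is informative only under conventions where
the orientation leaves the horizontal plane; the primary orientation
metric is always the axis angle against the known simulated truth.

What the generator does *not* emulate: peristalsis and wall contact,
capsule rotation about its own axis, the unknown curvature profile of the
3D-printed physical path, sensor placement error or array deformation
(a body-worn array flexes), and magnetic disturbances from nearby
ferromagnetic objects. Passing the simulated protocol therefore
demonstrates the method's intrinsic accuracy under a well-specified noise
model — not the accuracy achievable on a patient.

## The evaluation protocol

`run_experiment()` executes the full design — per magnet, 5 repeats ×
3 z-planes (−60, 0, +60 mm) × 2 layouts (path along x, path rotated 90°)
= 30 runs — and summarises mean and STD of the per-run relative distance
error and mean orientation error, per magnet. One master seed spawns one
child seed per run (a single draw of run-count integers), so any run is
reproducible in isolation and the whole batch is bit-reproducible. The
acceptance script runs this protocol at exactly the stated configuration
(10 × 10 mm magnet, 48 µT background, σ = 0.3 µT, 3-sample averaging,
32 nT LSB, 100 samples/run) and the test suite additionally runs the
5 × 10 and 3 × 10 mm magnets to check the expected error ordering: error
scales inversely with magnetic moment, so the 3 mm magnet must track
strictly worst. Problem sizes used throughout (30-run batches, 100
samples per run, $10^4$-sample geometry checks, $10^4$-cell volume
integrations) were chosen once as the smallest sizes at which each
quantity is statistically or numerically stable.

## Known limitations

* Single magnet, known moment: the moment is taken from the catalog, not
  estimated; multi-magnet scenes and moment estimation are out of scope.
* No temporal filtering: estimates are per-frame (warm-started, but not
  smoothed); an optional smoother was deliberately omitted because the
  reference procedure applies none.
* The homogeneity assumption: the differential method cancels *uniform*
  fields only; gradients from nearby ferromagnetic objects do not cancel
  and are not modelled.
* The serpentine preset matches the reference path's summary dimensions,
  not its actual shape; conclusions that depend on curvature detail
  (e.g. direction-change classification) cannot be drawn from it.
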