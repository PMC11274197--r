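---
title: "Methods: an idealized left ventricle under aortic stiffening and apical release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an idealized left ventricle under aortic stiffening and apical release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model answers

Left-ventricular (LV) long-axis shortening pumps mostly by pulling the
atrioventricular plane toward a (nearly) stationary apex, stretching the
ascending aorta in the process. If the ascending aorta stiffens, that
stretch costs more force, long-axis shortening falls, and filling pressure
rises — a mechanism implicated in heart failure with preserved ejection
fraction. The package simulates three configurations of one idealized LV:

* **A** — elastic ascending aorta (axial root spring 0.5 N/mm),
* **B** — stiff ascending aorta (10 N/mm, a "stationary" sino-tubular
  junction),
* **C** — stiff ascending aorta with the apical half of the pericardial
  constraint removed, so the apex is free to travel toward the base
  ("inverse longitudinal shortening").

Everything except the aortic spring stiffness and the freed-apex flag is
identical across the three runs.

## Geometry and microstructure

The ventricle is a truncated prolate ellipsoid (cavity semi-axes 22 x 52 mm,
wall thickness 10 mm, basal truncation at z = 20 mm, all scaled by one
calibrated factor), with landmarks at the epicardial apex, the annulus-plane
center and an aortic-root attachment offset 26 mm toward the septal azimuth.
Fibers follow the rule-based convention: helix angle linear across the wall
from +60 deg (endocardium) to -60 deg (epicardium), fiber in the local wall
tangent plane. The sheet axis is taken **in the wall tangent plane**
orthogonal to the fiber, with the sheet normal transmural. This is a
deliberate constitutive-frame choice: with the tabulated sheet moduli
(`a_s = 1.1e-3` MPa, `b_s = 11`), a transmural sheet axis would penalize
systolic wall thickening with energies of order `exp(30)` — physiological
radial strains (+0.4 to +0.6) would be impossible.

## Passive and active material

The passive wall follows the orthotropic Holzapfel–Ogden energy with the
tabulated human-ventricle constants; the isotropic term acts on the
isochoric invariant `I1bar = J^{-2/3} I1` so the reference state is exactly
stress-free, the fiber and sheet terms are tension-only, and a quadratic
volumetric penalty (`kappa = 5` MPa) carries the near-incompressibility.
Active contraction adds a fiber-aligned second Piola–Kirchhoff stress from
the time-varying-elastance model: a cosine twitch (time to peak 0.35 s, a
length-dependent linear relaxation duration) scaled by a calcium/sarcomere
length sensitivity, so that longer fibers produce more tension
(Frank–Starling). Contractility is fixed at `T_max = 0.2` MPa in every
scenario. An optional fraction of the active stress can be applied along
the sheet axis; the default is 0 (fiber only).

## Reduced-kinematics wall mechanics

Instead of a general finite-element discretization, the deformed
configuration is described by nine smooth global modes, and the constitutive
laws are evaluated by Gauss quadrature (3 transmural x 6 meridional x 8
circumferential points by default; the contract is energy minimization, not
any particular mesh). The radial kinematics are built to conserve volume
exactly: within each material slab the deformed squared radius is

    rho'^2 = rho_i^2 (1 + W(zhat)) + (rho^2 - rho_i^2) / lambda_z(zhat),

where `W` is a three-mode endocardial inflation profile and `lambda_z` the
axial stretch of the slab, which makes `det F = 1` identically for the
axisymmetric part of the map. The remaining modes are apex and base axial
translation, an axial bulge, one penalized transmural compressibility mode,
a tilt of the (planar, circular) basal ring about the in-plane axis normal
to the septal direction, and an apical-cap axial-thickening mode (the
epicardial apex moves away from the base as the cap thickens in systole).
Twist about the long axis is suppressed; torsion does not enter any of the
reported metrics.

Equilibrium minimizes total potential energy (strain energy + volumetric
penalty + active work − cavity-pressure work + spring energies) with a
Levenberg-regularized Newton method on batched finite-difference gradients
and Hessians. Volume-driven solves treat the pair (modes, pressure) as a
saddle system with the cavity-volume constraint, and the active stress is
re-linearized about the current fiber strain each iteration so the Newton
model carries the Frank–Starling tangent stiffness. Convergence is declared
when the undamped Newton step falls below `1e-6` of the characteristic mode
amplitudes (about 0.1 um of displacement); a gradient-based residual cannot
be driven much below ~1e-6 relative because the quadrature energy carries a
round-off floor of ~1e-10 of its magnitude in double precision. The
tension-only gates are smoothed over a width of 1e-3 in the squared-stretch
invariants so the energy stays twice differentiable; the difference from
the hard gate is of order 1e-10 MPa.

## Boundary conditions

*Pericardium.* Forty-nine clusters of epicardial nodes (k-means with a
fixed seed, evenly covering the epicardium) are each tethered by a spring
acting along the cluster's reference outward normal, so the wall can slide
tangentially within the pericardial sac while normal motion is resisted.
Near the apex the normal is axial — this is what holds the apex — and the
stiffness falls linearly from `k_apex` (calibrated) at the apex to
`k_base = 0.05` N/mm at the base. Scenario C deactivates every cluster in
the distal (apical) half.

*Aortic root.* The basal ring stays planar and circular; its center
translates axially and the ring may tilt about the in-plane axis normal to
the septal direction (twist is suppressed). The aortic-root attachment sits
on the septal side, 26 mm from the ring center; the root tissue between
that attachment and the sino-tubular junction is an axial spring of
2 N/mm in series with the ascending-aorta spring (0.5 or 10 N/mm) — the
root is "constrained from rotation but allowed to stretch". Root
displacement is reported at the sino-tubular junction, where the
ascending-aorta spring acts. An aorto-septal continuity tie (8 N/mm)
couples the upper septal wall to the root attachment; it is nearly inert
when the root travels with the base (scenario A) and loads the septum
specifically when the root is immobilized (B and C). This tie is what
produces the septal-dominant loss of longitudinal strain under a stiff
aorta.

*Valve plane.* The cavity pressure acts on the whole wetted surface,
including the fictitious basal cap that closes the cavity at the valve
plane. In the real heart the structures above that plane push back with
approximately atrial pressure; the model therefore applies a counter
pressure (the instantaneous atrial pressure from the circulation) to the
cap. Without it, the pressure piston on the cap lifts the base by ~7 mm
during diastole, which is an artifact of truncating the anatomy.

## Circulation and coupling

A closed loop of three compliance compartments (left atrium, two-element
Windkessel artery, lumped venous/pulmonary return) exchanges volume with
the cavity through diode-resistor valves. The coupling is volume-driven:
each 10 ms the constrained mechanical solve returns the cavity pressure
and the exact local chamber elastance dP/dV (from the saddle-system
factors), and the circulation advances in 1 ms explicit sub-steps using
that elastance as a pressure predictor. Total blood volume is conserved to
round-off (< 1e-9 mL per beat). Beats repeat until the stroke volume
changes by less than 1% between cycles (typically 4–8 beats). The cycle
length is 1.0 s; the atrial booster is off by default.

## Calibration

The published model leaves its operating constants unprinted, so the
baseline (scenario A) is calibrated once and the result reused verbatim for
B and C:

1. the geometry scale is found by a bounded root search so passive
   inflation at the end-diastolic pressure target (11.85 mmHg, with the
   valve-plane counter-pressure engaged) gives the end-diastolic volume
   target (158.3 mL);
2. a damped fixed point then adjusts the systemic resistance (mean arterial
   pressure target 94.9 mmHg, the stroke-work/stroke-volume ratio of the
   published baseline), the total blood volume (end-diastolic volume) and
   the apical pericardial stiffness (systolic root excursion target
   11.0 mm) on coupled runs, warm-starting each iteration from the previous
   limit cycle. A combined fixed point replaces strictly sequential 1-D
   searches because the three targets are only weakly coupled and each
   coupled run is the dominant cost.

The structural constants that are not calibrated per run — root-tissue
stiffness (2 N/mm), septal tie (8 N/mm), root offset (26 mm), pericardial
`k_base` — were chosen once so the model reproduces the qualitative
endpoints the source simulations state for the stiff-aorta limit
(near-stationary sino-tubular junction, septal-dominant strain loss,
elevated myofiber stress) and then frozen across all scenarios and seeds.

## Reported metrics

End-diastole and end-systole are the extrema of the volume trace of the
converged beat. The post-processing mirrors the published reporting
surface: PV-loop quantities with `SW = SV x MAP` (MAP is the time-averaged
Windkessel pressure; the shoelace loop area is reported alongside), strain
at 12 locations (3 axial levels x 4 azimuthal sectors, at an endocardial
and an epicardial layer, pooled in the averages) as relative length changes
of short material fiducials along the cylindrical radial, circumferential
and longitudinal directions (exact endpoints via Newton inversion of the
shell parameterization, so affine deformations are reproduced to machine
precision), regional longitudinal strain per sector, volumetric-averaged
Cauchy myofiber stress at end-systole (deformed volumes as weights;
comparisons as element-wise percent changes, mean ± population SD), and
apex/root displacements projected on the apex–base axis (apex positive
toward the base; root reported positive toward the apex).

## What the synthetic ventricle does and does not capture

The generator stands in for an anatomically detailed heart: it reproduces
an LV with a ~158 mL end-diastolic operating point, a partitionable
epicardium, identifiable landmarks and a transmurally rotating fiber field.
It omits the atrium and aortic root as solids, valve leaflets, papillary
muscles, the right ventricle, electrical propagation (activation is
prescribed and spatially uniform) and torsion. Passing tests therefore
demonstrate the *mechanism* — the axial force balance between aortic
spring, pericardial tethering and long-axis contraction, and its regional
septal expression — not patient-level accuracy of any absolute value. The
published absolute finite-element results (e.g. stroke volume 82.2 mL in
the stiff-aorta case, apex travel 15.4 mm with the apex freed, myofiber
stress 0.076 MPa) are treated as qualitative bands; directions and
orderings are the contract.

## Numerical choices and degenerate inputs

* Quadrature: Gauss–Legendre in the transmural and meridional coordinates,
  uniform (spectrally accurate) azimuthal rule; the cavity volume uses a
  smooth surface quadrature plus an analytic basal-cap term (ring tilt
  enters the cap at second order only).
* Load stepping: failed cold solves restart with ramped load fractions
  (0.25/0.5/0.75/1); element inversion (`det F <= 0`) or a vanishing
  deformed radius marks a trial step infeasible and the step is rejected.
* Degenerate inputs are rejected with errors: wall thickness at least the
  inner semi-axis, truncation above the cavity, fewer epicardial nodes
  than clusters, freed fraction outside [0, 1], non-positive relaxation
  duration where force develops, sampling sites outside the wall.
* Determinism: the only stochastic step is the k-means seeding of the
  epicardial clusters, controlled by the configuration seed; solves and
  calibration are deterministic given a configuration.
* Problem sizes: the default study uses 144 Gauss points, 100 mechanical
  steps per 1 s beat with 1 ms circulation sub-steps, and at most 12
  calibration iterations of at most 3 warm-started beats; a full
  calibrated three-scenario study completes in about two minutes on one
  CPU.

## Known limitations

* The rigid-ring basal reduction routes the entire axial wall pull through
  one attachment. Under the stiff aorta the sino-tubular junction therefore
  retains a residual systolic excursion of ~1.5 mm rather than falling
  below 1 mm; softening the root tissue enough to pin it also erases the
  stiff-aorta loading that elevates myofiber stress. This is the one
  stated acceptance bound the reduction does not meet; the 7x reduction
  versus baseline reproduces the qualitative "stationary aorta" endpoint.
* Margins on the myofiber-stress ordering (baseline < freed apex < stiff)
  are about 1%: real but small, reflecting that a global volume average
  dilutes what is regionally a septal stress concentration.
* The end-diastolic pressure of the calibrated loop (~14–17 mmHg) sits
  above the published 11.85 mmHg because the reduced wall is axially
  softer than radially; EDV, SV, MAP and SW are on target.
* The empirical single-beat filling curve is used only as a shape check on
  passive inflation (agreement within a factor of ~3 over the lower limb),
  not as a fitted constraint.
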