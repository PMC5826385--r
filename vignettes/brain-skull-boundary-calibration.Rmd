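---
title: "Measuring and calibrating the brain–skull boundary in rotational head injury models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and calibrating the brain–skull boundary in rotational head injury models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Rapid head rotation makes the soft brain lag behind the rigid skull. The
relative displacement at the brain–skull interface loads the parasagittal
bridging veins, whose rupture is the presumed mechanism of extra-axial
hemorrhage. Finite element head models therefore need a validated
brain–skull boundary condition, and the validation data come from
transection experiments: a hemisected neonatal piglet head is potted with
the cut plane against a transparent cover plate, ink dots mark the exposed
brain surface and the rigid skull/potting annulus, and a high-speed camera
films the dots during a 65° rotation at ~52 rad/s peak velocity. The
boundary is represented in the model by linear spring connectors between
brain surface nodes and their nearest skull nodes; the connector stiffness
is calibrated so that simulated displacement maxima match the measured
ones, via regression through the origin and a confidence-interval
criterion. This package implements the measurement procedure, a
reduced-order two-dimensional analogue of the simulator, the calibration,
and a synthetic-experiment generator that makes the whole chain testable
without any external data.

## The measurement procedure

Dots are segmented per frame (Otsu threshold on the preprocessed image,
8-connected components, area filter, intensity-weighted centroids for
sub-pixel precision) and linked frame to frame by greedy mutual-nearest
assignment with a hard 10-pixel radius — the linking rule used for the
original videos. Each peripheral brain dot is paired with its nearest
rigid dot; the inter-centroid distance over the 50 frames before motion is
averaged into a baseline, and the signed relative displacement is the
per-frame distance minus that baseline. Two quantities are extracted per
pair: the maximum displacement during motion, and the maximum over the
50 pre-motion frames, which serves as the digitization-error measure.
Summary tables pool pair-level values over the union of pairs
(count-weighted), never as a mean of per-experiment means. Wilcoxon
signed-rank tests compare motion maxima against error measures; the
statistic is min(V+, V−) with the exact null distribution for n ≤ 25.

The motion-start frame is detected from the angular-rate signal (first
sample above 1% of peak velocity); the original experiments aligned the
video and velocity streams manually, so this threshold is configurable.
The "superior-only" subset — the dots that govern bridging-vein
elongation — is defined as brain markers in the top tercile of the
first-frame bounding box, also configurable, since the original selection
was visual.

## The constitutive model

Brain tissue is a first-order Ogden hyperelastic solid,
W = (2μ(t)/α²)(λ₁^α + λ₂^α + λ₃^α − 3), with a two-term Prony series
shear relaxation μ(t) = μ₀(1 − ΣCᵢ(1 − exp(−t/τᵢ))). Defaults are the
neonatal porcine constants: μ₀ = 553 Pa, α = 0.01, C₁ = 0.3322,
C₂ = 0.3890, τ₁ = 2.9572 s, τ₂ = 0.1813 s, ρ = 1.04 g/cm³. With α this
small the deviatoric energy is within 0.5% of the log-strain form
μΣ(ln λᵢ)² over the working stretch range — a property the tests assert.
Near-incompressibility is enforced by a volumetric penalty K(J − 1) with K
from (μ₀, ν); the nominal ν = 0.49999 would force a vanishing explicit
time step, so the default is softened to ν = 0.495 (configurable), which
changes the bulk modulus, not the deviatoric response being calibrated.
Viscoelasticity is applied to the deviatoric Kirchhoff stress through
recursive exponential internal variables, the standard explicit-code
equivalent of the hereditary integral; the tests verify μ(0) = μ₀,
μ(∞) = μ₀(1 − C₁ − C₂), and relaxation of a held stretch by exactly
μ(t)/μ₀.

## The reduced-order simulator

The converged 3D hexahedral model is deliberately replaced by a
plane-strain triangle mesh of the transected section: the 2D cut plane is
where the physical measurement lives, and a desk-scale solver makes the
calibration *procedure* fully testable. Consequences to keep in mind:

* The out-of-plane thickness is set so the section carries the mass of the
  transected half brain (22.3 g, half the 44.6 g intact brain);
* connector stiffnesses calibrate to model-internal synthetic experiments
  — the published 46.133 N/m is specific to the published 3D mesh and is
  reproduced here only through the selection-rule worked example;
* eleven bridging veins against ~30–60 surface nodes is a far larger
  proportion than eleven against 1,398, so vein effects are amplified
  relative to the source model (see below).

The mesh is built from polar outline profiles: the sagittal profile is an
irregular closed curve with a brainstem notch, a cerebellar lobe, an
olfactory prominence and a smooth superior arc; the axial profile is a
smooth ovoid; a circle is available as a reference. Interior points sit on
arclength-graded rings and are Delaunay-triangulated (deldir), keeping
triangles whose centroid lies inside the star-shaped outline. The skull is
a rigid offset polyline at the subarachnoid gap (1.5 mm default); its
superior arc (50°–130°) is tagged as the falx, which the source model ties
rigidly to the skull — the falx elastic constants (ρ = 1.13 g/cm³,
E = 15 MPa, ν = 0.45) are four orders stiffer than brain, so the falx is
carried as part of the rigid boundary rather than as deformable elements.

Integration is explicit central-difference (leapfrog) with the time step
at 0.8× the stability bound from the smallest edge and dilatational wave
speed, further capped by the stiffest spring frequency
(connector/contact/vein) and snapped to divide the 2,500 Hz output
interval. Mass-proportional damping defaults to 1% of critical at the
fundamental bulk frequency. Contact with the skull uses a radial penalty
(10⁴ N/m per node) with normals from the polar boundary description and
Coulomb friction μ = 0.2, stick regularized viscously. The input pulse is
low-pass filtered at CFC 200 before driving the skull: a second-order
Butterworth applied forward and backward, designed so the two-pass −3 dB
point is at 1.65 × 200 = 330 Hz; `signal` is not available in this
environment, so the biquad and the reflection-padded filtfilt are
implemented in the package and verified against their design response.
Hourglass and distortion control are unnecessary for constant-strain
triangles. Energy accounting (kinetic + Ogden strain + connector energy,
with centred velocities) is exposed for diagnostics; a free-vibration run
with damping, contact and viscoelasticity off drifts < 2% over a
pulse-length window at the stable step.

## Connector formulations

"Linear elastic spring connectors" admits two readings, and they differ
materially in 2D:

* **axial** — force −k·(length − rest length) along the current chord.
  An axial spring at its rest length has *zero* tangential stiffness (and
  a destabilizing lateral term under compression), so with a 553 Pa brain
  even a very stiff axial boundary lets the surface skate along smooth
  arcs. Tangential restraint then comes only from boundary *geometry*:
  the brainstem notch and other irregularities of the sagittal outline
  restrain sliding that a circular section permits freely. That is
  exactly the geometry-dominance observation the source experiments make,
  and the package's qualitative test of it (circle slides more than
  sagittal at equal stiffness) runs in this mode.
* **vector** (default) — force −k times the deviation of the current
  chord from the rigidly co-rotated rest chord. This resists normal and
  tangential relative motion equally, behaves like a pair of
  fixed-direction component springs, and locks the boundary as k grows:
  at k = 10⁶ N/m the maximum relative displacement is below 0.02 mm. The
  calibration sweep, the recovery harness and the rigid-limit check use
  this mode, because a calibration variable must actually control the
  quantity being matched across its whole range.

Both modes are exposed via `attach_connectors(mode = )`; switching them is
a one-argument change everywhere downstream.

## Bridging veins

Eleven veins anchor along the falx arc divided anterior→posterior into
20/20/30/30% segments carrying 5/0/6/0 anchors, evenly spaced at interior
fractions i/(n + 1) so segment endpoints (including the exact midline
node) carry no vein. Each anchor ties the nearest falx node to the nearest
distinct brain surface node; those brain nodes lose their general
connector, which reproduces the published count arithmetic
(1,398 − 11 = 1,387 at the source model's scale). Veins are tension-only
nonlinear axial elements: force = area × σ(λ) for λ > 1, exactly zero in
compression, with λ clamped (and flagged) beyond the last curve knot. The
published stress–stretch source curves are not tabulated anywhere in
print, so the shipped `post_cyclic` (long low-stress toe — the worst case
for tethering) and `high_rate` (short toe, stiffest rise) curves are
clearly-labelled synthetic stand-ins with configurable knots, as is the
0.5 mm² cross-sectional area and the 1.6 ultimate-stretch flag threshold.
Because 2D veins are proportionally ~50× more numerous per surface node
than in the 3D source model, the slope difference between vein variants at
the optimal stiffness is larger here (≈0.05) than the published ≈0.001;
the sensitivity test asserts the qualitative conclusion (little influence
relative to the connectors) at a model-appropriate materiality of 0.15,
and virtual measurement markers never sit on vein anchor nodes — physical
ink dots do not coincide with vein insertion points, and connector-free
anchor nodes would otherwise dominate pooled maxima at this mesh scale.

## Calibration

For each stiffness k, the simulator runs every experiment; per-pair maxima
are extracted by the *same* displacement pipeline operating on virtual
markers (means of mapped node sets, mirroring the up-to-four-node dot
matching of the source study); pairs pool across all experiments into one
regression through the origin, d_FEM = a·d_EXP, with
a = Σxy/Σx², se = √(Σr²/((n−1)Σx²)) and a t quantile on n − 1 degrees of
freedom — the no-intercept convention is stated explicitly because it
varies between texts; with only the slope estimated, n − 1 degrees remain,
and the coverage test confirms 95% ± 2% over 10⁴ simulated regressions.
A stiffness is a candidate when both the all-pairs and superior-only CIs
contain 1; the winner minimizes max(|a_all − 1|, |a_sup − 1|). On the
published sweep this returns 46.133 N/m, and the sum-of-deviations metric
returns the same value, so the metric choice is not outcome-determining.
Sweeps share a common time step (the stiffest grid point's stable step) so
that d_FEM(k) is smooth and its monotone decrease in k is a meaningful
test.

The recovery harness closes the loop: synthetic "measured" maxima are the
simulator's own output at a true stiffness plus Gaussian noise, and the
sweep + selection must return that stiffness. Noiseless recovery is exact
(slope exactly 1, zero-width CI). With very small noise the CIs can become
narrower than the grid spacing so that *no* grid point formally satisfies
the CI criterion; `select_optimal()` keeps the prescribed error in that
case, while the harness falls back to the pure deviation metric so that
Monte-Carlo replicates remain comparable. At 0.1 mm noise (the measured
error scale), 20 seeded replicates select within one grid step of the true
stiffness well above the 80% requirement.

## What the synthetic generator does and does not emulate

The generator reproduces the *statistical structure* the analysis relies
on: pulse kinematics with half-cosine ramps hitting specified peak
velocity/acceleration/deceleration and total angle; 2–3 mm dots at
realistic counts and spacings; rigid-body motion of the annulus markers
(pairwise distances constant to 10⁻⁹ mm); a brain-lag waveform with two
peaks and its global maximum at the end of deceleration, applied along the
local direction of motion; sub-pixel centroid noise at the measured
0.31 mm error scale (0.13 mm per coordinate reproduces it); anti-aliased
8-bit rendering and optional 120 Hz illumination flicker. It does *not*
emulate tissue texture, dot-edge irregularity, motion blur, lens
distortion, or any actual brain dynamics — the lag waveform is a stated
shape, not physics. A green end-to-end test therefore establishes that the
pipeline measures what the generator put in (to ±0.05 mm through
rasterization), not that the waveform itself is biofidelic. The rotation
centre is unreported for the original apparatus beyond "within the
cervical spine"; the default places it 40 mm inferior to the section
centroid, and it is a configuration parameter everywhere.

## Numerical and design choices, in brief

* Image convention: 0-based pixel centres, x right / y down; physical
  frame x right / y up in mm; one conversion pair (`mm_to_px`,
  `px_to_mm`) owns the mapping.
* Linking ties resolve to the lowest centroid index (logged); pairing
  ties to the lowest rigid label (logged); selection ties to the stiffer
  candidate (logged).
* Tracks must span 90% of frames (configurable) to enter pairing,
  mirroring the "successfully segmented" language of the source protocol.
* Pooled SDs are computed from the union of pair-level values; when only
  rounded per-experiment rows exist (published-table recomputation mode),
  only pooled means are recomputed — pooled SDs are not recoverable from
  rounded summaries.
* The default calibration grid spans the published two-decade range
  (34.6–4,000 N/m) but concentrates points near k ≈ 10³ N/m where the
  default synthetic world's slopes cross 1, just as the published sweep
  concentrates its grid near its own crossing.
* Degenerate inputs error loudly and specifically: infeasible pulses name
  the minimum achievable angle, overcrowded layouts the maximum feasible
  count, out-of-frame markers the offending marker and frame, short
  baselines the missing frame count, element inversion the element and
  time.

## Known limitations

The dimensional reduction is the big one: absolute displacement magnitudes
and the calibrated stiffness are model-internal and must not be read as
the published 3D values (the published slope table itself is reproduced
only as the selection-rule input). Plane strain exaggerates in-plane
sliding; the contact normal field is polar-approximate; the lag waveform
is phenomenological; vein curves are synthetic stand-ins; and the Wilcoxon
normal approximation (n > 25) uses a plain tie correction without exact
conditional enumeration.
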