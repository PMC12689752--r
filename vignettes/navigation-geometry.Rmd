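---
title: "Navigation geometry for percutaneous sacroiliac screw placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Navigation geometry for percutaneous sacroiliac screw placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvnav)
```

## The problem

Sacroiliac (SI) screws stabilise the posterior pelvic ring by passing
percutaneously through the ilium into the S1 or S2 vertebral body. Each
screw must stay inside a narrow osseous corridor: breaching anteriorly
enters the small pelvis, superiorly or inferiorly the neuroforamina, and
posteriorly the spinal canal. Navigation systems that display the planned
trajectory to the surgeon must first *register* ("match") the planned
pelvis model to the patient. A radiation-free way to do this is to probe
three palpable landmarks — both anterior superior iliac spines (ASIS) and
the pubic symphysis — and fit the transform that aligns the model to them.

`pelvnav` implements that workflow's geometry end to end, together with a
parametric pelvis phantom and a Monte-Carlo error engine, so the whole
chain — landmark probing, registration, guidance, drilling, and scoring —
can be exercised and validated entirely in software.

## Registration model

Probed landmarks $y_i$ and their model counterparts $x_i$ (correspondence
by label) are related by a similarity transform $T(x) = s\,R\,x + t$ with
isotropic scale $s$, rotation $R$ and translation $t$. `fit_similarity()`
returns the closed-form least-squares optimum of
$\sum_i \lVert T(x_i) - y_i \rVert^2$ (absolute orientation via the SVD of
the cross-covariance of the centred landmark matrices, with the standard
determinant correction so $R$ is always a proper rotation — a mirrored
probe produces large residuals, never a reflection). Scale estimation is
on by default because the clinical workflow resizes the model pelvis to
the patient; `allow_scale = FALSE` gives the rigid fit.

Three landmarks are the minimum for a unique similarity fit, and the fit
is over-determined (9 constraints, 7 parameters), so residuals are
generically non-zero and are always reported: the root-mean-square
fiducial registration error (FRE) and the per-landmark residuals. What
matters surgically is the *target* registration error (TRE) at the screw
corridors, which `target_registration_error()` evaluates at arbitrary
points; for a rotational registration error of angle $\theta$ about an
axis, the displacement of a target at distance $r$ from that axis is
$2\sin(\theta/2)\,r$, so TRE grows with the lever arm — the mechanism
behind the S2 sensitivity discussed below.

## Anatomical frame

`build_frame()` turns the three landmarks into a right-handed orthonormal
frame: origin at the inter-ASIS midpoint, `lateral_right` along the
inter-ASIS axis, `inferior` the direction to the symphysis
orthogonalised against it (so the symphysis lies exactly in the
lateral–inferior plane), `anterior = lateral_right x inferior`, and
`superior = -inferior`. All perforation directions are classified in this
frame, which makes statements like "tilting about the inter-ASIS axis"
and "anterior perforation" computable. Landmark triangles with area below
1 mm² are rejected as degenerate — palpable pelvic landmarks are
centimetres apart in any real pelvis, so this threshold only screens out
broken input.

## Placement metrics

All metrics compare a *planned* and a *drilled* trajectory, each an entry
point, a central aim point (the target at the vertebral body centre), a
screw diameter and an insertion depth.

* **Maximal lateral deviation (MLD)** — the largest orthogonal distance
  of any point of the drilled axis from the planned axis, evaluated over
  the inserted segment (entry to tip). The distance from a point moving
  affinely along a segment to a fixed line is convex in the segment
  parameter, so the maximum is *always* attained at an endpoint; MLD
  therefore localises to the screw base or tip by construction, and
  `mld()` evaluates exactly those two points. Ties report `"tip"`, the
  clinically riskier end.
* **Entry deviation** — Euclidean distance between the entry points.
* **Central-aim deviation** — distance from the planned aim point to the
  *drilled tip*. Using the tip makes the metric depth-aware: drilling
  short or long shows up even on a perfectly aligned axis. (The
  depth-independent alternative, closest approach of the drilled axis,
  was deliberately rejected; anyone comparing numbers across systems
  should note this definition.)
* **Angular deviation** — the angle between the two axis directions, in
  degrees, computed as `atan2(|u x v|, u . v)`, which is numerically exact
  near 0° and 180° where the arccos of a dot product loses half its
  digits. Antiparallel axes report 180°, never folded.
* **Perforation** — the screw is a capsule of radius `diameter/2` along
  the inserted segment, the corridor a capsule of its own radius along
  its axis. The screw breaches iff at some insertion position the
  distance from the drilled axis to the corridor axis plus the screw
  radius exceeds the corridor radius. That excess is again convex along
  the insertion, so the worst breach is found exactly at an endpoint. The
  breach direction is the radial offset at the worst breach projected on
  the (anterior, superior) plane, classified by an 8-sector compass:
  pure labels plus adjacent combinations (e.g. anterior+superior), with a
  combined label whenever the minor component reaches
  $\tan(22.5^\circ)$ of the major one.
* **Correct placement** — defined as absence of perforation.

An optional mesh route (`detect_perforation_mesh()`) samples the screw
capsule surface (default 1 point/mm²) and tests containment in a closed
triangle mesh by ray parity; it exists for mesh-defined corridors and
cross-checks the analytic capsule rule in the tests.

## The phantom

`make_phantom()` builds a parametric, pelvis-like geometry, not an
anatomical atlas: the navigation analysis depends only on the landmark
geometry and the corridor dimensions, and those are the parameters.

Defaults (all configurable through `phantom_params()`):

| parameter | default | rationale |
|---|---|---|
| ASIS span | 240 mm | order-of-magnitude adult pelvis |
| symphysis drop | 90 mm | the symphysis sits much closer to the inter-ASIS axis than the ASIS are to each other — the ratio drives the tilt sensitivity |
| S1 corridor radius | 7.5 mm | S1 offers the wider safe channel |
| S2 corridor radius | 5.5 mm | S2 is flatter and narrower |
| S1/S2 tip margin | 15 / 8 mm | room past the aim point before the far cortex; larger for S1 |
| screw diameter | 7.5 mm | standard cannulated SI screw |

Corridor radii are phantom parameters (the narrowest-section radius of
the safe channel), not published measurements. Each pelvis carries four
corridors (S1 and S2, both sides) with the planned trajectory along each
corridor axis. With `anatomy_jitter_sigma = 0` (default) all phantoms are
identical, like a test series on identical foam pelvis models; setting it
positive adds per-pelvis anatomical variation.

Two modelling simplifications matter when interpreting results. First,
the capsule corridor applies its narrowest radius along the *whole* axis,
while real cortex is only tight mid-canal; in-silico correct rates are
therefore conservative relative to physical trials, and the meaningful
outputs are orderings and mechanisms, not absolute rates. Second, there
is no soft tissue, no imaging chain and no display instability as a
separate process: everything between probing and drilling is lumped into
the landmark noise and the operator jitter.

## Noise model and trial protocol

`noise_model()` has four terms, all configurable:

* `landmark_sigma` (default 2 mm) — isotropic Gaussian probing error per
  landmark, the typical fiducial-localisation error when probing palpable
  bony landmarks percutaneously; it also absorbs display drift.
* `symphysis_anterior_bias` (default 0) — a *systematic* displacement of
  the probed symphysis along the world anterior axis: marking the
  symphysis too far anteriorly through the soft tissue, the specific
  failure mode that tilts the registration plane.
* `operator_entry_sigma` (default 1 mm) and `operator_angle_sigma`
  (default 1°) — freehand execution error against the displayed
  trajectory, applied as Gaussian entry jitter and an exact Rodrigues
  rotation of the axis about a random perpendicular direction.

`run_trial()` reproduces the clinical protocol: each pelvis is placed at
a random rigid pose, its landmarks are probed *once*, one registration is
fitted, and the resulting world-space guidance error (estimated map
composed with the inverse true map) is shared by all four screws, drilled
in the fixed order S1 right, S1 left, S2 right, S2 left. Because the
systematic error component is shared within a pelvis,
direction-concordant perforations within a pelvis are the signature of
matching error — `summarize_trial()` reports exactly that per-pelvis
flag, alongside per-type rates, medians with IQRs, a perforation-direction
histogram and descriptive S1-vs-S2 comparisons (Mann–Whitney for the
distance metrics, t-test for the angular one; nothing is gated on these
p-values).

`symphysis_tilt_experiment()` isolates the bias term: sweeping a pure
anterior symphysis bias, it reports the induced rotation (which is about
the inter-ASIS axis, because the two ASIS stay put), the onset bias at
which each screw type starts perforating, and the fraction of induced S2
perforations with an anterior component. With the default geometry the
narrow S2 corridor fails at roughly half the bias S1 tolerates, and the
induced S2 breaches are anterior — the structural explanation for why S2
screws are so much harder to place than S1 screws under identical noise.

## Guidance semantics

`guidance_update()` is a deterministic state machine over tracked drill
poses. The alignment criterion (the specification of "positioned
correctly") is an entry sphere plus an aim corridor: `entry_ok` when the
tip is within `entry_mm` (default 2 mm) of the planned entry, `axis_ok`
when additionally the drill ray passes within `aim_mm` (default 2 mm) of
the planned central aim. Both defaults sit well below the corridor radii,
so satisfied guidance implies geometric safety in the default phantom.
Flags are pure functions of the current pose given the phase; the only
hidden state is the monotone phase progression `searching ->
entry_captured -> aligned -> depth_reached`. Two refinements keep the
semantics physical: once aligned and advancing, the entry stays captured
while the tip remains within tolerance of the planned axis segment (the
tip necessarily leaves the entry *sphere* as it advances), and depth only
counts after the aligned milestone, so phases never skip alignment.
Tracking loss is modelled as gaps in the pose stream: flags hold their
last values and a `tracking_stale` event is emitted after 1 s (default).
`guidance_advance()` moves to the next screw in the fixed drilling order
and ends in a terminal `complete` state after the last screw.

## Numerical choices

* Degenerate landmark triangles: area < 1 mm² is an error.
* Reflection handling in the fit: sign flip on the smallest singular
  vector (determinant correction); with three planar points the
  cross-covariance is rank 2 and the correction acts on the null vector,
  so exact similarity correspondences are still recovered exactly.
* MLD and perforation maxima are evaluated at segment endpoints; this is
  exact (convexity), not an approximation, and the tests verify it
  against dense-sampling oracles (10^5 axis samples for MLD, 10^4
  capsule-surface samples for perforation).
* Angles: degrees in all interfaces, radians internally; `atan2`
  formulation for angles near 0/180.
* MLD base/tip tie-break: `"tip"`.
* Fitted scale outside [0.5, 2.0] raises a warning flag on the result
  (never an error): patient and model pelves should be within a factor
  of ~2.
* All randomness flows through explicit seeds; sampling functions restore
  the caller's RNG stream.

## Problem sizes used in validation

The shipped test suite validates exact registration recovery on 1000
random transforms, MLD against the dense oracle on 1000 random trajectory
pairs, perforation against capsule-surface sampling on 1000 random
screw/corridor pairs, a 10-pelvis zero-noise trial (40/40 correct with
all metrics at numerical zero), a 9-level bias sweep at 500 pelves per
level, a 5-level noise-monotonicity sweep at 200 pelves per level, and
byte-identical guidance replays. The bundled `scripts/acceptance.R`
re-runs the default 10-pelvis trial, a 100-pelves-per-level tilt sweep
and a 500-transform recovery check from a caller-supplied seed.

## Limitations

* The phantom is geometric; no CT synthesis, segmentation, DICOM or
  soft-tissue modelling, and no separate model of display drift
  ("swimming") — it is not separable from matching error in this design
  and is absorbed into the lumped noise terms.
* Correct-placement rates depend strongly on the corridor-radius
  parameters; only orderings and mechanisms transfer to other geometries.
* Central-aim deviation is defined to the drilled tip; compare with care
  against systems using closest-approach definitions.
* Registration supports exactly the three-landmark anatomy; the math
  generalises to more fiducials but no additional anatomy model is
  provided, and surface/ICP registration is out of scope.
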