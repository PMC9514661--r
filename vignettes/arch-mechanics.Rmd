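---
title: "Forward-dynamic stance simulation of foot arch mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-dynamic stance simulation of foot arch mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adult acquired flatfoot deformity follows dysfunction of the posterior
tibialis (PT), the muscle whose tendon inserts on the navicular and
suspends the medial longitudinal arch.  The standard surgical response is
a flexor digitorum longus (FDL) to PT tendon transfer, but the FDL has
roughly one third of the PT's force capability, so the transfer only
partially restores the physiological medial/lateral distribution of
vertical ground reaction force (vGRF) and an osteotomy is usually added.
A passive pulley-like implant placed between the transferred tendon and
the navicular insertion can amplify the delivered force — here twofold, at
the cost of twofold donor excursion — and this package quantifies, in
simulation, how much of the physiological force distribution such an
implant recovers compared with the direct transfer.

`archgait` simulates the stance phase of gait with the methodology of
robotic cadaver gait rigs: the tibia is fixed in space and a rigid ground
plane plays back the inverse motion of gait beneath the foot while nine
extrinsic muscles are driven by activation profiles.  Four configurations
are compared: an arched foot, a flatfoot (PT disabled, arch dropped), a
flatfoot with the FDL-to-PT tendon transfer, and a flatfoot with the
implant-modified transfer.

## Model

**Skeleton.** Five rigid segments (talus; lateral hindfoot comprising
calcaneus, cuboid and rays 2–5; medial midfoot comprising navicular,
first cuneiform and first metatarsal; hallux; lateral toes) connect to the
fixed tibia through five revolute joints: ankle, subtalar, arch, and the
medial and lateral metatarsophalangeal (MTP) joints.  The arch joint's
axis runs anteroposteriorly under the second ray, so that rotation lets
the first ray drop (arch flattening) or rise independently of the lateral
column.  The arch joint carries a torsional spring of 1 N·m/° — a lumped
representation of the deltoid and spring ligaments — and the flatfoot
configuration raises its rest angle until the first metatarsocuneiform
landmark sits 8 mm lower, the difference typically observed between arched
and flat feet.  All other segments' masses, inertias and joint axes are
literature-plausible schematic defaults for an 82 kg adult; none of them
are fitted to outputs after the fact.  Each non-arch joint carries a small
passive spring and a viscous damper sized towards the short-range
impedance that active muscle provides in reality (the muscle model here is
deliberately impedance-free, see below), plus stiff soft-stops at the
anatomical range limits.

**Muscles.** Nine extrinsic muscles (PT, FDL, anterior tibialis, extensor
digitorum longus, extensor hallucis longus, flexor hallucis longus,
peroneus longus, peroneus brevis, soleus) are straight-line via-point
paths from the tibia to their insertions.  Muscle tension is activation
times maximum isometric force — no force–length, force–velocity or
activation dynamics — and the force is applied along each path segment at
its endpoints.  The FDL's maximum isometric force is one third of the
PT's (500 vs 1500 N).

**Scenarios.** The flatfoot disables the PT.  The tendon transfer
additionally disables the native FDL and drives the PT's path with the
FDL's activation and force capacity (the transferred tendon follows the
original PT course exactly, an idealised surgical routing).  The
implant-modified transfer routes the transferred tendon around an ideal,
frictionless pulley anchored on the tibia: the artificial tendon from the
implant to the navicular carries twice the donor tension, the donor must
provide twice the excursion, and mechanical work balances identically.
With amplification 1 the implant reduces exactly to the direct transfer.

**Contact.** Five spheres (heel 6 cm, first metatarsal head 4 cm, fifth
metatarsal head 3 cm, hallux 3 cm, fifth toe 2 cm — diameters) meet the
plane through an analytic sphere–half-space law: normal force
$k\,d^{3/2}(1 + c\,\dot d)$, floored at zero, with per-sphere stiffness
scales (softer forefoot and toe pads than the heel pad) chosen so the
peak heel-pad deformation during a calibrated run is about 1 cm.
Friction is viscous, $F_F = F_N f_v v_s$.  The default coefficient is
small (1 s/m): with five rigid
contact spheres under a plane that pitches at up to 0.6 rad/s, a large
viscous coefficient converts transient slip into tangential forces that
wedge the foot and destabilise the run — tangential compliance that a
distributed elastic-foundation contact would provide is simply absent
from a five-point model.  The no-slip behaviour of the gait rig is instead
built into the trajectory kinematically (below).

## Synthetic inputs

The experimentally derived inputs of such a rig — EMG-based activation
levels at ten evenly spaced stance points, and the 6-DOF plane trajectory
fitted to gait data over the 4.09 s slowed stance — are not available
numerically, so the package generates inputs with the same structure:

* **Activations.** The ankle-torque demand implied by the target loading
  profile (the classic double-peak vGRF of healthy gait: first peak
  1.14 BW at 29.7% stance, valley 0.900 BW near 50%, second peak 1.07 BW
  at 73%) applied at the advancing centre of pressure is distributed over
  the dorsiflexor group in early stance and the plantarflexor group in
  late stance, through per-muscle weights and Gaussian timing envelopes,
  then converted to activation via each muscle's capacity and ankle moment
  arm.  A small early peroneal co-activation stabilises the subtalar
  joint during the loading response.  The result is sampled at the ten
  control abscissae and interpolated linearly — faithfully reproducing the
  low-resolution piecewise-linear muscle forces of the emulated rig,
  including their visible corner artifacts in the force curves.
* **Trajectory.** A quasi-static inversion marches over the stance grid:
  with the pitch schedule (heel-down +17° at heel strike to toe-down −44°
  at toe off), late-stance roll and yaw prescribed, the foot's equilibrium
  posture and the plane height are solved so the total vertical contact
  force matches the target loading profile (dynamic-relaxation equilibria
  with a secant iteration on plane height).  At heel strike the plane is
  tangent to the heel sphere alone; at toe off to the toe spheres alone.
  A dynamic probe then rescales the late activation control points (in
  push-off the force is set by plantarflexor torque, not plane height),
  and a few height-refinement passes against short forward-dynamic runs
  absorb the remaining static-to-dynamic offsets.  Finally the plane's
  material origin is integrated as a rolling (no-slip) path, so the
  surface under the load centroid is instantaneously at rest — the
  kinematic counterpart of "the foot does not slip".
* A late-stance plane roll (−5.3°, lateral edge raised) presses the
  lateral forefoot during propulsion.  It balances the model's otherwise
  medial-heavy frictionless push-off equilibria, standing in for the
  lateral load-sharing that distributed plantar tissue and intrinsic
  musculature provide in vivo.

All generation is deterministic; the seed only enters if the optional
weight jitter is switched on.  The defaults are therefore the study
conditions, not tunables.

## Dynamics and numerics

The equations of motion $M(q)\ddot q = \tau - C(q,\dot q)$ use a
centre-of-mass-Jacobian mass matrix and a recursive Newton–Euler
velocity-product sweep; all applied forces (muscle, contact, gravity,
passive) enter through point Jacobians.  The stance is integrated with
`deSolve::lsoda` at `rtol = 1e-6`, `atol = 1e-8`, with a compiled (C++)
right-hand side cross-checked against the plain-R reference
implementation to 1e-14.  Traces are resampled to 1025 uniform samples
over 0–100% stance.  Body-weight calibration shifts the plane vertically
until the mean of the two vGRF peak magnitudes matches the 82 kg
double-peak scale (1.105 BW, tolerance 0.02 BW) on the arched model; the
offset is shared by all four scenarios, mirroring the shared rig setup.

Initial conditions are the static equilibrium against the heel-strike
plane pose.  Static equilibria throughout the package are found by
dynamic relaxation (damped integration to rest) polished by a damped
Newton iteration — far more robust than Newton alone when contact
activates or a joint rests on a range stop.

## What the defaults reproduce, and what they do not

With the shipped defaults the calibrated arched simulation shows the
double-peak profile (first peak ≈ 1.10 BW at 28%, valley ≈ 0.87 BW,
second peak at 68% stance, heel-pad penetration ≈ 1 cm), and the four
scenarios split peak forefoot vGRF medially/laterally near the published
pattern: arched ≈ 37%, flatfoot ≈ 50%, tendon transfer ≈ 45%, implant ≈
40% medial, i.e. lateral shifts of ≈ 5 and ≈ 10 percentage points and an
implant-to-transfer improvement ratio of ≈ 2.1.

Known limitations, deliberate and otherwise:

* The heel-sphere force trace is *similar*, not identical, across
  scenarios (within ~25% of its peak): the dropped arch feeds back into
  mid-stance totals through the shared calibration.  A rig with per-model
  load calibration would suppress this.
* Per-sphere slip distances of a rigid-segment foot on a rigid plane are
  millimetres to centimetres over a stance in which joints rotate by tens
  of degrees; "no slip" holds at the load centroid by construction, not
  at every sphere.
* The activation profiles are structural emulations, not recordings; the
  piecewise-linear 10-point resolution leaves corner artifacts in the
  force curves, as it does in the emulated rig.
* No wrapping surfaces, no Hill-type muscle, no ligaments beyond the arch
  spring, no soft-tissue or healing biology.  Between-scenario
  comparisons are the intended use; absolute magnitudes inherit the
  schematic parameter set.

## Reproducing the analysis

```{r example}
library(archgait)

cfg <- run_config(scenarios = c("ARCHED", "FLATFOOT", "FLATFOOT_TT",
                                "FLATFOOT_TT_IMPLANT"),
                  out_dir = "archgait_out", seed = 1L)
report <- run_compare(cfg)
print(report)
```

`scripts/acceptance.R` (repository root) runs the same pipeline headless
and writes the worked-example restorations, the pulley amplification, the
calibrated first-peak magnitude and the per-scenario peak medial
percentages to JSON.
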